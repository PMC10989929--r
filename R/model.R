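#' Synthesis-rate fold change from intensity and decay fold changes
#'
#' At steady state `Int = alpha / lambda`, so the ratio of synthesis
#' rates between two transcript segments (or conditions) i and j is
#' \deqn{FC_{synt} = \alpha_i/\alpha_j =
#'       (Int_i/Int_j) \times (\lambda_i/\lambda_j),}
#' the product of the intensity fold change and the decay-constant fold
#' change. When the two segments are the 5' UTR and the ORF of one
#' transcript driven by a single promoter, `FCsynt > 1` indicates
#' premature termination after the UTR and the termination fraction is
#' `1 - 1/FCsynt` (see [termination_fraction()]).
#'
#' @param fc_intensity Intensity fold change(s), > 0.
#' @param fc_decay Decay-constant fold change(s), > 0.
#' @return A tibble with `fc_intensity`, `fc_decay`, `fc_synthesis`
#'   (their product, unrounded), `termination_fraction`,
#'   `readthrough_fraction` and `no_evidence` (TRUE where
#'   `fc_synthesis < 1`, in which case the termination fraction is 0).
#' @export
#' @examples
#' synthesis_ratio(11, 2.2)$fc_synthesis  # 24.2
synthesis_ratio <- function(fc_intensity, fc_decay) {
  check_positive(fc_intensity, "fc_intensity")
  check_positive(fc_decay, "fc_decay")
  fc_synthesis <- fc_intensity * fc_decay
  tf <- termination_fraction(fc_synthesis)
  tibble::tibble(
    fc_intensity = fc_intensity,
    fc_decay = fc_decay,
    fc_synthesis = fc_synthesis,
    termination_fraction = tf,
    readthrough_fraction = 1 - tf,
    no_evidence = fc_synthesis < 1
  )
}

#' Premature-termination fraction from a UTR/ORF synthesis ratio
#'
#' Under a single promoter, every initiation synthesizes the 5' UTR but
#' only the read-through fraction synthesizes the ORF, so
#' `FCsynt(UTR/ORF) = 1 / (1 - f)` and hence `f = 1 - 1/FCsynt`. A ratio
#' below 1 carries no evidence of termination and returns 0.
#'
#' @param fc_synthesis Synthesis-rate fold change(s) UTR over ORF, > 0.
#' @return Numeric vector of termination fractions in \[0, 1).
#' @export
#' @examples
#' termination_fraction(24.2)  # 0.9587..., i.e. 95.9%
termination_fraction <- function(fc_synthesis) {
  check_positive(fc_synthesis, "fc_synthesis")
  ifelse(fc_synthesis >= 1, 1 - 1 / fc_synthesis, 0)
}

#' Decay-constant fold change from two half-lives
#'
#' Since `lambda = log(2) / t_half`, the ratio of decay constants is the
#' inverse ratio of half-lives: `lambda_num / lambda_den =
#' t_half_den / t_half_num`.
#'
#' @param t_half_num,t_half_den Half-lives in minutes (> 0) of the
#'   numerator and denominator segments/conditions.
#' @return Numeric fold change of the decay constant.
#' @export
#' @examples
#' decay_fc_from_half_lives(17.1, 7.5)  # 0.4386
decay_fc_from_half_lives <- function(t_half_num, t_half_den) {
  check_positive(t_half_num, "t_half_num")
  check_positive(t_half_den, "t_half_den")
  t_half_den / t_half_num
}

#' Reconstruct the synthesis-rate / termination summary table
#'
#' Combines three fold-change comparisons — 5' UTR vs ORF under the
#' control condition, 5' UTR vs ORF under the stress condition, and the
#' UTR between stress and control — into the full synthesis-rate
#' calculus: intensity FC, decay-constant FC, their product (synthesis
#' FC), the premature-termination percentage for the within-condition
#' comparisons, and the transcription-rate interpretation (reciprocal of
#' the UTR stress/control synthesis FC) for the between-condition
#' comparison.
#'
#' Each comparison needs an intensity fold change and either a
#' decay-constant fold change directly or the pair of half-lives it
#' derives from (numerator segment first). All arithmetic is on
#' unrounded values; the `*_label` columns apply the reporting
#' convention (fold changes >= 1 to one decimal, < 1 to two decimals,
#' percentages to one decimal, half away from zero).
#'
#' @param fc_int_mock,fc_int_uv,fc_int_utr_uvmock Intensity fold changes
#'   for mock UTR/ORF, UV UTR/ORF and UTR UV/mock.
#' @param fc_decay_mock,fc_decay_uv,fc_decay_utr_uvmock Decay-constant
#'   fold changes; each may instead be given via the corresponding
#'   half-life pair.
#' @param t12_mock_utr,t12_mock_orf Mock half-lives (min) of UTR and ORF.
#' @param t12_uv_utr,t12_uv_orf UV half-lives (min).
#' @return A tibble with one row per comparison: `comparison`,
#'   `fc_intensity`, `fc_decay`, `fc_synthesis`, `termination_fraction`,
#'   `readthrough_fraction`, `transcription_rate_factor` (non-NA only
#'   for the UV/mock row: the factor by which transcription is reduced),
#'   and formatted `fc_synthesis_label` / `termination_label`.
#' @seealso [format_table1()] to lay the result out with quantities as
#'   rows, as in a publication table.
#' @export
#' @examples
#' table1_report(
#'   fc_int_mock = 11, fc_decay_mock = 2.2,
#'   fc_int_uv = 6.5, t12_uv_utr = 17.1, t12_uv_orf = 7.5,
#'   fc_int_utr_uvmock = 2.52, t12_mock_utr = 3.1
#' )
table1_report <- function(fc_int_mock = NULL,
                          fc_int_uv = NULL,
                          fc_int_utr_uvmock = NULL,
                          fc_decay_mock = NULL,
                          fc_decay_uv = NULL,
                          fc_decay_utr_uvmock = NULL,
                          t12_mock_utr = NULL,
                          t12_mock_orf = NULL,
                          t12_uv_utr = NULL,
                          t12_uv_orf = NULL) {
  resolve_decay <- function(fc, t_num, t_den, what) {
    if (!is.null(fc)) return(fc)
    if (!is.null(t_num) && !is.null(t_den)) {
      return(decay_fc_from_half_lives(t_num, t_den))
    }
    NULL
  }
  fc_decay_mock <- resolve_decay(fc_decay_mock, t12_mock_utr, t12_mock_orf)
  fc_decay_uv <- resolve_decay(fc_decay_uv, t12_uv_utr, t12_uv_orf)
  fc_decay_utr_uvmock <- resolve_decay(fc_decay_utr_uvmock,
                                       t12_uv_utr, t12_mock_utr)

  cells <- list(
    "mock intensity FC" = fc_int_mock,
    "UV intensity FC" = fc_int_uv,
    "UTR UV/mock intensity FC" = fc_int_utr_uvmock,
    "mock decay FC (or mock half-life pair)" = fc_decay_mock,
    "UV decay FC (or UV half-life pair)" = fc_decay_uv,
    "UTR UV/mock decay FC (or UTR half-life pair)" = fc_decay_utr_uvmock
  )
  absent <- names(cells)[vapply(cells, is.null, logical(1))]
  if (length(absent)) {
    stop("incomplete input; missing cells: ",
         paste(absent, collapse = "; "), call. = FALSE)
  }

  mock <- synthesis_ratio(fc_int_mock, fc_decay_mock)
  uv <- synthesis_ratio(fc_int_uv, fc_decay_uv)
  uvmock <- synthesis_ratio(fc_int_utr_uvmock, fc_decay_utr_uvmock)

  out <- dplyr::bind_rows(mock, uv, uvmock) |>
    dplyr::mutate(
      comparison = c("mock UTR/ORF", "UV UTR/ORF", "UTR UV/mock"),
      .before = 1
    )

  # termination is a UTR-vs-ORF concept; the between-condition row
  # instead reads as a transcription-rate change
  out$termination_fraction[3] <- NA_real_
  out$readthrough_fraction[3] <- NA_real_
  out$transcription_rate_factor <-
    c(NA_real_, NA_real_, 1 / out$fc_synthesis[3])
  out$fc_intensity_label <- format_fold(out$fc_intensity)
  out$fc_decay_label <- format_fold(out$fc_decay)
  out$fc_synthesis_label <- format_fold(out$fc_synthesis)
  out$termination_label <- c(format_pct(out$termination_fraction[1:2]), NA)
  out
}

#' Lay a synthesis report out with quantities as rows
#'
#' @param report The tibble returned by [table1_report()].
#' @return A data frame of formatted strings with rows "FC of
#'   intensity", "FC of decay constant", "FC of synthesis rate" and
#'   "Termination after UTR", one column per comparison — the layout of
#'   a publication summary table.
#' @export
format_table1 <- function(report) {
  stopifnot(all(c("comparison", "fc_synthesis_label") %in% names(report)))
  out <- data.frame(
    quantity = c("FC of intensity", "FC of decay constant",
                 "FC of synthesis rate", "Termination after UTR"),
    check.names = FALSE
  )
  for (i in seq_len(nrow(report))) {
    out[[report$comparison[i]]] <- c(
      report$fc_intensity_label[i],
      report$fc_decay_label[i],
      report$fc_synthesis_label[i],
      if (is.na(report$termination_label[i])) "NA"
      else report$termination_label[i]
    )
  }
  out
}

#' Synthesis report from per-compartment measurements
#'
#' Alternative entry to [table1_report()] when absolute (or commensurate)
#' steady-state intensities and fitted decay constants are available for
#' all four compartment/condition cells. Also emits the implied absolute
#' synthesis rates `alpha_hat = intensity * lambda` per cell (arbitrary
#' units / min) as the `"alpha_hat"` attribute.
#'
#' @param measurements Tibble with columns `condition` (two values,
#'   control first in factor/alphabetical order given by `conditions`),
#'   `compartment` ("UTR"/"ORF"), `intensity` (> 0) and `lambda`
#'   (min^-1) or `half_life` (min).
#' @param conditions Length-2 character vector naming the control and
#'   stress condition as they appear in `measurements`.
#' @return As [table1_report()].
#' @export
#' @examples
#' meas <- tibble::tibble(
#'   condition = c("mock", "mock", "uv", "uv"),
#'   compartment = c("UTR", "ORF", "UTR", "ORF"),
#'   intensity = c(10, 1, 25.2, 4),
#'   lambda = log(2) / c(3.1, 7.2, 17.1, 7.5)
#' )
#' table1_from_measurements(meas)
table1_from_measurements <- function(measurements,
                                     conditions = c("mock", "uv")) {
  m <- tibble::as_tibble(measurements)
  if (!"lambda" %in% names(m)) {
    if (!"half_life" %in% names(m)) {
      stop("measurements need `lambda` or `half_life`", call. = FALSE)
    }
    m$lambda <- decay_constant(m$half_life)
  }
  needed <- tidyr::expand_grid(condition = conditions,
                               compartment = c("UTR", "ORF"))
  have <- dplyr::semi_join(needed, m, by = c("condition", "compartment"))
  if (nrow(have) < 4L) {
    miss <- dplyr::anti_join(needed, m, by = c("condition", "compartment"))
    stop("incomplete input; missing cells: ",
         paste(paste(miss$condition, miss$compartment), collapse = "; "),
         call. = FALSE)
  }
  cell <- function(cond, comp, col) {
    v <- m[[col]][m$condition == cond & m$compartment == comp]
    check_positive(v[1], paste(cond, comp, col))
    v[1]
  }
  ctl <- conditions[1]; trt <- conditions[2]

  out <- table1_report(
    fc_int_mock = cell(ctl, "UTR", "intensity") / cell(ctl, "ORF", "intensity"),
    fc_int_uv = cell(trt, "UTR", "intensity") / cell(trt, "ORF", "intensity"),
    fc_int_utr_uvmock =
      cell(trt, "UTR", "intensity") / cell(ctl, "UTR", "intensity"),
    fc_decay_mock = cell(ctl, "UTR", "lambda") / cell(ctl, "ORF", "lambda"),
    fc_decay_uv = cell(trt, "UTR", "lambda") / cell(trt, "ORF", "lambda"),
    fc_decay_utr_uvmock =
      cell(trt, "UTR", "lambda") / cell(ctl, "UTR", "lambda")
  )
  attr(out, "alpha_hat") <- m |>
    dplyr::mutate(alpha_hat = .data$intensity * .data$lambda) |>
    dplyr::select("condition", "compartment", "alpha_hat")
  out
}
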