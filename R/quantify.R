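#' Relative quantification of qPCR Ct records by the delta-delta-Ct method
#'
#' Converts a table of raw Ct values into relative abundances. Technical
#' replicates are averaged on the Ct scale (geometric averaging on the
#' abundance scale), then per biological series
#' \deqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{reference}, \quad
#'       \Delta\Delta Ct(t) = \Delta Ct(t) - \Delta Ct(t_{cal}), \quad
#'       rq = 2^{-\Delta\Delta Ct},}
#' with amplification efficiency fixed at exactly 2. The reference gene
#' is matched on (condition, biological replicate, timepoint); by
#' construction `rq = 1` at the calibrator time in every series.
#' Biological replicates are not averaged — each series passes through
#' for pooled curve fitting downstream.
#'
#' @param records Tibble/data frame of Ct records with columns
#'   `condition`, `region`, `compartment`, `time_min`, `bio_rep`,
#'   `tech_rep`, `target`, `ct` (the layout written by
#'   [simulate_chase()] / [read_qpcr_csv()]).
#' @param reference_target Name of the reference amplicon (default
#'   `"16S"`).
#' @param calibrator_time Chase time (min) whose abundance defines 1.
#' @return A tibble of relative quantities: `condition`, `region`,
#'   `compartment`, `bio_rep`, `series`, `time_min`, `rq`.
#' @export
#' @examples
#' ct <- simulate_chase(simulation_params(ct_noise_sd = 0, seed = 1))
#' rq <- delta_delta_ct(ct)
#' rq[rq$time_min == 0, "rq"]  # all exactly 1
delta_delta_ct <- function(records, reference_target = "16S",
                           calibrator_time = 0) {
  needed <- c("condition", "region", "compartment", "time_min",
              "bio_rep", "tech_rep", "target", "ct")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("Ct table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)

  bad <- !is.finite(records$ct)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite Ct rejected", call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }

  is_ref <- records$target == reference_target
  if (!any(is_ref)) {
    stop(sprintf("no rows for reference target '%s'", reference_target),
         call. = FALSE)
  }

  ref <- records[is_ref, ] |>
    dplyr::group_by(.data$condition, .data$bio_rep, .data$time_min) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")

  tgt <- records[!is_ref, ] |>
    dplyr::group_by(.data$condition, .data$region, .data$compartment,
                    .data$bio_rep, .data$time_min) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    dplyr::left_join(ref, by = c("condition", "bio_rep", "time_min"))

  if (anyNA(tgt$ref_ct)) {
    miss <- tgt[is.na(tgt$ref_ct), ]
    stop(sprintf(
      "missing reference Ct for series %s",
      paste(unique(paste0(miss$condition, "/", miss$region, "/bio",
                          miss$bio_rep, "/t", miss$time_min)),
            collapse = "; ")
    ), call. = FALSE)
  }

  tgt <- dplyr::mutate(tgt, dct = .data$ct - .data$ref_ct)

  cal <- tgt |>
    dplyr::filter(.data$time_min == calibrator_time) |>
    dplyr::select("condition", "region", "compartment", "bio_rep",
                  dct0 = "dct")
  out <- dplyr::left_join(
    tgt, cal,
    by = c("condition", "region", "compartment", "bio_rep")
  )
  if (anyNA(out$dct0)) {
    miss <- out[is.na(out$dct0), ]
    stop(sprintf(
      "no calibrator (t = %g) measurement for series %s",
      calibrator_time,
      paste(unique(paste0(miss$condition, "/", miss$region, "/bio",
                          miss$bio_rep)), collapse = "; ")
    ), call. = FALSE)
  }

  out |>
    dplyr::mutate(
      rq = 2^(-(.data$dct - .data$dct0)),
      series = paste0(.data$region, "/b", .data$bio_rep)
    ) |>
    dplyr::select("condition", "region", "compartment", "bio_rep",
                  "series", "time_min", "rq") |>
    dplyr::arrange(.data$condition, .data$compartment, .data$region,
                   .data$bio_rep, .data$time_min)
}

#' Normalize a signal series by a reference series
#'
#' Elementwise `values / reference`, optionally rescaled so the element
#' at `baseline` equals 1 — the normalization used for enzymatic-activity
#' readouts (signal at a fixed incubation time divided by the pre-treatment
#' signal) and for immunoblot band intensities divided by a loading
#' control.
#'
#' @param values Numeric vector.
#' @param reference Numeric vector of the same length, strictly positive.
#' @param baseline Optional index; the returned series is divided by its
#'   value at this index.
#' @return Numeric vector of normalized ratios.
#' @export
#' @examples
#' normalize_signal(c(4, 2), c(2, 2), baseline = 1)  # 1.0 0.5
normalize_signal <- function(values, reference, baseline = NULL) {
  if (length(values) != length(reference)) {
    stop("`values` and `reference` must have equal length", call. = FALSE)
  }
  if (length(values) == 0L) return(numeric(0))
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("`reference` must be strictly positive and finite", call. = FALSE)
  }
  out <- values / reference
  if (!is.null(baseline)) {
    if (!is.numeric(baseline) || length(baseline) != 1L ||
        baseline < 1 || baseline > length(out)) {
      stop("`baseline` must index the series", call. = FALSE)
    }
    out <- out / out[baseline]
  }
  out
}
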