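#' Steady-state segment abundances under the promoter/termination model
#'
#' At steady state a first-order species balances synthesis against decay,
#' so its level is Int = alpha / lambda. Every initiation transcribes the
#' 5' UTR, but only the read-through fraction `1 - f_term` transcribes the
#' ORF, hence
#' \deqn{Int_{UTR} = \alpha/\lambda_{UTR}, \quad
#'       Int_{ORF} = (1 - f)\,\alpha/\lambda_{ORF}.}
#'
#' @param params A [simulation_params()] object.
#' @return A tibble with one row per compartment: `compartment`
#'   ("UTR"/"ORF"), `lambda` (min^-1), `synthesis_rate`
#'   (effective initiations/min reaching the segment) and `intensity`
#'   (steady-state abundance, arbitrary units).
#' @export
#' @examples
#' steady_state_abundance(simulation_params(f_term = 0, lambda_orf = log(2) / 3.1))
steady_state_abundance <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  tibble::tibble(
    compartment = c("UTR", "ORF"),
    lambda = c(params$lambda_utr, params$lambda_orf),
    synthesis_rate = c(params$alpha, (1 - params$f_term) * params$alpha),
    intensity = .data$synthesis_rate / .data$lambda
  )
}

#' Simulate a rifampicin-chase RT-qPCR experiment
#'
#' Generates per-well Ct values for a transcription-arrest time course.
#' The true relative abundance of a segment at chase time t is
#' `exp(-lambda * t)`; the emitted Ct is
#' `ref_ct_mean + baseline_offset - log2(Int * exp(-lambda * t)) + e`
#' with `e ~ Normal(0, ct_noise_sd)` per well (amplification efficiency
#' exactly 2, so one half-life costs one cycle). The reference gene is
#' decay-free: its Ct is `ref_ct_mean + e`. Output is deterministic for a
#' given `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @param condition Condition label stamped on every row (e.g. "mock").
#' @param baseline_offset Cycles separating the target baseline from the
#'   reference gene at unit abundance; arbitrary, cancels in the
#'   delta-delta-Ct analysis.
#' @param reference_target Name of the reference amplicon.
#' @return A tibble of Ct records with columns `sample`, `condition`,
#'   `region`, `compartment`, `time_min`, `bio_rep`, `tech_rep`,
#'   `target`, `ct`.
#' @seealso [delta_delta_ct()] to convert to relative quantities.
#' @export
#' @examples
#' ct <- simulate_chase(simulation_params(ct_noise_sd = 0, seed = 1))
#' head(ct)
simulate_chase <- function(params, condition = "mock",
                           baseline_offset = 10,
                           reference_target = "16S") {
  stopifnot(inherits(params, "simulation_params"))
  ss <- steady_state_abundance(params)

  grid <- tidyr::expand_grid(
    compartment = c("UTR", "ORF"),
    region_i = seq_len(params$n_regions),
    bio_rep = seq_len(params$n_bio_reps),
    time_min = params$timepoints,
    tech_rep = seq_len(params$n_tech_reps)
  ) |>
    dplyr::left_join(ss, by = "compartment") |>
    dplyr::mutate(
      region = paste0(ifelse(.data$compartment == "UTR", "5UTR", "ORF"),
                      "-", .data$region_i),
      ct_true = params$ref_ct_mean + baseline_offset -
        log2(.data$intensity * exp(-.data$lambda * .data$time_min))
    )

  ref <- tidyr::expand_grid(
    bio_rep = seq_len(params$n_bio_reps),
    time_min = params$timepoints,
    tech_rep = seq_len(params$n_tech_reps)
  ) |>
    dplyr::mutate(
      compartment = "reference",
      region = reference_target,
      ct_true = params$ref_ct_mean
    )

  keep <- c("region", "compartment", "time_min", "bio_rep", "tech_rep",
            "ct_true")
  out <- dplyr::bind_rows(grid[keep], ref[keep]) |>
    dplyr::mutate(
      condition = condition,
      target = ifelse(.data$compartment == "reference",
                      reference_target, .data$region),
      sample = paste(condition, "b", .data$bio_rep, "t", .data$time_min,
                     sep = "_")
    )

  noise <- withr::with_seed(
    derive_seed(params$seed, 1L),
    stats::rnorm(nrow(out), mean = 0, sd = params$ct_noise_sd)
  )

  out |>
    dplyr::mutate(ct = .data$ct_true + noise) |>
    dplyr::select(
      "sample", "condition", "region", "compartment",
      "time_min", "bio_rep", "tech_rep", "target", "ct"
    ) |>
    dplyr::arrange(
      .data$compartment, .data$region, .data$bio_rep,
      .data$time_min, .data$tech_rep
    )
}

#' Simulate steady-state intensity fold changes between compartments and
#' conditions
#'
#' From the steady-state levels of two parameterised conditions, emits
#' the fold changes a transcriptome-intensity comparison would measure:
#' UTR/ORF within each condition and condition2/condition1 within each
#' compartment. Optional multiplicative log-normal noise models
#' measurement error on the intensity scale.
#'
#' @param params_1,params_2 [simulation_params()] for the two conditions
#'   (e.g. mock and UV).
#' @param labels Length-2 character vector of condition labels.
#' @param log_noise_sd Standard deviation of Gaussian noise added to
#'   `log(fc)`; 0 (default) gives exact model fold changes.
#' @param seed Seed for the noise stream; defaults to `params_1$seed`.
#' @return A tibble with columns `comparison`, `numerator`,
#'   `denominator`, `fc`.
#' @export
#' @examples
#' simulate_intensity_fc(study_params("mock"), study_params("uv"),
#'                       labels = c("mock", "uv"))
simulate_intensity_fc <- function(params_1, params_2,
                                  labels = c("mock", "uv"),
                                  log_noise_sd = 0,
                                  seed = NULL) {
  stopifnot(inherits(params_1, "simulation_params"),
            inherits(params_2, "simulation_params"),
            length(labels) == 2L)
  if (!is.numeric(log_noise_sd) || log_noise_sd < 0) {
    stop("`log_noise_sd` must be >= 0", call. = FALSE)
  }
  ss1 <- steady_state_abundance(params_1)
  ss2 <- steady_state_abundance(params_2)
  int <- function(ss, comp) ss$intensity[ss$compartment == comp]

  out <- tibble::tibble(
    comparison = c(
      paste0(labels[1], " UTR/ORF"),
      paste0(labels[2], " UTR/ORF"),
      paste0("UTR ", labels[2], "/", labels[1]),
      paste0("ORF ", labels[2], "/", labels[1])
    ),
    numerator = c(paste0(labels[1], ":UTR"), paste0(labels[2], ":UTR"),
                  paste0(labels[2], ":UTR"), paste0(labels[2], ":ORF")),
    denominator = c(paste0(labels[1], ":ORF"), paste0(labels[2], ":ORF"),
                    paste0(labels[1], ":UTR"), paste0(labels[1], ":ORF")),
    fc = c(
      int(ss1, "UTR") / int(ss1, "ORF"),
      int(ss2, "UTR") / int(ss2, "ORF"),
      int(ss2, "UTR") / int(ss1, "UTR"),
      int(ss2, "ORF") / int(ss1, "ORF")
    )
  )

  if (log_noise_sd > 0) {
    if (is.null(seed)) seed <- params_1$seed
    eps <- withr::with_seed(
      derive_seed(seed, 2L),
      stats::rnorm(nrow(out), 0, log_noise_sd)
    )
    out$fc <- out$fc * exp(eps)
  }
  out
}

#' Simulate an RNA sequence with planted cleavage signatures
#'
#' Builds a random RNA string whose background alphabet is {C, G} (so no
#' accidental +2U or -3/4A matches arise), then plants the AU-clamp
#' signature of an endonucleolytic site at each requested scissile bond
#' (A at the 3rd and 4th residues upstream, U at the 2nd residue
#' downstream) and optionally one uridine tract. Intended as a
#' ground-truth fixture for [scan_cleavage_sites()] and
#' [find_u_tracts()].
#'
#' @param length Sequence length in nt (>= 6).
#' @param site_positions Integer bond positions to plant; each bond `b`
#'   (between residues `b` and `b + 1`) must satisfy `4 <= b <= length - 2`
#'   so all signature residues fit.
#' @param u_tract `NULL` or `c(start, end)` (1-based inclusive) of a
#'   uridine tract to plant.
#' @param seed Integer RNG seed.
#' @return A list with elements `id`, `seq` (character string over
#'   A/C/G/U), `bonds` (planted bond positions) and `u_tract`.
#' @export
#' @examples
#' sim <- simulate_sequence_with_sites(50, site_positions = 20, seed = 1)
#' substr(sim$seq, 17, 22)
simulate_sequence_with_sites <- function(length, site_positions = integer(),
                                         u_tract = NULL, seed = 1L) {
  if (!is.numeric(length) || length < 6) {
    stop("`length` must be >= 6", call. = FALSE)
  }
  length <- as.integer(length)
  site_positions <- as.integer(site_positions)
  if (any(site_positions < 4L | site_positions > length - 2L)) {
    stop("planted bonds must lie in [4, length - 2]", call. = FALSE)
  }

  # residue -> demanded base; conflicts between plants are an error
  demand <- new.env(parent = emptyenv())
  ask <- function(pos, base) {
    key <- as.character(pos)
    prev <- if (!is.null(demand[[key]])) demand[[key]] else NA_character_
    if (!is.na(prev) && prev != base) {
      stop(sprintf(
        "contradictory plants: position %d demanded both %s and %s",
        pos, prev, base
      ), call. = FALSE)
    }
    demand[[key]] <- base
  }
  for (b in site_positions) {
    ask(b - 2L, "A")   # 3 nt upstream of the bond
    ask(b - 3L, "A")   # 4 nt upstream
    ask(b + 2L, "U")   # 2 nt downstream
  }
  if (!is.null(u_tract)) {
    if (length(u_tract) != 2L || u_tract[1] < 1 || u_tract[2] > length ||
        u_tract[1] > u_tract[2]) {
      stop("`u_tract` must be c(start, end) within the sequence",
           call. = FALSE)
    }
    for (pos in seq(u_tract[1], u_tract[2])) ask(as.integer(pos), "U")
    # guard tract maximality: flanks must not be forced to U
    for (pos in c(u_tract[1] - 1, u_tract[2] + 1)) {
      if (pos >= 1 && pos <= length) {
        key <- as.character(as.integer(pos))
        if (!is.null(demand[[key]]) && demand[[key]] == "U") {
          stop("u_tract flank collides with a planted U", call. = FALSE)
        }
      }
    }
  }

  residues <- withr::with_seed(
    derive_seed(seed, 3L),
    sample(c("C", "G"), length, replace = TRUE)
  )
  for (key in ls(demand)) {
    residues[as.integer(key)] <- demand[[key]]
  }

  list(
    id = "synthetic_rna",
    seq = paste(residues, collapse = ""),
    bonds = sort(site_positions),
    u_tract = if (is.null(u_tract)) NULL else as.integer(u_tract)
  )
}
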