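#' Parameters for a synthetic chase experiment
#'
#' Bundles the generative model behind a rifampicin-chase experiment on a
#' transcript with a long 5' UTR: a single promoter initiates `alpha`
#' transcripts per minute; a fraction `f_term` of RNA polymerases
#' terminates within the 5' UTR, so only `1 - f_term` of initiations
#' produce the full-length (ORF-containing) message; the UTR and ORF
#' segments decay first-order with constants `lambda_utr` and
#' `lambda_orf` (per minute). At transcription arrest (t = 0) abundance
#' of each segment decays as `exp(-lambda * t)`, observed by qPCR on the
#' Ct scale with additive Gaussian noise of `ct_noise_sd` cycles against
#' a stable reference gene (16S rRNA, simulated decay-free).
#'
#' Defaults are the mock (non-stressed) condition of the study system:
#' 95.9% premature termination, UTR half-life 3.1 min, ORF half-life
#' 7.2 min, chase timepoints 0/5/10/30 min, two probed regions per
#' compartment, three biological and three technical replicates, and
#' 0.15 cycles of Ct noise.
#'
#' @param alpha Transcription initiation rate, initiations/min (> 0).
#' @param f_term Fraction of initiations terminating within the 5' UTR,
#'   in \[0, 1).
#' @param lambda_utr,lambda_orf First-order decay constants (min^-1, > 0)
#'   of the UTR and ORF segments.
#' @param timepoints Chase times in minutes; sorted, first element 0.
#' @param n_regions Probed regions per compartment (positive integer).
#' @param n_bio_reps,n_tech_reps Biological / technical replicates.
#' @param ct_noise_sd Standard deviation of additive Ct noise (cycles,
#'   >= 0).
#' @param ref_ct_mean Mean Ct of the reference gene (cycles).
#' @param seed Integer RNG seed; all simulation randomness derives from
#'   it deterministically.
#' @return An object of class `simulation_params` (a validated list).
#' @seealso [study_params()] for the mock/UV presets,
#'   [simulate_chase()], [steady_state_abundance()].
#' @export
#' @examples
#' p <- simulation_params(seed = 1)
#' p$f_term
simulation_params <- function(alpha = 1,
                              f_term = 0.959,
                              lambda_utr = log(2) / 3.1,
                              lambda_orf = log(2) / 7.2,
                              timepoints = c(0, 5, 10, 30),
                              n_regions = 2L,
                              n_bio_reps = 3L,
                              n_tech_reps = 3L,
                              ct_noise_sd = 0.15,
                              ref_ct_mean = 12,
                              seed = 1L) {
  check_positive(alpha, "alpha")
  check_positive(lambda_utr, "lambda_utr")
  check_positive(lambda_orf, "lambda_orf")
  if (!is.numeric(f_term) || length(f_term) != 1L || !is.finite(f_term) ||
      f_term < 0 || f_term >= 1) {
    stop("`f_term` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(timepoints) || length(timepoints) < 1L ||
      any(!is.finite(timepoints)) || any(timepoints < 0)) {
    stop("`timepoints` must be non-negative and finite", call. = FALSE)
  }
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0) {
    stop("`timepoints` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  for (nm in c("n_regions", "n_bio_reps", "n_tech_reps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != as.integer(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (!is.numeric(ct_noise_sd) || length(ct_noise_sd) != 1L ||
      !is.finite(ct_noise_sd) || ct_noise_sd < 0) {
    stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(ref_ct_mean) || length(ref_ct_mean) != 1L ||
      !is.finite(ref_ct_mean)) {
    stop("`ref_ct_mean` must be finite", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }

  structure(
    list(
      alpha = alpha, f_term = f_term,
      lambda_utr = lambda_utr, lambda_orf = lambda_orf,
      timepoints = as.numeric(timepoints),
      n_regions = as.integer(n_regions),
      n_bio_reps = as.integer(n_bio_reps),
      n_tech_reps = as.integer(n_tech_reps),
      ct_noise_sd = ct_noise_sd,
      ref_ct_mean = ref_ct_mean,
      seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

#' Study-condition presets for the chase simulator
#'
#' Returns [simulation_params()] filled with the two experimental
#' conditions of the study system: `"mock"` (no UV stress; termination
#' fraction 0.959, half-lives 3.1 / 7.2 min for UTR / ORF) and `"uv"`
#' (2 h after UV-C; termination fraction 0.653, half-lives 17.1 /
#' 7.5 min). Under UV the transcription-initiation rate is reduced by
#' the factor 2.2 relative to mock.
#'
#' @param condition `"mock"` or `"uv"`.
#' @param seed Integer RNG seed.
#' @param ... Overrides passed on to [simulation_params()].
#' @return A `simulation_params` object.
#' @export
#' @examples
#' study_params("uv", seed = 7)$f_term  # 0.653
study_params <- function(condition = c("mock", "uv"), seed = 1L, ...) {
  condition <- match.arg(condition)
  if (condition == "mock") {
    simulation_params(
      alpha = 1, f_term = 0.959,
      lambda_utr = log(2) / 3.1, lambda_orf = log(2) / 7.2,
      seed = seed, ...
    )
  } else {
    simulation_params(
      alpha = 1 / 2.2, f_term = 0.653,
      lambda_utr = log(2) / 17.1, lambda_orf = log(2) / 7.5,
      seed = seed, ...
    )
  }
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("<simulation_params>\n")
  cat(sprintf("  alpha: %.4g /min, f_term: %.3f\n", x$alpha, x$f_term))
  cat(sprintf("  lambda (UTR, ORF): %.4g, %.4g /min  (t1/2 %.2f, %.2f min)\n",
              x$lambda_utr, x$lambda_orf,
              log(2) / x$lambda_utr, log(2) / x$lambda_orf))
  cat(sprintf("  timepoints: %s min\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  design: %d regions x %d bio x %d tech, ct_noise_sd %.3g\n",
              x$n_regions, x$n_bio_reps, x$n_tech_reps, x$ct_noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
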