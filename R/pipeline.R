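#' Default pipeline configuration
#'
#' A flat key-value list controlling [run_pipeline()]. Values supplied
#' via a YAML config file or the `config` argument override these
#' defaults (and command-line flags, when the bundled CLI wrapper is
#' used, override both).
#'
#' @return Named list of defaults: simulation design (`*_f_term`,
#'   `*_t12_utr`, `*_t12_orf` for the mock and uv conditions,
#'   `uv_alpha_factor` — the transcription-rate reduction under stress,
#'   `ct_noise_sd`, `timepoints`, replicate counts), analysis parameters
#'   (`reference_target`, `calibrator_time`, `n_boot`), scanning
#'   parameters (`min_len`, `max_gap`, optional `fasta` and `positions`
#'   input paths), `seed`, `out_dir` and `verbose`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    verbose = TRUE,
    # simulation design (study conditions)
    mock_f_term = 0.959, mock_t12_utr = 3.1, mock_t12_orf = 7.2,
    uv_f_term = 0.653, uv_t12_utr = 17.1, uv_t12_orf = 7.5,
    uv_alpha_factor = 1 / 2.2,
    timepoints = c(0, 5, 10, 30),
    n_regions = 2L, n_bio_reps = 3L, n_tech_reps = 3L,
    ct_noise_sd = 0.15,
    ref_ct_mean = 12,
    # quantification / fitting
    reference_target = "16S",
    calibrator_time = 0,
    n_boot = 1000L,
    # scanning / clustering
    min_len = 6L, max_gap = 10L,
    fasta = NULL, positions = NULL
  )
}

#' Read a pipeline configuration file
#'
#' Flat key-value YAML; unknown keys are an error so typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list merged over [default_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(cfg)
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(config)] <- config
  base
}

stage_msg <- function(verbose, stage, ...) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order
#' `simulate -> quantify -> fit -> model -> scan -> cluster`, reading
#' and writing the package's CSV/TSV/BED/JSON formats under
#' `config$out_dir`. Every artifact is accompanied by a provenance
#' sidecar (stage, parameters, seed, input hashes). Later stages consume
#' the files earlier stages wrote, so the pipeline can be resumed from
#' any stage whose inputs exist on disk.
#'
#' Stages:
#' \describe{
#'   \item{simulate}{Chase Ct tables for the mock and uv conditions plus
#'     steady-state intensity fold changes (`qpcr.csv`,
#'     `intensity.csv`).}
#'   \item{quantify}{Delta-delta-Ct relative quantities (`rq.csv`).}
#'   \item{fit}{Pooled exponential fits per condition x compartment with
#'     bootstrap CIs (`fits.csv`).}
#'   \item{model}{Synthesis-rate / termination report from the fitted
#'     decay constants and the intensity fold changes (`table1.tsv`,
#'     `report.json`).}
#'   \item{scan}{If `config$fasta` is set: cleavage-site calls
#'     (`sites.bed`) and U-tracts (`utracts.csv`).}
#'   \item{cluster}{If `config$positions` is set: clustered 3'-end
#'     regions (`clusters.csv`).}
#' }
#'
#' @param config Named list of overrides, a path to a YAML config file,
#'   or `NULL` for [default_config()].
#' @param stages Character vector of stages to run (default: the first
#'   four core stages plus any of scan/cluster whose inputs are
#'   configured).
#' @return Invisibly, a named list of artifact paths.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(out_dir = tempfile(), n_boot = 50L))
#' }
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "quantify", "fit",
                                    "model", "scan", "cluster")) {
  cfg <- if (is.character(config)) {
    read_pipeline_config(config)
  } else {
    merge_config(config)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)
  artifacts <- list()

  sim_params <- function(cond) {
    simulation_params(
      alpha = if (cond == "mock") 1 else cfg$uv_alpha_factor,
      f_term = cfg[[paste0(cond, "_f_term")]],
      lambda_utr = log(2) / cfg[[paste0(cond, "_t12_utr")]],
      lambda_orf = log(2) / cfg[[paste0(cond, "_t12_orf")]],
      timepoints = cfg$timepoints,
      n_regions = cfg$n_regions, n_bio_reps = cfg$n_bio_reps,
      n_tech_reps = cfg$n_tech_reps,
      ct_noise_sd = cfg$ct_noise_sd, ref_ct_mean = cfg$ref_ct_mean,
      seed = derive_seed(cfg$seed, if (cond == "mock") 11L else 12L)
    )
  }

  if ("simulate" %in% stages) {
    stage_msg(cfg$verbose, "simulate",
              "chase design %d regions x %d bio x %d tech, sd %.3g",
              cfg$n_regions, cfg$n_bio_reps, cfg$n_tech_reps,
              cfg$ct_noise_sd)
    ct <- dplyr::bind_rows(
      simulate_chase(sim_params("mock"), condition = "mock",
                     reference_target = cfg$reference_target),
      simulate_chase(sim_params("uv"), condition = "uv",
                     reference_target = cfg$reference_target)
    )
    write_qpcr_csv(ct, path("qpcr.csv"))
    write_provenance(path("qpcr.csv"), "simulate",
                     params = cfg[grepl("^(mock|uv)_|^n_|^ct_|^ref_",
                                        names(cfg))],
                     seed = cfg$seed)
    fcs <- simulate_intensity_fc(sim_params("mock"), sim_params("uv"),
                                 labels = c("mock", "uv"))
    write_intensity_csv(fcs, path("intensity.csv"))
    write_provenance(path("intensity.csv"), "simulate", seed = cfg$seed)
    artifacts$qpcr <- path("qpcr.csv")
    artifacts$intensity <- path("intensity.csv")
  }

  if ("quantify" %in% stages) {
    ct <- read_qpcr_csv(path("qpcr.csv"))
    rq <- delta_delta_ct(ct, reference_target = cfg$reference_target,
                         calibrator_time = cfg$calibrator_time)
    stage_msg(cfg$verbose, "quantify", "%d relative quantities", nrow(rq))
    write_rq_csv(rq, path("rq.csv"))
    write_provenance(path("rq.csv"), "quantify",
                     params = list(reference_target = cfg$reference_target,
                                   calibrator_time = cfg$calibrator_time),
                     inputs = path("qpcr.csv"))
    artifacts$rq <- path("rq.csv")
  }

  if ("fit" %in% stages) {
    rq <- read_rq_csv(path("rq.csv"))
    fits <- fit_decay(rq, n_boot = cfg$n_boot, seed = cfg$seed)
    stage_msg(cfg$verbose, "fit", "half-lives: %s min",
              paste(sprintf("%s/%s %.2f", fits$condition,
                            fits$compartment, fits$half_life),
                    collapse = ", "))
    write_fits_csv(fits, path("fits.csv"))
    write_provenance(path("fits.csv"), "fit",
                     params = list(n_boot = cfg$n_boot),
                     seed = cfg$seed, inputs = path("rq.csv"))
    artifacts$fits <- path("fits.csv")
  }

  if ("model" %in% stages) {
    fits <- read_fits_csv(path("fits.csv"))
    fcs <- read_intensity_csv(path("intensity.csv"))
    lam <- function(cond, comp) {
      v <- fits$lambda[fits$condition == cond & fits$compartment == comp]
      if (length(v) != 1L) {
        stop(sprintf("model stage: no unique fit for %s/%s", cond, comp),
             call. = FALSE)
      }
      v
    }
    fc <- function(cmp) {
      v <- fcs$fc[fcs$comparison == cmp]
      if (length(v) != 1L) {
        stop(sprintf("model stage: missing intensity FC '%s'", cmp),
             call. = FALSE)
      }
      v
    }
    report <- table1_report(
      fc_int_mock = fc("mock UTR/ORF"),
      fc_int_uv = fc("uv UTR/ORF"),
      fc_int_utr_uvmock = fc("UTR uv/mock"),
      fc_decay_mock = lam("mock", "UTR") / lam("mock", "ORF"),
      fc_decay_uv = lam("uv", "UTR") / lam("uv", "ORF"),
      fc_decay_utr_uvmock = lam("uv", "UTR") / lam("mock", "UTR")
    )
    stage_msg(cfg$verbose, "model", "termination: %s (mock), %s (uv)",
              report$termination_label[1], report$termination_label[2])
    utils::write.table(format_table1(report), path("table1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, na = "null")
    for (f in c("table1.tsv", "report.json")) {
      write_provenance(path(f), "model",
                       inputs = c(path("fits.csv"), path("intensity.csv")))
    }
    artifacts$table1 <- path("table1.tsv")
    artifacts$report <- path("report.json")
  }

  if ("scan" %in% stages && !is.null(cfg$fasta)) {
    seqs <- read_rna_fasta(cfg$fasta)
    sites <- purrr::map2(seqs$seq, seqs$id, scan_cleavage_sites) |>
      dplyr::bind_rows()
    tracts <- purrr::map2(seqs$seq, seqs$id, function(s, i) {
      find_u_tracts(s, min_len = cfg$min_len, id = i)
    }) |>
      dplyr::bind_rows()
    stage_msg(cfg$verbose, "scan", "%d site calls, %d U-tract(s)",
              nrow(sites), nrow(tracts))
    write_site_bed(sites, path("sites.bed"))
    readr::write_csv(tracts, path("utracts.csv"), na = "")
    write_provenance(path("sites.bed"), "scan",
                     params = list(min_len = cfg$min_len),
                     inputs = cfg$fasta)
    artifacts$sites <- path("sites.bed")
    artifacts$utracts <- path("utracts.csv")
  }

  if ("cluster" %in% stages && !is.null(cfg$positions)) {
    pos <- read_positions(cfg$positions)
    clusters <- cluster_end_positions(pos, max_gap = cfg$max_gap)
    stage_msg(cfg$verbose, "cluster", "%d cluster(s)", nrow(clusters))
    readr::write_csv(clusters, path("clusters.csv"), na = "")
    write_provenance(path("clusters.csv"), "cluster",
                     params = list(max_gap = cfg$max_gap),
                     inputs = cfg$positions)
    artifacts$clusters <- path("clusters.csv")
  }

  invisible(artifacts)
}
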