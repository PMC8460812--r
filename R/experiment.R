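#' Configuration for the end-to-end stability experiment
#'
#' Bundles every knob of [run_experiment()]: the scenario (ploidy, per-plasmid
#' copy number and carriage), library sizes for the bulk culture and for each
#' clonal colony, the analysis window, and the test parameters. The default
#' scenario is the polyploid hypothesis on the full MSH1 registry genome:
#' ploidy 2, every plasmid at one copy per carrying cell and full carriage, a
#' 100,000-pair bulk library and a 14-colony panel.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory (created if needed).
#' @param genome optional `genome_model` with sequences; when `NULL`, random
#'   sequences are simulated for `registry`.
#' @param registry registry used when `genome` is `NULL`.
#' @param ploidy,plasmid_copy,carriage,shared_loss_prob see
#'   [population_model()].
#' @param n_colonies colonies in the panel (default 14).
#' @param bulk_pairs read pairs for the bulk library (default 100000).
#' @param colony_pairs read pairs per colony library (default 5000).
#' @param window_bp analysis window (default 1000).
#' @param epsilon,alpha see [test_stability()].
#' @param read_length,fragment_mean,fragment_sd,substitution_rate see
#'   [read_pair_spec()].
#' @param presence_normcov_min a plasmid is scored present in a colony when
#'   its colony-library NormCov reaches this floor (default 0.05).
#' @param bootstrap_reps bootstrap replicates for copy-number intervals.
#' @param write_fastq,write_sam_file also write the bulk FASTQ pair / SAM.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, out_dir = tempfile("normcov_run"),
                              genome = NULL, registry = msh1_registry(),
                              ploidy = 2, plasmid_copy = 1, carriage = 1,
                              shared_loss_prob = 0, n_colonies = 14L,
                              bulk_pairs = 100000L, colony_pairs = 5000L,
                              window_bp = 1000L, epsilon = 0.02, alpha = 0.05,
                              read_length = 151L, fragment_mean = 400L,
                              fragment_sd = 40L, substitution_rate = 0,
                              presence_normcov_min = 0.05,
                              bootstrap_reps = 1000L,
                              write_fastq = FALSE, write_sam_file = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

config_md5 <- function(config) {
  cfg <- config[setdiff(names(config),
                        c("genome", "registry", "out_dir",
                          "write_fastq", "write_sam_file"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full plasmid-stability experiment on simulated data
#'
#' Reproduces, on synthetic data, the design of a plasmid-stability
#' experiment: sequence a bulk culture, compute windowed depth and NormCov,
#' estimate per-replicon copy number, then pick `n_colonies` clonal colonies,
#' sequence each, score plasmid presence/absence, and run the exact binomial
#' test separating chromosome polyploidy from unstable inheritance.
#'
#' Stages: simulate genome (if needed) -> simulate bulk reads -> windowed
#' depth -> NormCov -> copy-number estimates -> colony panel (founders +
#' per-colony libraries, presence scored from colony NormCov) -> per-plasmid
#' stability tests. All outputs are TSV/JSON with provenance headers and are
#' byte-identical for a fixed seed.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a list with `genome`, `model`, `bulk` (sim), `coverage`,
#'   `normcov`, `estimates`, `panel`, `report`, `paths`, `seed`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  md5 <- config_md5(config)
  prov <- sprintf("# config_md5=%s", md5)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  genome <- stage("simulate-genome", {
    config$genome %||% simulate_genome(config$registry,
                                       seed = derive_seed(seed, 1L))
  })
  model <- stage("population", {
    population_model(genome, ploidy = config$ploidy,
                     plasmid_copy = config$plasmid_copy,
                     carriage = config$carriage,
                     shared_loss_prob = config$shared_loss_prob)
  })

  bulk <- stage("simulate-reads", {
    simulate_reads(model, read_pair_spec(
      config$bulk_pairs, read_length = config$read_length,
      fragment_mean = config$fragment_mean, fragment_sd = config$fragment_sd,
      substitution_rate = config$substitution_rate,
      seed = derive_seed(seed, 2L)))
  })
  if (isTRUE(config$write_fastq)) {
    write_fastq_pair(bulk, p("bulk"))
  }
  if (isTRUE(config$write_sam_file)) {
    write_sam(bulk$alignments, p("bulk.sam"))
  }

  cov <- stage("coverage", windowed_depth(bulk$alignments, config$window_bp))
  nct <- stage("normcov", normcov(cov, chromosome = genome$chromosome))
  est <- stage("infer-cn", {
    copy_number_summary(nct, bootstrap_reps = config$bootstrap_reps,
                        seed = derive_seed(seed, 3L))
  })
  write_track_tsv(nct, p("normcov_windows.tsv"), seed = seed)
  write_tsv_provenance(est, p("copy_number.tsv"), seed = seed, extra = prov)

  panel <- stage("colony-panel", {
    pl <- plasmid_names(genome)
    pres <- matrix(FALSE, nrow = config$n_colonies, ncol = length(pl),
                   dimnames = list(NULL, pl))
    for (i in seq_len(config$n_colonies)) {
      fnd <- sample_founder(model, seed = derive_seed(seed, 100L + i))
      csim <- simulate_reads(model, read_pair_spec(
        config$colony_pairs, read_length = config$read_length,
        fragment_mean = config$fragment_mean,
        fragment_sd = config$fragment_sd,
        substitution_rate = config$substitution_rate,
        seed = derive_seed(seed, 200L + i)), founder = fnd)
      cn <- normcov(windowed_depth(csim$alignments, config$window_bp),
                    chromosome = genome$chromosome)
      cest <- copy_number_summary(cn, bootstrap_reps = 0L)
      pres[i, ] <- cest$normcov_mean[match(pl, cest$replicon)] >=
        config$presence_normcov_min
    }
    colony_panel(pres)
  })
  write_panel_tsv(panel, p("colony_panel.tsv"), seed = seed)

  report <- stage("colony-test", {
    stability_report(est, panel, epsilon = config$epsilon,
                     alpha = config$alpha)
  })
  write_stability_report(report, p("stability_tests.tsv"),
                         p("stability_report.json"), seed = seed)

  invisible(list(genome = genome, model = model, bulk = bulk, coverage = cov,
                 normcov = nct, estimates = est, panel = panel,
                 report = report, seed = seed, config_md5 = md5,
                 paths = c(normcov = p("normcov_windows.tsv"),
                           copy_number = p("copy_number.tsv"),
                           panel = p("colony_panel.tsv"),
                           tests = p("stability_tests.tsv"),
                           report = p("stability_report.json"))))
}
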