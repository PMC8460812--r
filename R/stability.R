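#' Expected colony losses under plasmid instability
#'
#' Under the instability hypothesis a plasmid with carriage fraction `c` is
#' absent from a random clonal colony with probability `1 - c`. Returns the
#' expected number of colonies lacking each plasmid and, assuming independent
#' loss across plasmids, the expected number of colonies lacking at least one
#' plasmid.
#'
#' @param carriage named numeric vector of carriage fractions in `[0, 1]`.
#' @param n number of colonies (>= 1).
#' @return List with `per_plasmid` (named, `n * (1 - c)`) and `any_loss`
#'   (`n * (1 - prod(c))`).
#' @export
expected_losses <- function(carriage, n) {
  stopifnot(is.numeric(carriage), all(carriage >= 0 & carriage <= 1), n >= 1)
  list(per_plasmid = n * (1 - carriage),
       any_loss = n * (1 - prod(carriage)))
}

#' Exact binomial test separating polyploidy from plasmid instability
#'
#' A plasmid with bulk NormCov below 1 is ambiguous: either only a fraction
#' `c_hat = min(NormCov, 1)` of cells carry it (instability) or the chromosome
#' is present in multiple copies per cell (polyploidy). Among `n` clonal
#' colonies the instability hypothesis predicts `X ~ Binomial(n, 1 - c_hat)`
#' colonies lacking the plasmid; under polyploidy losses occur only at a small
#' background rate `epsilon`. The test reports the exact lower tail
#' `p_value_loss = P(X <= k | X ~ Binomial(n, 1 - c_hat))` (few losses
#' contradict instability; the tail is computed by direct summation of
#' binomial point masses) and the log10 likelihood ratio
#' `log_lr = log10 Binom(k; n, epsilon) / Binom(k; n, 1 - c_hat)`.
#'
#' Verdict: `polyploidy_supported` iff `p_value_loss < alpha` and
#' `log_lr > 0`; `instability_supported` iff `p_value_loss >= alpha` and
#' `log_lr < 0`; otherwise `inconclusive`.
#'
#' @param bulk bulk-culture NormCov of the plasmid: a single number or a
#'   [estimate_copy_number()] result. Values above 1 are capped at 1 with a
#'   warning (instability cannot explain NormCov > 1).
#' @param n number of colonies in the panel (>= 1).
#' @param k number of colonies lacking the plasmid (0 <= k <= n).
#' @param epsilon background loss probability under polyploidy (default 0.02).
#' @param alpha significance level (default 0.05).
#' @param plasmid optional plasmid name for the report.
#' @return Object of class `stability_test`: list with `plasmid`, `c_hat`,
#'   `n`, `k`, `epsilon`, `alpha`, `p_value_loss`, `log_lr`, `verdict`.
#' @export
test_stability <- function(bulk, n, k, epsilon = 0.02, alpha = 0.05,
                           plasmid = NULL) {
  if (inherits(bulk, "copy_number_estimate")) {
    plasmid <- plasmid %||% bulk$replicon
    bulk <- bulk$normcov_mean
  }
  stopifnot(is.numeric(bulk), length(bulk) == 1L, bulk > 0,
            n >= 1, k >= 0, k <= n,
            epsilon >= 0, epsilon <= 1, alpha > 0, alpha < 1)
  n <- as.integer(n); k <- as.integer(k)
  if (bulk > 1) {
    warning("bulk NormCov ", format(bulk), " > 1: carriage capped at 1 ",
            "(instability cannot explain NormCov above 1)")
  }
  c_hat <- min(bulk, 1)
  p_loss <- 1 - c_hat
  p_value <- sum(stats::dbinom(0:k, n, p_loss))
  p_value <- min(p_value, 1)  # guard summation rounding
  log_lr <- (stats::dbinom(k, n, epsilon, log = TRUE) -
               stats::dbinom(k, n, p_loss, log = TRUE)) / log(10)
  verdict <- if (p_value < alpha && log_lr > 0) {
    "polyploidy_supported"
  } else if (p_value >= alpha && log_lr < 0) {
    "instability_supported"
  } else {
    "inconclusive"
  }
  structure(
    list(plasmid = plasmid %||% NA_character_, c_hat = c_hat, n = n, k = k,
         epsilon = epsilon, alpha = alpha, p_value_loss = p_value,
         log_lr = log_lr, verdict = verdict),
    class = "stability_test"
  )
}

#' @export
print.stability_test <- function(x, ...) {
  cat(sprintf(
    "<stability_test> %s: c_hat=%.3f, k=%d/%d, p=%.3g, log10 LR=%.2f -> %s\n",
    x$plasmid, x$c_hat, x$k, x$n, x$p_value_loss, x$log_lr, x$verdict))
  invisible(x)
}

#' Per-plasmid stability report for a colony panel
#'
#' Runs [test_stability()] for every plasmid, pairing each bulk NormCov
#' estimate with the panel's loss count, and adds an epsilon sensitivity
#' sweep of the verdicts.
#'
#' @param estimates data frame from [copy_number_summary()] (bulk culture).
#' @param panel a [colony_panel()].
#' @param epsilon,alpha see [test_stability()].
#' @param eps_grid epsilon values for the sensitivity sweep.
#' @return List of class `stability_report`: `tests` (data frame, one row per
#'   plasmid), `sensitivity` (long data frame plasmid x epsilon -> verdict),
#'   `epsilon`, `alpha`.
#' @export
stability_report <- function(estimates, panel, epsilon = 0.02, alpha = 0.05,
                             eps_grid = c(0.005, 0.01, 0.02, 0.05, 0.1)) {
  stopifnot(inherits(panel, "colony_panel"))
  pl <- intersect(panel$plasmids, estimates$replicon)
  if (length(pl) == 0L) stop("panel plasmids not found among the estimates")
  one <- function(nm, eps) {
    b <- estimates$normcov_mean[estimates$replicon == nm]
    suppressWarnings(
      test_stability(b, panel$n, panel$losses[[nm]], epsilon = eps,
                     alpha = alpha, plasmid = nm))
  }
  tests <- do.call(rbind, lapply(pl, function(nm) {
    t <- one(nm, epsilon)
    data.frame(plasmid = nm, bulk_normcov = t$c_hat, c_hat = t$c_hat,
               n = t$n, k = t$k, epsilon = t$epsilon,
               p_value_loss = t$p_value_loss, log_lr = t$log_lr,
               verdict = t$verdict, stringsAsFactors = FALSE)
  }))
  tests$bulk_normcov <-
    estimates$normcov_mean[match(tests$plasmid, estimates$replicon)]
  sens <- do.call(rbind, lapply(pl, function(nm) {
    data.frame(plasmid = nm, epsilon = eps_grid,
               verdict = vapply(eps_grid, function(e) one(nm, e)$verdict, ""),
               stringsAsFactors = FALSE)
  }))
  structure(list(tests = tests, sensitivity = sens, epsilon = epsilon,
                 alpha = alpha),
            class = "stability_report")
}

#' Write a stability report as TSV + JSON
#' @param report a `stability_report`.
#' @param tsv_path per-plasmid test table (TSV).
#' @param json_path verdicts + sensitivity sweep (JSON).
#' @param seed optional seed recorded in the TSV provenance header.
#' @return Invisibly, the two paths.
#' @export
write_stability_report <- function(report, tsv_path, json_path, seed = NULL) {
  write_tsv_provenance(report$tests, tsv_path, seed = seed)
  jsonlite::write_json(
    list(seed = seed, epsilon = report$epsilon, alpha = report$alpha,
         verdicts = stats::setNames(as.list(report$tests$verdict),
                                    report$tests$plasmid),
         tests = report$tests, sensitivity = report$sensitivity),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
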