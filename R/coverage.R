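#' Windowed read depth per replicon
#'
#' Accumulates per-base depth from every aligned base of every record (both
#' mates counted independently by default) and reports the mean depth in
#' fixed-width tiling windows (0-based half-open; the trailing partial window
#' uses its actual width, so window means are unbiased per-base means).
#'
#' @param aln an [alignment_set()] (e.g. from [simulate_reads()] or
#'   [read_sam()]).
#' @param window_bp window width in bp (default 1000).
#' @param double_count count overlapping mate pairs twice (`TRUE`, the default
#'   behaviour of standard depth tooling) or subtract the mate overlap so each
#'   fragment base counts once (`FALSE`).
#' @return Data frame of class `coverage_track` with columns `replicon`,
#'   `start`, `end`, `mean_depth`; attributes `window_bp` and `lengths`.
#'   Replicons without reads appear with all-zero windows.
#' @export
windowed_depth <- function(aln, window_bp = 1000L, double_count = TRUE) {
  stopifnot(inherits(aln, "alignment_set"), window_bp >= 1)
  window_bp <- as.integer(window_bp)
  lens <- attr(aln, "lengths")
  wdt <- if (nrow(aln) > 0L) cigar_ref_len(aln$cigar) else integer()
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    r <- names(lens)[i]
    L <- lens[[i]]
    sel <- which(aln$replicon == r)
    cvg <- IRanges::coverage(
      IRanges::IRanges(start = aln$start[sel] + 1L, width = wdt[sel]),
      width = L)
    if (!double_count && length(sel) > 1L) {
      cvg <- cvg - mate_overlap_coverage(aln[sel, , drop = FALSE],
                                         wdt[sel], L)
    }
    starts <- seq.int(1L, L, by = window_bp)
    ends <- pmin(starts + window_bp - 1L, L)
    mu <- IRanges::viewMeans(IRanges::Views(cvg, starts, ends))
    out[[i]] <- data.frame(replicon = r, start = starts - 1L, end = ends,
                           mean_depth = as.numeric(mu),
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), window_bp = window_bp, lengths = lens,
            class = c("coverage_track", "data.frame"))
}

# Coverage contributed a second time by mate-pair overlap on one replicon.
mate_overlap_coverage <- function(rec, wdt, L) {
  s <- rec$start + 1L
  e <- rec$start + wdt
  grp <- split(seq_len(nrow(rec)), rec$read_id)
  grp <- grp[lengths(grp) == 2L]
  if (length(grp) == 0L) return(IRanges::coverage(IRanges::IRanges(), width = L))
  i1 <- vapply(grp, `[[`, 0L, 1L)
  i2 <- vapply(grp, `[[`, 0L, 2L)
  os <- pmax(s[i1], s[i2])
  oe <- pmin(e[i1], e[i2])
  keep <- oe >= os
  IRanges::coverage(IRanges::IRanges(start = os[keep], end = oe[keep]),
                    width = L)
}

#' Chromosome-normalized coverage (NormCov)
#'
#' Divides every window's mean depth by the chromosome mean depth
#' `mu_chr = total aligned bases on the chromosome / chromosome length`
#' (the per-base mean over the whole chromosome, identical to the
#' width-weighted mean of its window means). A NormCov of 1 means one replicon
#' copy per chromosome copy.
#'
#' @param track a `coverage_track` from [windowed_depth()].
#' @param chromosome chromosome replicon name (default: longest replicon in
#'   the track header).
#' @return Data frame of class `normcov_track`: the track plus a `normcov`
#'   column; attributes `mu_chr` and `chromosome`.
#' @export
normcov <- function(track, chromosome = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  lens <- attr(track, "lengths")
  chromosome <- chromosome %||% names(lens)[which.max(lens)]
  if (!chromosome %in% track$replicon) {
    stop("chromosome '", chromosome, "' not present in the coverage track")
  }
  chr <- track[track$replicon == chromosome, , drop = FALSE]
  wdt <- chr$end - chr$start
  mu_chr <- sum(chr$mean_depth * wdt) / lens[[chromosome]]
  if (mu_chr == 0) stop("chromosome mean depth is zero; NormCov undefined")
  out <- track
  out$normcov <- out$mean_depth / mu_chr
  structure(out, window_bp = attr(track, "window_bp"), lengths = lens,
            mu_chr = mu_chr, chromosome = chromosome,
            class = c("normcov_track", "coverage_track", "data.frame"))
}

#' Replicon copy-number estimate from a NormCov track
#'
#' The point estimate is the window-width-weighted mean NormCov of the
#' replicon (equal to its total-depth ratio against the chromosome); the
#' median is reported for robustness. The 95% interval is a percentile
#' bootstrap over windows.
#'
#' @param nct a `normcov_track`.
#' @param replicon replicon name.
#' @param bootstrap_reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `copy_number_estimate`: list with `replicon`,
#'   `normcov_mean`, `normcov_median`, `ci95` (low, high), `n_windows`.
#' @export
estimate_copy_number <- function(nct, replicon, bootstrap_reps = 1000L,
                                 seed = NULL) {
  stopifnot(inherits(nct, "normcov_track"))
  rows <- nct[nct$replicon == replicon, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no windows for replicon '", replicon, "'")
  w <- rows$end - rows$start
  nc <- rows$normcov
  est <- sum(nc * w) / sum(w)
  nw <- length(nc)
  ci <- if (bootstrap_reps > 0L) {
    boot <- with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(b) {
        i <- sample.int(nw, nw, replace = TRUE)
        sum(nc[i] * w[i]) / sum(w[i])
      }, numeric(1))
    })
    unname(stats::quantile(boot, c(0.025, 0.975)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(replicon = replicon, normcov_mean = est,
         normcov_median = stats::median(nc), ci95 = ci, n_windows = nw),
    class = "copy_number_estimate"
  )
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy_number_estimate> %s: NormCov mean %.4f (median %.4f), 95%% CI [%.4f, %.4f], %d windows\n",
    x$replicon, x$normcov_mean, x$normcov_median, x$ci95[1], x$ci95[2],
    x$n_windows))
  invisible(x)
}

#' Copy-number summary for every replicon of a NormCov track
#'
#' @inheritParams estimate_copy_number
#' @return Data frame with one row per replicon: `replicon`, `normcov_mean`,
#'   `normcov_median`, `ci_low`, `ci_high`, `n_windows`.
#' @export
copy_number_summary <- function(nct, bootstrap_reps = 1000L, seed = NULL) {
  reps <- unique(nct$replicon)
  do.call(rbind, lapply(seq_along(reps), function(i) {
    e <- estimate_copy_number(nct, reps[i], bootstrap_reps = bootstrap_reps,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, i))
    data.frame(replicon = e$replicon, normcov_mean = e$normcov_mean,
               normcov_median = e$normcov_median, ci_low = e$ci95[1],
               ci_high = e$ci95[2], n_windows = e$n_windows,
               stringsAsFactors = FALSE)
  }))
}

#' Write a coverage or NormCov track as BED-like TSV
#' @param track a `coverage_track` or `normcov_track`.
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path, seed = NULL) {
  extra <- sprintf("# window_bp=%d", attr(track, "window_bp"))
  if (!is.null(attr(track, "mu_chr"))) {
    extra <- c(extra, sprintf("# mu_chr=%.10g chromosome=%s",
                              attr(track, "mu_chr"), attr(track, "chromosome")))
  }
  write_tsv_provenance(as.data.frame(track), path, seed = seed, extra = extra)
}
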