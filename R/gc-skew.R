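#' GC and GC-skew track for a replicon
#'
#' Tiles the replicon with fixed-width windows (0-based, half-open; the last
#' window may be partial; circular replicons do not wrap) and reports, per
#' window, the GC fraction and the GC skew `(G - C) / (G + C)`. Windows with
#' `G + C == 0` report a skew of 0. `N` bases are excluded from the GC
#' numerator and denominator.
#'
#' @param rep a [replicon()] carrying a sequence.
#' @param window_bp window width in bp (>= 1).
#' @return A data frame of class `gc_skew_track` with columns `replicon`,
#'   `start`, `end`, `gc_fraction`, `skew`; attribute `window_bp`.
#' @export
gc_skew_track <- function(rep, window_bp) {
  stopifnot(inherits(rep, "replicon"))
  if (is.null(rep$sequence)) stop("replicon '", rep$name, "' has no sequence")
  stopifnot(window_bp >= 1)
  dna <- Biostrings::DNAString(rep$sequence)
  L <- length(dna)
  starts <- seq.int(1L, L, by = as.integer(window_bp))
  ends <- pmin(starts + as.integer(window_bp) - 1L, L)
  lf <- Biostrings::letterFrequency(Biostrings::Views(dna, starts, ends),
                                    c("A", "C", "G", "T"))
  g <- lf[, "G"]; cc <- lf[, "C"]
  valid <- rowSums(lf)
  out <- data.frame(
    replicon = rep$name,
    start = starts - 1L,
    end = ends,
    gc_fraction = ifelse(valid > 0, (g + cc) / valid, 0),
    skew = ifelse(g + cc > 0, (g - cc) / (g + cc), 0),
    stringsAsFactors = FALSE
  )
  structure(out, window_bp = as.integer(window_bp),
            class = c("gc_skew_track", "data.frame"))
}

#' Write a GC-skew track as BED-like TSV
#' @param track a `gc_skew_track`.
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_gc_skew_tsv <- function(track, path, seed = NULL) {
  write_tsv_provenance(as.data.frame(track), path, seed = seed,
                       extra = sprintf("# window_bp=%d", attr(track, "window_bp")))
}
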