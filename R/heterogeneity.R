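#' Per-position base counts (pileup) from an alignment set
#'
#' Tallies A/C/G/T counts at every covered reference position from the
#' forward-strand aligned sequences (M/=/X columns only; `N` read bases are
#' skipped and excluded from depth). Positions with no coverage are absent
#' from the result.
#'
#' @param aln an [alignment_set()] whose records carry sequences.
#' @param genome a [genome_model()] with sequences (supplies the reference
#'   base).
#' @return Data frame of class `pileup` with columns `replicon`, `pos`
#'   (0-based), `ref`, `A`, `C`, `G`, `T`, `depth`.
#' @export
build_pileup <- function(aln, genome) {
  stopifnot(inherits(aln, "alignment_set"), inherits(genome, "genome_model"))
  wdt <- if (nrow(aln) > 0L) cigar_ref_len(aln$cigar) else integer()
  if (any(nchar(aln$seq) != wdt)) {
    stop("alignment sequence length inconsistent with CIGAR")
  }
  out <- list()
  for (r in unique(aln$replicon)) {
    ref <- genome$replicons[[r]]$sequence
    if (is.null(ref)) stop("replicon '", r, "' has no reference sequence")
    sel <- which(aln$replicon == r)
    L <- genome$replicons[[r]]$length_bp
    lens <- wdt[sel]
    pos0 <- rep.int(aln$start[sel], lens) +
      (sequence(lens) - 1L)  # 0-based reference positions
    base <- unlist(strsplit(aln$seq[sel], "", fixed = TRUE), use.names = FALSE)
    bi <- match(base, DNA_BASES)  # NA for N
    keep <- !is.na(bi)
    cnt <- tabulate(pos0[keep] * 4L + bi[keep], nbins = 4L * L)
    m <- matrix(cnt, nrow = 4L)
    depth <- as.integer(colSums(m))
    covered <- which(depth > 0)
    if (length(covered) == 0L) next
    out[[r]] <- data.frame(
      replicon = r, pos = covered - 1L,
      ref = substring(ref, covered, covered),
      A = m[1L, covered], C = m[2L, covered],
      G = m[3L, covered], T = m[4L, covered],
      depth = depth[covered], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(), pos = integer(), ref = character(),
               A = integer(), C = integer(), G = integer(), T = integer(),
               depth = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("pileup", "data.frame"))
}

#' Call variants from a pileup at an allele-fraction cutoff
#'
#' A site/allele is called when the non-reference base is supported by at
#' least `threshold` of the (non-N) depth — the 35% consensus cutoff of
#' CLC-style variant screening, with an inclusive boundary — and the depth is
#' at least `min_depth`. Multiple alternate alleles at one site are evaluated
#' independently. Indels are out of scope (alignments are M-only).
#'
#' @param pileup a [build_pileup()] result.
#' @param threshold minimum alternate-allele fraction (default 0.35).
#' @param min_depth minimum site depth (default 10).
#' @param sample sample label attached to the calls.
#' @return Data frame of class `variant_calls`: `replicon`, `pos` (0-based),
#'   `ref`, `alt`, `alt_count`, `depth`, `alt_fraction`, `sample`.
#' @export
call_variants <- function(pileup, threshold = 0.35, min_depth = 10L,
                          sample = "sample") {
  stopifnot(threshold > 0, threshold <= 1, min_depth >= 0)
  calls <- list()
  for (b in DNA_BASES) {
    cnt <- pileup[[b]]
    hit <- which(pileup$ref != b & pileup$depth >= min_depth &
                   cnt / pileup$depth >= threshold)
    if (length(hit)) {
      calls[[b]] <- data.frame(
        replicon = pileup$replicon[hit], pos = pileup$pos[hit],
        ref = pileup$ref[hit], alt = b, alt_count = cnt[hit],
        depth = pileup$depth[hit],
        alt_fraction = cnt[hit] / pileup$depth[hit],
        sample = sample, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(calls)) do.call(rbind, calls) else
    data.frame(replicon = character(), pos = integer(), ref = character(),
               alt = character(), alt_count = integer(), depth = integer(),
               alt_fraction = numeric(), sample = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$replicon, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, threshold = threshold, min_depth = as.integer(min_depth),
            class = c("variant_calls", "data.frame"))
}

# Alternate-allele fraction of one site in a pileup; NA when uncovered.
alt_fraction_at <- function(pileup, replicon, pos, alt) {
  i <- which(pileup$replicon == replicon & pileup$pos == pos)
  if (length(i) == 0L || pileup$depth[i] == 0L) return(NA_real_)
  pileup[[alt]][i] / pileup$depth[i]
}

#' Classify variant sites between two samples
#'
#' Every site/allele called in either sample is classified from its
#' alternate-allele fractions `fa`, `fb` in the two samples:
#' `fixed_difference` when one fraction is >= `fixed_hi` and the other is
#' <= `absent_lo`; `shared_heterogeneity` when both lie in
#' `[threshold, fixed_hi)`; `private_heterogeneity` when exactly one lies in
#' `[threshold, fixed_hi)` and the other is <= `absent_lo`; otherwise
#' `ambiguous` (including sites uncovered in one sample).
#'
#' @param calls_a,calls_b [call_variants()] results for the two samples
#'   (mapped to the same reference).
#' @param pileup_a,pileup_b the matching pileups (used to look up the
#'   fraction in the sample where the site was not called).
#' @param threshold heterozygosity floor tau (default 0.35).
#' @param fixed_hi fraction treated as fixed (default 0.95).
#' @param absent_lo fraction treated as absent (default 0.05).
#' @return Data frame: `replicon`, `pos`, `ref`, `alt`, `fraction_a`,
#'   `fraction_b`, `class`.
#' @export
compare_samples <- function(calls_a, calls_b, pileup_a, pileup_b,
                            threshold = 0.35, fixed_hi = 0.95,
                            absent_lo = 0.05) {
  key <- function(d) paste(d$replicon, d$pos, d$alt, sep = "\r")
  u <- rbind(calls_a[c("replicon", "pos", "ref", "alt")],
             calls_b[c("replicon", "pos", "ref", "alt")])
  u <- u[!duplicated(key(u)), , drop = FALSE]
  u <- u[order(u$replicon, u$pos, u$alt), , drop = FALSE]
  fa <- mapply(alt_fraction_at, u$replicon, u$pos, u$alt,
               MoreArgs = list(pileup = pileup_a))
  fb <- mapply(alt_fraction_at, u$replicon, u$pos, u$alt,
               MoreArgs = list(pileup = pileup_b))
  het <- function(f) !is.na(f) & f >= threshold & f < fixed_hi
  absent <- function(f) !is.na(f) & f <= absent_lo
  fixed <- function(f) !is.na(f) & f >= fixed_hi
  cls <- rep("ambiguous", nrow(u))
  cls[(fixed(fa) & absent(fb)) | (fixed(fb) & absent(fa))] <- "fixed_difference"
  cls[het(fa) & het(fb)] <- "shared_heterogeneity"
  cls[(het(fa) & absent(fb)) | (het(fb) & absent(fa))] <- "private_heterogeneity"
  res <- data.frame(u, fraction_a = unname(fa), fraction_b = unname(fb),
                    class = cls, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Introduce a point substitution into a replicon
#'
#' Convenience for building haplotypes that differ from a reference at
#' engineered SNV sites.
#'
#' @param rep a [replicon()] with a sequence.
#' @param pos 0-based positions.
#' @param alt replacement bases (recycled against `pos`).
#' @return A new `replicon` (same name/role/topology).
#' @export
mutate_replicon <- function(rep, pos, alt) {
  stopifnot(inherits(rep, "replicon"), !is.null(rep$sequence),
            all(pos >= 0), all(pos < rep$length_bp))
  alt <- rep_len(toupper(alt), length(pos))
  s <- rep$sequence
  for (i in seq_along(pos)) {
    substr(s, pos[i] + 1L, pos[i] + 1L) <- alt[i]
  }
  replicon(rep$name, sequence = s, role = rep$role, topology = rep$topology)
}

#' Write variant calls as minimal VCF v4.2
#'
#' Emits `CHROM`, 1-based `POS`, `REF`, `ALT` and `INFO AF=...;DP=...`.
#'
#' @param calls a [call_variants()] result.
#' @param path output file.
#' @param lengths optional named replicon lengths for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=normcov %s",
                   as.character(utils::packageVersion("normcov"))),
           if (!is.null(lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(lengths),
                     as.integer(lengths)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele fraction\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- if (nrow(calls)) {
    paste(calls$replicon, calls$pos + 1L, ".", calls$ref, calls$alt, ".", ".",
          sprintf("AF=%.6g;DP=%d", calls$alt_fraction, calls$depth),
          sep = "\t")
  } else character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}
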