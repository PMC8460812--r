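#' Write an alignment set as minimal SAM
#'
#' Emits an `@HD` line, one `@SQ` line per replicon and one record per aligned
#' mate. FLAG carries the paired (0x1), reverse-strand (0x10) and mate
#' (0x40/0x80) bits; POS is 1-based per SAM convention; CIGAR is the stored
#' M-run; SEQ is the forward-strand aligned sequence.
#'
#' @param aln an [alignment_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  stopifnot(inherits(aln, "alignment_set"))
  lens <- attr(aln, "lengths")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- 1L + ifelse(aln$mate == 1L, 64L, 128L) +
    ifelse(aln$strand == "-", 16L, 0L)
  rec <- paste(aln$read_id, flag, aln$replicon, aln$start + 1L, 60L,
               aln$cigar, "*", 0L, 0L, aln$seq, "*", sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file into an alignment set
#'
#' Accepts the minimal dialect written by [write_sam()], or any SAM whose
#' records use only M/=/X CIGAR operations; other operations are rejected
#' with an error. Unmapped records (FLAG 0x4 or `*` RNAME) are dropped.
#'
#' @param path SAM file.
#' @return An [alignment_set()].
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  hd <- ln[startsWith(ln, "@")]
  sq <- hd[startsWith(hd, "@SQ")]
  if (length(sq) == 0L) stop("SAM header has no @SQ lines: ", path)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  lenv <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  body <- ln[!startsWith(ln, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(alignment_set(
      data.frame(read_id = character(), mate = integer(),
                 replicon = character(), start = integer(),
                 strand = character(), seq = character(),
                 cigar = character(), stringsAsFactors = FALSE),
      stats::setNames(lenv, sn)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM record (fewer than 11 fields)")
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  f <- f[keep]; flag <- flag[keep]; rname <- rname[keep]
  rec <- data.frame(
    read_id = vapply(f, `[[`, "", 1L),
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    replicon = rname,
    start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = vapply(f, `[[`, "", 10L),
    cigar = vapply(f, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
  alignment_set(rec, stats::setNames(lenv, sn))
}
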