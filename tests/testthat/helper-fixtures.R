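# Small multi-replicon genomes and hand-built alignment sets used across the
# suite. Everything is generated in code at test time.

toy_genome <- function(chr_len = 20000L, plasmid_lens = c(pA = 4000L, pB = 6000L),
                       gc = 0.5, seed = 42L) {
  reps <- c(
    list(random_replicon("chr", chr_len, gc, seed = seed, role = "chromosome")),
    lapply(seq_along(plasmid_lens), function(i) {
      random_replicon(names(plasmid_lens)[i], plasmid_lens[[i]], gc,
                      seed = seed + i)
    })
  )
  genome_model(reps)
}

# Alignment set over given replicon lengths from parallel vectors.
make_aln <- function(lengths, replicon, start, seq, mate = 1L, strand = "+",
                     read_id = NULL) {
  n <- length(start)
  alignment_set(
    data.frame(
      read_id = read_id %||% sprintf("r%03d", seq_len(n)),
      mate = rep_len(mate, n),
      replicon = rep_len(replicon, n),
      start = as.integer(start),
      strand = rep_len(strand, n),
      seq = seq,
      cigar = sprintf("%dM", nchar(seq)),
      stringsAsFactors = FALSE
    ),
    lengths
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent per-base depth oracle: walk every record and increment a plain
# integer array, then average windows by hand.
naive_windowed_depth <- function(aln, window_bp) {
  lens <- attr(aln, "lengths")
  out <- list()
  for (r in names(lens)) {
    depth <- integer(lens[[r]])
    rows <- which(aln$replicon == r)
    for (i in rows) {
      w <- nchar(aln$seq[i])
      idx <- (aln$start[i] + 1L):(aln$start[i] + w)
      depth[idx] <- depth[idx] + 1L
    }
    starts <- seq.int(1L, lens[[r]], by = window_bp)
    ends <- pmin(starts + window_bp - 1L, lens[[r]])
    out[[r]] <- data.frame(
      replicon = r, start = starts - 1L, end = ends,
      mean_depth = vapply(seq_along(starts), function(j) {
        mean(depth[starts[j]:ends[j]])
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Independent pileup oracle: per-position tally over all reads, one position
# at a time.
naive_pileup_counts <- function(aln, replicon, L) {
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in which(aln$replicon == replicon)) {
    bases <- strsplit(aln$seq[i], "")[[1]]
    for (j in seq_along(bases)) {
      b <- bases[j]
      if (b %in% rownames(counts)) {
        p <- aln$start[i] + j
        counts[b, p] <- counts[b, p] + 1L
      }
    }
  }
  counts
}
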