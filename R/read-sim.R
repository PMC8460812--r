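#' Paired-end read simulation parameters
#'
#' Defaults mirror a standard 2 x 151 bp Illumina library with an error-free
#' substitution model (qualities are constant Q40 and unused downstream).
#'
#' @param n_pairs number of read pairs (>= 1).
#' @param read_length read length in bp (default 151).
#' @param fragment_mean,fragment_sd insert-size distribution (normal,
#'   truncated per replicon to `[read_length, length)`).
#' @param substitution_rate per-base substitution error rate in `[0, 0.1]`.
#' @param seed RNG seed; a fixed seed yields byte-identical FASTQ/SAM.
#' @return An object of class `read_pair_spec`.
#' @export
read_pair_spec <- function(n_pairs, read_length = 151L, fragment_mean = 400L,
                           fragment_sd = 40L, substitution_rate = 0,
                           seed = NULL) {
  stopifnot(n_pairs >= 1, read_length >= 1, fragment_sd >= 0)
  if (read_length > fragment_mean) {
    stop("read_length must not exceed fragment_mean")
  }
  if (substitution_rate < 0 || substitution_rate > 0.1) {
    stop("substitution_rate outside [0, 0.1]")
  }
  structure(
    list(n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
         fragment_mean = as.numeric(fragment_mean),
         fragment_sd = as.numeric(fragment_sd),
         substitution_rate = as.numeric(substitution_rate), seed = seed),
    class = "read_pair_spec"
  )
}

#' Construct an alignment set
#'
#' The minimal alignment container used throughout: one row per aligned mate,
#' with 0-based starts, forward-strand aligned sequence and an M-only CIGAR.
#'
#' @param records data frame with columns `read_id`, `mate` (1/2), `replicon`,
#'   `start` (0-based), `strand` (`"+"`/`"-"`), `seq` (aligned forward-strand
#'   sequence), `cigar`.
#' @param lengths named integer vector of replicon lengths (the header).
#' @return Data frame of class `alignment_set` with a `lengths` attribute.
#' @export
alignment_set <- function(records, lengths) {
  stopifnot(is.data.frame(records),
            all(c("read_id", "mate", "replicon", "start", "strand",
                  "seq", "cigar") %in% names(records)),
            is.numeric(lengths), !is.null(names(lengths)))
  lengths <- stats::setNames(as.integer(lengths), names(lengths))
  if (nrow(records) > 0L) {
    if (!all(records$replicon %in% names(lengths))) {
      stop("alignment references a replicon absent from the header")
    }
    w <- cigar_ref_len(records$cigar)
    if (any(nchar(records$seq) != w)) {
      stop("alignment sequence length inconsistent with CIGAR")
    }
    if (any(records$start < 0) ||
        any(records$start + w > lengths[records$replicon])) {
      stop("alignment beyond replicon bounds")
    }
  }
  rownames(records) <- NULL
  structure(records, lengths = lengths,
            class = c("alignment_set", "data.frame"))
}

#' Simulate paired-end reads with truth alignments
#'
#' Fragments are assigned to replicons with probability proportional to
#' `effective_copies(r) * length(r)`, where effective copies are the ploidy
#' for the chromosome and `carriage * copy_number` for each plasmid (or
#' `presence * copy_number` when a [sample_founder()] colony founder is
#' supplied). Fragment starts are uniform over all positions at which the
#' fragment fits; fragments never wrap the origin. Both mates are recorded
#' with their true coordinates; substitution errors are applied after
#' placement. Replicons no longer than one read length are excluded with a
#' warning.
#'
#' @param model a [population_model()] (replicons must carry sequences).
#' @param spec a [read_pair_spec()].
#' @param founder optional `colony_founder`; restricts plasmid content to the
#'   founder's presence pattern (a clonal colony library).
#' @return Object of class `read_sim`: list with `alignments` (an
#'   [alignment_set()]; two rows per pair, mate 1 forward / mate 2 reverse)
#'   and `reads` (list `id`, `r1`, `r2` with as-sequenced orientations).
#' @export
simulate_reads <- function(model, spec, founder = NULL) {
  stopifnot(inherits(model, "population_model"),
            inherits(spec, "read_pair_spec"))
  genome <- model$genome
  reps <- genome$replicons
  has_seq <- vapply(reps, function(r) !is.null(r$sequence), logical(1))
  if (!all(has_seq)) {
    stop("all replicons need sequences to simulate reads (missing: ",
         paste(names(reps)[!has_seq], collapse = ", "), ")")
  }
  lens <- replicon_lengths(genome)
  eff <- numeric(length(reps))
  names(eff) <- names(reps)
  eff[genome$chromosome] <- model$ploidy
  pl <- plasmid_names(genome)
  if (is.null(founder)) {
    eff[pl] <- model$carriage[pl] * model$plasmid_copy[pl]
  } else {
    stopifnot(inherits(founder, "colony_founder"))
    eff[pl] <- as.numeric(founder$presence[pl]) * model$plasmid_copy[pl]
  }
  rl <- spec$read_length
  usable <- lens > rl
  if (any(!usable & eff > 0)) {
    warning("replicon(s) shorter than a read excluded from simulation: ",
            paste(names(lens)[!usable & eff > 0], collapse = ", "))
  }
  w <- eff * lens
  w[!usable] <- 0
  if (all(w == 0)) stop("no usable replicon with positive abundance")

  n <- spec$n_pairs
  sim <- with_seed(spec$seed, {
    ri <- sample.int(length(reps), n, replace = TRUE, prob = w)
    L <- lens[ri]
    frag <- as.integer(pmin(pmax(round(stats::rnorm(
      n, spec$fragment_mean, spec$fragment_sd)), rl), L - 1L))
    start1 <- as.integer(floor(stats::runif(n) * (L - frag + 1)))
    start2 <- start1 + frag - rl
    seq1 <- character(n)
    seq2 <- character(n)
    for (j in unique(ri)) {
      idx <- which(ri == j)
      s <- reps[[j]]$sequence
      seq1[idx] <- substring(s, start1[idx] + 1L, start1[idx] + rl)
      seq2[idx] <- substring(s, start2[idx] + 1L, start2[idx] + rl)
    }
    if (spec$substitution_rate > 0) {
      all_seq <- c(seq1, seq2)
      total <- 2L * n * rl
      n_sub <- stats::rbinom(1L, total, spec$substitution_rate)
      if (n_sub > 0L) {
        slot <- sample.int(total, n_sub)
        rd <- (slot - 1L) %/% rl + 1L
        off <- (slot - 1L) %% rl + 1L
        for (t in seq_len(n_sub)) {
          cur <- substr(all_seq[rd[t]], off[t], off[t])
          alt <- sample(setdiff(DNA_BASES, cur), 1L)
          substr(all_seq[rd[t]], off[t], off[t]) <- alt
        }
      }
      seq1 <- all_seq[seq_len(n)]
      seq2 <- all_seq[n + seq_len(n)]
    }
    list(ri = ri, start1 = start1, start2 = start2, seq1 = seq1, seq2 = seq2)
  })

  ids <- sprintf("sim%07d", seq_len(n))
  ord <- as.vector(rbind(seq_len(n), n + seq_len(n)))  # interleave mates
  rec <- data.frame(
    read_id = c(ids, ids),
    mate = rep(c(1L, 2L), each = n),
    replicon = names(reps)[c(sim$ri, sim$ri)],
    start = c(sim$start1, sim$start2),
    strand = rep(c("+", "-"), each = n),
    seq = c(sim$seq1, sim$seq2),
    cigar = sprintf("%dM", rl),
    stringsAsFactors = FALSE
  )[ord, ]
  list(
    alignments = alignment_set(rec, lens),
    reads = list(id = ids, r1 = sim$seq1, r2 = revcomp(sim$seq2))
  )
}

#' Write simulated reads as a FASTQ pair
#'
#' Files are `<prefix>_1.fastq` / `<prefix>_2.fastq`; read names carry `/1`
#' and `/2` suffixes; qualities are constant `I` (Q40).
#'
#' @param sim result of [simulate_reads()].
#' @param prefix output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(sim, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    s <- sim$reads[[c("r1", "r2")[m]]]
    lines <- as.vector(rbind(
      paste0("@", sim$reads$id, "/", m), s, "+", strrep("I", nchar(s))))
    writeLines(lines, paths[m])
  }
  invisible(paths)
}
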