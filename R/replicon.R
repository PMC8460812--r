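DNA_BASES <- c("A", "C", "G", "T")

#' Construct a replicon
#'
#' A replicon is a named, usually circular, DNA element of a bacterial genome:
#' the chromosome or a plasmid. The sequence is optional — registry entries may
#' carry only a length and a GC percentage. When a sequence is supplied, length
#' and GC are computed from it; `N` bases count toward the length but are
#' excluded from both the numerator and denominator of the GC fraction.
#'
#' @param name replicon identifier (unique within a genome).
#' @param sequence optional DNA string over `A,C,G,T,N`.
#' @param length_bp length in bp; required when `sequence` is absent.
#' @param gc_percent GC content in percent (0–100); ignored (recomputed) when a
#'   sequence is supplied.
#' @param role `"chromosome"` or `"plasmid"`.
#' @param topology `"circular"` or `"linear"`; recorded only — windowed
#'   statistics never wrap the origin.
#' @return An object of class `replicon`.
#' @export
replicon <- function(name, sequence = NULL, length_bp = NULL, gc_percent = NULL,
                     role = c("plasmid", "chromosome"),
                     topology = c("circular", "linear")) {
  role <- match.arg(role)
  topology <- match.arg(topology)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    stopifnot(length(sequence) == 1L)
    if (grepl("[^ACGTN]", sequence)) {
      stop("replicon '", name, "': sequence contains characters outside A,C,G,T,N")
    }
    if (is.null(length_bp)) length_bp <- nchar(sequence)
    if (length_bp != nchar(sequence)) {
      stop("replicon '", name, "': length_bp does not match sequence length")
    }
    gc_percent <- 100 * gc_fraction(sequence)
  }
  if (is.null(length_bp) || length_bp < 1) {
    stop("replicon '", name, "': positive length_bp required")
  }
  if (!is.null(gc_percent) && (gc_percent < 0 || gc_percent > 100)) {
    stop("replicon '", name, "': gc_percent outside [0, 100]")
  }
  structure(
    list(name = name, role = role, sequence = sequence,
         length_bp = as.integer(length_bp),
         gc_percent = if (is.null(gc_percent)) NA_real_ else as.numeric(gc_percent),
         topology = topology),
    class = "replicon"
  )
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s (%s, %s): %s bp, GC %s%%, sequence %s\n",
              x$name, x$role, x$topology, format(x$length_bp, big.mark = ","),
              ifelse(is.na(x$gc_percent), "?", sprintf("%.1f", x$gc_percent)),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

# GC fraction of a DNA string; N excluded from numerator and denominator.
gc_fraction <- function(sequence) {
  lf <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                    c("A", "C", "G", "T"))
  lf <- drop(lf)
  valid <- sum(lf)
  if (valid == 0) return(0)
  unname((lf[["C"]] + lf[["G"]]) / valid)
}

#' Construct a multi-replicon genome model
#'
#' @param replicons list of [replicon()] objects; names must be unique and
#'   exactly one must have role `"chromosome"`.
#' @return An object of class `genome_model` with elements `replicons` (named
#'   list), `chromosome` (its name) and `total_length`.
#' @export
genome_model <- function(replicons) {
  stopifnot(is.list(replicons), length(replicons) >= 1L)
  ok <- vapply(replicons, inherits, logical(1), "replicon")
  if (!all(ok)) stop("all elements must be replicon objects")
  nms <- vapply(replicons, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate replicon names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  roles <- vapply(replicons, `[[`, character(1), "role")
  if (sum(roles == "chromosome") != 1L) {
    stop("a genome must contain exactly one chromosome (found ",
         sum(roles == "chromosome"), ")")
  }
  names(replicons) <- nms
  structure(
    list(replicons = replicons,
         chromosome = nms[roles == "chromosome"],
         total_length = sum(vapply(replicons, `[[`, integer(1), "length_bp"))),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d replicons, %s bp total (chromosome: %s)\n",
              length(x$replicons), format(x$total_length, big.mark = ","),
              x$chromosome))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' Replicon lengths of a genome model
#' @param genome a `genome_model`.
#' @return Named integer vector of lengths in bp.
#' @export
replicon_lengths <- function(genome) {
  vapply(genome$replicons, `[[`, integer(1), "length_bp")
}

#' Names of the plasmid replicons
#' @param genome a `genome_model`.
#' @return Character vector.
#' @export
plasmid_names <- function(genome) {
  setdiff(names(genome$replicons), genome$chromosome)
}

#' Load a multi-record FASTA file as a genome model
#'
#' Each record becomes one replicon. The chromosome is the longest record
#' unless `chromosome_name` designates another.
#'
#' @param path FASTA file.
#' @param chromosome_name record to treat as the chromosome (default: longest).
#' @param topology assumed topology for every record.
#' @return A `genome_model`.
#' @export
load_genome_fasta <- function(path, chromosome_name = NULL,
                              topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA record names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  chr <- chromosome_name %||% nms[which.max(Biostrings::width(seqs))]
  if (!chr %in% nms) stop("chromosome_name '", chr, "' not among FASTA records")
  reps <- lapply(seq_along(seqs), function(i) {
    replicon(nms[i], sequence = as.character(seqs[[i]]),
             role = if (nms[i] == chr) "chromosome" else "plasmid",
             topology = topology)
  })
  genome_model(reps)
}

#' Write a genome model to FASTA (70-column wrap)
#' @param genome a `genome_model` whose replicons carry sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- lapply(genome$replicons, function(r) {
    if (is.null(r$sequence)) stop("replicon '", r$name, "' has no sequence")
    r$sequence
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(genome$replicons)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' The MSH1 (substrain DK1) replicon registry
#'
#' Sequence-free registry of the eight replicons of *Aminobacter* sp. MSH1:
#' the chromosome and plasmids pBAM1, pBAM2 and pUSP1–pUSP5, with their
#' published lengths and GC percentages.
#'
#' @return A `genome_model` whose replicons carry lengths and GC but no
#'   sequence.
#' @export
msh1_registry <- function() {
  reg <- data.frame(
    name = c("chromosome", "pBAM1", "pBAM2", "pUSP1", "pUSP2",
             "pUSP3", "pUSP4", "pUSP5"),
    length_bp = c(5301518L, 40559L, 53893L, 367423L, 365485L,
                  97029L, 64122L, 31577L),
    gc_percent = c(63.2, 64.4, 56.0, 63.1, 60.1, 60.5, 61.9, 62.9),
    stringsAsFactors = FALSE
  )
  genome_model(lapply(seq_len(nrow(reg)), function(i) {
    replicon(reg$name[i], length_bp = reg$length_bp[i],
             gc_percent = reg$gc_percent[i],
             role = if (reg$name[i] == "chromosome") "chromosome" else "plasmid",
             topology = "circular")
  }))
}

#' Generate a random replicon with a target GC content
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_target/2` and
#' `P(A) = P(T) = (1 - gc_target)/2`.
#'
#' @param name replicon name.
#' @param length_bp sequence length (>= 1).
#' @param gc_target target GC fraction in `[0, 1]`.
#' @param seed RNG seed (reproducible sequences for a fixed seed).
#' @param role,topology passed to [replicon()].
#' @return A `replicon` with a sequence.
#' @export
random_replicon <- function(name, length_bp, gc_target, seed = NULL,
                            role = c("plasmid", "chromosome"),
                            topology = c("circular", "linear")) {
  stopifnot(length_bp >= 1)
  if (!is.numeric(gc_target) || gc_target < 0 || gc_target > 1) {
    stop("gc_target must lie in [0, 1]")
  }
  bases <- with_seed(seed, {
    sample(DNA_BASES, length_bp, replace = TRUE,
           prob = c((1 - gc_target) / 2, gc_target / 2,
                    gc_target / 2, (1 - gc_target) / 2))
  })
  replicon(name, sequence = paste(bases, collapse = ""),
           role = role, topology = topology)
}

#' Simulate sequences for a sequence-free genome registry
#'
#' Draws a random sequence for every replicon of `registry` at its recorded
#' length and GC percentage. Defaults to the MSH1 registry, i.e. the full
#' 6.32-Mb eight-replicon genome.
#'
#' @param registry a `genome_model` (sequences ignored if present).
#' @param seed RNG seed; each replicon uses a seed derived from it.
#' @return A `genome_model` with sequences.
#' @export
simulate_genome <- function(registry = msh1_registry(), seed = NULL) {
  reps <- lapply(seq_along(registry$replicons), function(i) {
    r <- registry$replicons[[i]]
    gc <- if (is.na(r$gc_percent)) 0.5 else r$gc_percent / 100
    random_replicon(r$name, r$length_bp, gc,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                    role = r$role, topology = r$topology)
  })
  genome_model(reps)
}

#' Cross-check a genome against a printed registry
#'
#' Compares computed replicon lengths and GC percentages of a sequenced genome
#' against the lengths and GC a registry records, matching replicons by name.
#'
#' @param genome `genome_model` with sequences (e.g. from [load_genome_fasta()]).
#' @param registry reference registry; default [msh1_registry()].
#' @param gc_tol allowed absolute GC deviation in percentage points.
#' @return Data frame with printed vs computed values and per-replicon
#'   `length_ok` / `gc_ok` flags.
#' @export
validate_registry <- function(genome, registry = msh1_registry(), gc_tol = 0.05) {
  common <- intersect(names(registry$replicons), names(genome$replicons))
  if (length(common) == 0L) stop("no replicon names shared with the registry")
  out <- do.call(rbind, lapply(common, function(nm) {
    reg <- registry$replicons[[nm]]
    obs <- genome$replicons[[nm]]
    data.frame(name = nm,
               length_registry = reg$length_bp, length_observed = obs$length_bp,
               gc_registry = reg$gc_percent, gc_observed = obs$gc_percent,
               length_ok = reg$length_bp == obs$length_bp,
               gc_ok = is.na(reg$gc_percent) ||
                 abs(reg$gc_percent - obs$gc_percent) <= gc_tol,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
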