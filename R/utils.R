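`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded simulation helpers do not perturb the session stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for stage i of a pipeline run; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647)
}

# Vectorized reverse complement on plain character DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reference-consuming length of CIGAR strings restricted to M/=/X ops.
cigar_ref_len <- function(cigar) {
  u <- unique(cigar)
  bad <- !grepl("^([0-9]+[M=X])+$", u)
  if (any(bad)) {
    stop("unsupported CIGAR operation (only M/=/X are accepted): ",
         paste(utils::head(u[bad], 3L), collapse = ", "))
  }
  len <- vapply(u, function(cg) {
    sum(as.numeric(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]]))
  }, numeric(1))
  unname(len[match(cigar, u)])
}

# Provenance comment lines prepended to every tabular output.
provenance_header <- function(seed = NULL, extra = character()) {
  c(sprintf("# normcov %s", as.character(utils::packageVersion("normcov"))),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed)),
    extra)
}

write_tsv_provenance <- function(df, path, seed = NULL, extra = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(seed = seed, extra = extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_provenance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
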