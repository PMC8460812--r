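#' Describe a cell population over a multi-replicon genome
#'
#' A population is characterized by its chromosome ploidy `P` (chromosome
#' copies per cell), a per-plasmid copy number (copies per *carrying* cell;
#' fractional values are interpreted as an average abundance weight, not as
#' per-cell integer sampling) and a per-plasmid carriage fraction `c` (the
#' fraction of cells harbouring the plasmid). Carriage below 1 is the
#' plasmid-instability hypothesis; ploidy above 1 with carriage 1 is the
#' chromosome-polyploidy hypothesis.
#'
#' Plasmid presence events in a founder cell are independent across plasmids
#' (the null of no plasmid codependence). A correlation hook is exposed via
#' `shared_loss_prob`: with that probability a founder undergoes a shared loss
#' event in which every unstably carried plasmid (carriage < 1) is lost
#' together. It defaults to 0 (off).
#'
#' @param genome a [genome_model()].
#' @param ploidy chromosome copies per cell (> 0); a population constant.
#' @param plasmid_copy scalar or named numeric vector of copies per carrying
#'   cell; plasmids not named default to 1.
#' @param carriage scalar or named numeric vector of carriage fractions in
#'   `[0, 1]`; plasmids not named default to 1.
#' @param shared_loss_prob probability of a shared loss event (default 0).
#' @return An object of class `population_model`.
#' @export
population_model <- function(genome, ploidy = 1, plasmid_copy = 1,
                             carriage = 1, shared_loss_prob = 0) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(ploidy) || length(ploidy) != 1L || ploidy <= 0) {
    stop("ploidy must be a single positive number")
  }
  pl <- plasmid_names(genome)
  expand <- function(x, what, lo, hi) {
    if (is.null(names(x))) {
      stopifnot(length(x) == 1L)
      x <- stats::setNames(rep(x, length(pl)), pl)
    } else {
      if (!all(names(x) %in% pl)) {
        stop("unknown plasmid in ", what, ": ",
             paste(setdiff(names(x), pl), collapse = ", "))
      }
      full <- stats::setNames(rep(1, length(pl)), pl)
      full[names(x)] <- x
      x <- full
    }
    if (any(x < lo | x > hi)) stop(what, " outside [", lo, ", ", hi, "]")
    x
  }
  plasmid_copy <- expand(plasmid_copy, "plasmid_copy", 0, Inf)
  carriage <- expand(carriage, "carriage", 0, 1)
  stopifnot(shared_loss_prob >= 0, shared_loss_prob <= 1)
  structure(
    list(genome = genome, ploidy = as.numeric(ploidy),
         plasmid_copy = plasmid_copy, carriage = carriage,
         shared_loss_prob = as.numeric(shared_loss_prob)),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> ploidy %.3g, %d plasmids\n",
              x$ploidy, length(x$plasmid_copy)))
  print(data.frame(plasmid = names(x$plasmid_copy),
                   copy_number = unname(x$plasmid_copy),
                   carriage = unname(x$carriage)))
  invisible(x)
}

#' Sample a single clonal colony founder
#'
#' Each plasmid is present independently with probability equal to its
#' carriage fraction (plus the optional shared-loss event, see
#' [population_model()]). A colony founded by this cell is assumed clonal:
#' colony-level plasmid presence equals founder presence.
#'
#' @param model a `population_model`.
#' @param seed RNG seed.
#' @return Object of class `colony_founder`: list with `presence` (named
#'   logical over plasmids) and `ploidy`.
#' @export
sample_founder <- function(model, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  pres <- with_seed(seed, {
    p <- stats::runif(length(model$carriage)) < model$carriage
    if (model$shared_loss_prob > 0 &&
        stats::runif(1) < model$shared_loss_prob) {
      p[model$carriage < 1] <- FALSE
    }
    p
  })
  names(pres) <- names(model$carriage)
  structure(list(presence = pres, ploidy = model$ploidy),
            class = "colony_founder")
}

#' Sample a panel of clonal colonies
#'
#' Draws `n` independent colony founders and tallies, per plasmid, the number
#' of colonies lacking it.
#'
#' @param model a `population_model`.
#' @param n number of colonies (>= 1).
#' @param seed RNG seed.
#' @return Object of class `colony_panel`: list with `n`, `plasmids`, `losses`
#'   (named integer, colonies lacking each plasmid) and `founders` (n x
#'   plasmid logical presence matrix).
#' @export
sample_panel <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive number of colonies")
  }
  n <- as.integer(n)
  pl <- names(model$carriage)
  pres <- with_seed(seed, {
    m <- matrix(stats::runif(n * length(pl)), nrow = n) <
      matrix(model$carriage, nrow = n, ncol = length(pl), byrow = TRUE)
    if (model$shared_loss_prob > 0) {
      shared <- stats::runif(n) < model$shared_loss_prob
      m[shared, model$carriage < 1] <- FALSE
    }
    m
  })
  colnames(pres) <- pl
  colony_panel(pres)
}

#' Build a colony panel from a presence/absence matrix
#' @param presence logical matrix, colonies x plasmids (column names are
#'   plasmid names).
#' @return A `colony_panel`.
#' @export
colony_panel <- function(presence) {
  stopifnot(is.matrix(presence), is.logical(presence),
            !is.null(colnames(presence)), nrow(presence) >= 1L)
  structure(
    list(n = nrow(presence), plasmids = colnames(presence),
         losses = colSums(!presence), founders = presence),
    class = "colony_panel"
  )
}

#' @export
print.colony_panel <- function(x, ...) {
  cat(sprintf("<colony_panel> %d colonies\n", x$n))
  print(data.frame(plasmid = x$plasmids, colonies_lost = unname(x$losses)))
  invisible(x)
}

#' Write a colony panel as a colony x plasmid TSV
#' @param panel a `colony_panel`.
#' @param path output file.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path, seed = NULL) {
  df <- data.frame(colony = seq_len(panel$n),
                   as.data.frame(panel$founders))
  write_tsv_provenance(df, path, seed = seed)
}

#' Read a colony panel written by [write_panel_tsv()]
#' @param path TSV file.
#' @return A `colony_panel`.
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_provenance(path)
  m <- as.matrix(df[, setdiff(names(df), "colony"), drop = FALSE])
  storage.mode(m) <- "logical"
  colony_panel(m)
}

#' Write / read a population model as JSON
#' @param model a `population_model`.
#' @param path JSON file.
#' @return `path` (write), or the parameter list (read; the genome itself is
#'   not serialized — re-attach with [population_model()]).
#' @export
write_population_json <- function(model, path) {
  jsonlite::write_json(
    list(ploidy = model$ploidy,
         plasmid_copy = as.list(model$plasmid_copy),
         carriage = as.list(model$carriage),
         shared_loss_prob = model$shared_loss_prob),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population_json
#' @export
read_population_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
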