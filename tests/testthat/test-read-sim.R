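two_replicon_model <- function(copies_b = 2, len = 1000L) {
  g <- genome_model(list(
    random_replicon("ra", len, 0.5, seed = 1, role = "chromosome"),
    random_replicon("rb", len, 0.5, seed = 2)))
  population_model(g, ploidy = 1, plasmid_copy = c(rb = copies_b))
}

test_that("read share follows copy-number x length weights", {
  m <- two_replicon_model(copies_b = 2)
  sim <- simulate_reads(m, read_pair_spec(20000L, read_length = 50L,
                                          fragment_mean = 200L,
                                          fragment_sd = 20L, seed = 5))
  counts <- table(sim$alignments$replicon) / 2  # two mates per pair
  frac_b <- counts[["rb"]] / sum(counts)
  se <- sqrt((2 / 3) * (1 / 3) / 20000)
  expect_lt(abs(frac_b - 2 / 3), 3 * se)
})

test_that("per-replicon pair counts pass a multinomial goodness-of-fit", {
  g <- genome_model(list(
    random_replicon("chr", 20000L, 0.5, seed = 1, role = "chromosome"),
    random_replicon("p1", 5000L, 0.5, seed = 2),
    random_replicon("p2", 8000L, 0.5, seed = 3)))
  m <- population_model(g, ploidy = 2, plasmid_copy = c(p1 = 1, p2 = 2.5))
  w <- c(chr = 2 * 20000, p1 = 1 * 5000, p2 = 2.5 * 8000)
  sim <- simulate_reads(m, read_pair_spec(50000L, seed = 8))
  pairs <- table(sim$alignments$replicon[sim$alignments$mate == 1L])
  gof <- stats::chisq.test(as.vector(pairs[names(w)]), p = w / sum(w))
  expect_gt(gof$p.value, 0.001)
})

test_that("error-free reads equal the reference substring at their coordinates", {
  m <- two_replicon_model()
  sim <- simulate_reads(m, read_pair_spec(500L, read_length = 60L,
                                          fragment_mean = 150L,
                                          fragment_sd = 10L, seed = 4))
  aln <- sim$alignments
  seqs <- vapply(seq_len(nrow(aln)), function(i) {
    s <- m$genome$replicons[[aln$replicon[i]]]$sequence
    substring(s, aln$start[i] + 1L, aln$start[i] + nchar(aln$seq[i]))
  }, character(1))
  expect_identical(aln$seq, seqs)
})

test_that("substitution errors change about the requested fraction of bases", {
  m <- two_replicon_model()
  spec <- read_pair_spec(2000L, read_length = 100L, fragment_mean = 300L,
                         fragment_sd = 10L, substitution_rate = 0.02, seed = 6)
  sim <- simulate_reads(m, spec)
  aln <- sim$alignments
  mism <- sum(vapply(seq_len(nrow(aln)), function(i) {
    s <- m$genome$replicons[[aln$replicon[i]]]$sequence
    ref <- substring(s, aln$start[i] + 1L, aln$start[i] + nchar(aln$seq[i]))
    sum(strsplit(aln$seq[i], "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1)))
  total <- sum(nchar(aln$seq))
  expect_lt(abs(mism - total * 0.02), 3 * sqrt(total * 0.02 * 0.98))
})

test_that("a fixed seed yields byte-identical FASTQ and SAM", {
  m <- two_replicon_model()
  spec <- read_pair_spec(300L, read_length = 50L, fragment_mean = 150L,
                         fragment_sd = 15L, seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  for (d in c(d1, d2)) {
    sim <- simulate_reads(m, spec)
    write_fastq_pair(sim, file.path(d, "run"))
    write_sam(sim$alignments, file.path(d, "run.sam"))
  }
  for (f in c("run_1.fastq", "run_2.fastq", "run.sam")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("mate geometry is consistent: mate 2 is the fragment's far end", {
  m <- two_replicon_model()
  sim <- simulate_reads(m, read_pair_spec(200L, read_length = 50L,
                                          fragment_mean = 120L,
                                          fragment_sd = 5L, seed = 9))
  a <- sim$alignments
  m1 <- a[a$mate == 1L, ]; m2 <- a[a$mate == 2L, ]
  expect_identical(m1$read_id, m2$read_id)
  expect_true(all(m2$start >= m1$start))
  expect_true(all(m1$strand == "+") && all(m2$strand == "-"))
  # R2 as sequenced is the reverse complement of its aligned sequence
  i <- match(m2$read_id, sim$reads$id)
  expect_identical(sim$reads$r2[i], as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(m2$seq))))
})

test_that("too-short replicons are excluded with a warning, or fail when none usable", {
  g <- genome_model(list(
    random_replicon("chr", 2000L, 0.5, seed = 1, role = "chromosome"),
    random_replicon("tiny", 100L, 0.5, seed = 2)))
  m <- population_model(g)
  spec <- read_pair_spec(100L, read_length = 120L, fragment_mean = 300L,
                         fragment_sd = 10L, seed = 3)
  expect_warning(sim <- simulate_reads(m, spec), "tiny")
  expect_false("tiny" %in% sim$alignments$replicon)

  g2 <- genome_model(list(
    random_replicon("chr", 100L, 0.5, seed = 1, role = "chromosome")))
  expect_error(suppressWarnings(
    simulate_reads(population_model(g2), spec)), "no usable replicon")
})

test_that("SAM round-trips exactly and converts coordinates to 1-based POS", {
  lens <- c(ra = 500L)
  aln <- make_aln(lens, "ra", start = c(0L, 99L),
                  seq = c(strrep("A", 50), strrep("C", 50)),
                  mate = c(1L, 2L), strand = c("+", "-"),
                  read_id = c("q1", "q1"))
  path <- tempfile(fileext = ".sam")
  write_sam(aln, path)
  lines <- readLines(path)
  rec <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_identical(rec[[1]][4], "1")      # start 0 -> POS 1
  expect_identical(rec[[2]][4], "100")
  back <- read_sam(path)
  expect_equal(as.data.frame(back), as.data.frame(aln))
  expect_identical(attr(back, "lengths"), attr(aln, "lengths"))
})

test_that("an empty alignment set writes a header-only SAM", {
  empty <- alignment_set(
    data.frame(read_id = character(), mate = integer(), replicon = character(),
               start = integer(), strand = character(), seq = character(),
               cigar = character(), stringsAsFactors = FALSE),
    c(ra = 100L))
  path <- tempfile(fileext = ".sam")
  write_sam(empty, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "@")))
  back <- read_sam(path)
  expect_identical(nrow(back), 0L)
  expect_identical(attr(back, "lengths"), c(ra = 100L))
})

test_that("read_sam rejects CIGAR operations outside M/=/X", {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ra\tLN:100",
               paste("q", 0, "ra", 1, 60, "5M2D5M", "*", 0, 0,
                     strrep("A", 10), "*", sep = "\t")), path)
  expect_error(read_sam(path), "CIGAR")
})

test_that("alignment sets reject out-of-bounds and inconsistent records", {
  lens <- c(ra = 100L)
  expect_error(make_aln(lens, "ra", 60L, strrep("A", 50)), "bounds")
  expect_error(make_aln(lens, "rb", 0L, strrep("A", 50)), "absent")
  expect_error(
    alignment_set(data.frame(read_id = "q", mate = 1L, replicon = "ra",
                             start = 0L, strand = "+", seq = "ACGT",
                             cigar = "5M", stringsAsFactors = FALSE), lens),
    "inconsistent")
})

test_that("written SAM agrees with an external SAM parser", {
  skip_if_not_installed("Rsamtools")
  m <- two_replicon_model()
  sim <- simulate_reads(m, read_pair_spec(100L, read_length = 50L,
                                          fragment_mean = 150L,
                                          fragment_sd = 10L, seed = 13))
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$alignments, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  ours <- sim$alignments[order(sim$alignments$read_id, sim$alignments$mate), ]
  ord <- order(rec$qname, !Rsamtools::bamFlagTest(rec$flag, "isFirstMateRead"))
  expect_identical(as.integer(rec$pos[ord]), ours$start + 1L)
  expect_identical(as.character(rec$rname[ord]), ours$replicon)
  expect_identical(as.character(rec$seq[ord]), ours$seq)
})
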