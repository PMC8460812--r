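ref_replicon <- function(len = 2000L, seed = 31L) {
  random_replicon("chr", len, 0.5, seed = seed, role = "chromosome")
}

# Align n_ref reads matching the reference and n_alt carrying `alt` at pos.
site_aln <- function(rp, pos, alt, n_ref, n_alt, read_len = 51L) {
  start <- max(0L, pos - (read_len %/% 2L))
  ref_read <- substring(rp$sequence, start + 1L, start + read_len)
  alt_read <- ref_read
  substr(alt_read, pos - start + 1L, pos - start + 1L) <- alt
  make_aln(stats::setNames(rp$length_bp, rp$name), rp$name,
           start = rep_len(start, n_ref + n_alt),
           seq = c(rep(ref_read, n_ref), rep(alt_read, n_alt)))
}

test_that("pileup counts match direct tallies", {
  r <- ref_replicon(400L)
  g <- genome_model(list(r))
  pos <- 200L
  ref_base <- substring(r$sequence, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  aln <- site_aln(r, pos, alt, n_ref = 6L, n_alt = 4L)
  pu <- build_pileup(aln, g)
  row <- pu[pu$pos == pos, ]
  expect_identical(row$depth, 10L)
  expect_identical(row[[ref_base]], 6L)
  expect_identical(row[[alt]], 4L)
  # uncovered positions are absent
  expect_false(0L %in% pu$pos)
  expect_identical(row$ref, ref_base)
})

test_that("pileup equals the brute-force per-position oracle", {
  g <- toy_genome(chr_len = 3000L, plasmid_lens = c(pA = 1200L), seed = 17)
  m <- population_model(g, ploidy = 1)
  sim <- simulate_reads(m, read_pair_spec(300L, read_length = 60L,
                                          fragment_mean = 180L,
                                          fragment_sd = 20L,
                                          substitution_rate = 0.01, seed = 18))
  pu <- build_pileup(sim$alignments, g)
  for (r in c("chr", "pA")) {
    counts <- naive_pileup_counts(sim$alignments, r,
                                  g$replicons[[r]]$length_bp)
    sub <- pu[pu$replicon == r, ]
    got <- t(as.matrix(sub[, c("A", "C", "G", "T")]))
    expect_identical(unname(got), unname(counts[, sub$pos + 1L]))
    covered <- which(colSums(counts) > 0) - 1L
    expect_identical(sub$pos, as.integer(covered))
  }
})

test_that("N read bases are excluded from counts and depth", {
  r <- replicon("chr", sequence = strrep("ACGT", 25), role = "chromosome")
  g <- genome_model(list(r))
  aln <- make_aln(c(chr = 100L), "chr", start = c(0L, 0L),
                  seq = c(substring(r$sequence, 1, 20),
                          paste0("N", substring(r$sequence, 2, 20))))
  pu <- build_pileup(aln, g)
  expect_identical(pu$depth[pu$pos == 0L], 1L)
  expect_identical(pu$depth[pu$pos == 1L], 2L)
})

test_that("the 35% cutoff is inclusive and respects min_depth", {
  r <- ref_replicon(400L)
  g <- genome_model(list(r))
  pos <- 200L
  ref_base <- substring(r$sequence, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]

  called <- call_variants(build_pileup(site_aln(r, pos, alt, 6L, 4L), g))
  expect_identical(nrow(called), 1L)           # 40% >= 35%
  expect_equal(called$alt_fraction, 0.4)
  expect_identical(called$alt, alt)

  not_called <- call_variants(build_pileup(site_aln(r, pos, alt, 7L, 3L), g))
  expect_identical(nrow(not_called), 0L)       # 30% < 35%

  boundary <- call_variants(build_pileup(site_aln(r, pos, alt, 13L, 7L), g))
  expect_identical(nrow(boundary), 1L)         # 7/20 = 35% exactly
  expect_equal(boundary$alt_fraction, 0.35)

  thin <- call_variants(build_pileup(site_aln(r, pos, alt, 5L, 4L), g),
                        min_depth = 10L)
  expect_identical(nrow(thin), 0L)             # depth 9 < 10
})

test_that("raising the threshold can only shrink the call set", {
  g <- toy_genome(chr_len = 2500L, plasmid_lens = c(pA = 900L), seed = 23)
  m <- population_model(g, ploidy = 1)
  sim <- simulate_reads(m, read_pair_spec(2500L, read_length = 60L,
                                          fragment_mean = 180L,
                                          fragment_sd = 20L,
                                          substitution_rate = 0.1, seed = 24))
  pu <- build_pileup(sim$alignments, g)
  lo <- call_variants(pu, threshold = 0.35, min_depth = 5L)
  hi <- call_variants(pu, threshold = 0.5, min_depth = 5L)
  key <- function(d) paste(d$replicon, d$pos, d$alt)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("a 60/40 two-haplotype mixture recovers every engineered SNV", {
  L <- 2000L
  ref <- ref_replicon(L, seed = 41L)
  g <- genome_model(list(ref))
  set.seed(77)
  sites <- sort(sample(300:(L - 300L), 30L))
  ref_bases <- vapply(sites, function(p) {
    substring(ref$sequence, p + 1L, p + 1L)
  }, character(1))
  alt_bases <- vapply(ref_bases, function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  hap <- mutate_replicon(ref, sites, alt_bases)
  g_hap <- genome_model(list(hap))
  spec <- function(n, seed) {
    read_pair_spec(n, fragment_mean = 400L, fragment_sd = 40L,
                   substitution_rate = 0, seed = seed)
  }
  sim_ref <- simulate_reads(population_model(g), spec(9000L, 51))
  sim_alt <- simulate_reads(population_model(g_hap), spec(6000L, 52))
  combined <- alignment_set(
    rbind(as.data.frame(sim_ref$alignments),
          as.data.frame(sim_alt$alignments)),
    c(chr = L))
  pu <- build_pileup(combined, g)
  calls <- call_variants(pu, threshold = 0.35, min_depth = 10L)
  expect_identical(calls$pos, as.integer(sites))   # all 30, nothing else
  expect_identical(calls$alt, unname(alt_bases))
  expect_true(all(calls$alt_fraction > 0.3 & calls$alt_fraction < 0.5))
})

test_that("two-sample comparison applies the decision table", {
  mk_pu <- function(fracs, depth = 100L) {
    # single-replicon pileup at positions 0..(k-1), ref A, alt G at `fracs`
    k <- length(fracs)
    data.frame(replicon = "chr", pos = seq_len(k) - 1L, ref = "A",
               A = as.integer(round(depth * (1 - fracs))),
               C = 0L, G = as.integer(round(depth * fracs)), T = 0L,
               depth = depth, stringsAsFactors = FALSE)
  }
  fa <- c(1.00, 0.40, 0.40, 0.20, 0.96)
  fb <- c(0.00, 0.45, 0.00, 0.40, 0.50)
  pa <- mk_pu(fa); pb <- mk_pu(fb)
  ca <- call_variants(pa, sample = "A")
  cb <- call_variants(pb, sample = "B")
  cmp <- compare_samples(ca, cb, pa, pb)
  cls <- cmp$class[order(cmp$pos)]
  expect_identical(cls, c("fixed_difference",      # 100% vs 0%
                          "shared_heterogeneity",  # 40% vs 45%
                          "private_heterogeneity", # 40% vs 0%
                          "ambiguous",             # 20% vs 40%: 0.20 is neither het nor absent
                          "ambiguous"))            # 96% vs 50%: fixed vs het
})

test_that("variant calls serialize to minimal VCF with 1-based positions", {
  r <- ref_replicon(400L)
  g <- genome_model(list(r))
  pos <- 200L
  ref_base <- substring(r$sequence, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  calls <- call_variants(build_pileup(site_aln(r, pos, alt, 6L, 4L), g))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, lengths = replicon_lengths(g))
  lines <- readLines(path)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  rec <- strsplit(lines[!startsWith(lines, "#")], "\t")[[1]]
  expect_identical(rec[2], as.character(pos + 1L))
  expect_identical(rec[4], ref_base)
  expect_identical(rec[5], alt)
  expect_match(rec[8], "AF=0\\.4;DP=10")
})
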