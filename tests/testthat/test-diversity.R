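# Diversity measures: HOM, IBS, RoH calling and F_ROH.

test_that("homozygosity proportion counts non-missing calls only", {
  g <- toy_geno(rbind(c(0L, 1L, 2L, 1L, NA),
                      c(1L, 1L, 1L, 1L, 1L),
                      c(0L, 2L, 0L, 2L, 0L)))
  expect_equal(hom_per_individual(g, 1), 0.5)
  expect_equal(hom_per_individual(g, 2), 0)
  expect_equal(hom_per_individual(g, 3), 1)
  # allele relabeling 0 <-> 2 leaves HOM unchanged
  g2 <- toy_geno(2L - g$calls)
  for (i in 1:3)
    expect_equal(hom_per_individual(g2, i), hom_per_individual(g, i))
  g_all_na <- toy_geno(matrix(NA_integer_, 1, 4))
  expect_warning(res <- hom_per_individual(g_all_na, 1))
  expect_true(is.na(res))
})

test_that("pairwise IBS is the co-typed genotype match fraction, symmetric", {
  g <- toy_geno(rbind(c(0L, 1L, 2L, 1L),
                      c(0L, 2L, 2L, NA)))
  expect_equal(ibs_pairwise(g, 1, 2), 2 / 3)
  expect_equal(ibs_pairwise(g, 2, 1), ibs_pairwise(g, 1, 2))
  g_id <- toy_geno(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(ibs_pairwise(g_id, 1, 2), 1)
  g_opp <- toy_geno(rbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(ibs_pairwise(g_opp, 1, 2), 0)
  set.seed(4)
  for (k in 1:20) {
    calls <- matrix(sample(c(0:2, NA), 40, TRUE), 2)
    gk <- toy_geno(calls)
    expect_equal(suppressWarnings(ibs_pairwise(gk, 1, 2)),
                 suppressWarnings(ibs_pairwise(gk, 2, 1)))
  }
})

test_that("individual IBS summary is the mean of the pairwise distribution", {
  expect_equal(ibs_individual_summary(c(0.8, 0.9)), 0.85)
  expect_equal(ibs_individual_summary(0.7), 0.7)       # population of two
  expect_equal(ibs_individual_summary(rep(0.42, 5)), 0.42)
  expect_warning(res <- ibs_individual_summary(numeric(0)))
  expect_true(is.na(res))
})

test_that("RoH calling matches the window-enumeration oracle on a constructed run", {
  # 60 evenly spaced homozygous SNPs (49 kb apart, within the density limit)
  # with one interior het, dense heterozygous flanks on both sides
  bp <- c(seq(5e4, 1.0e6, by = 5e4),                   # 20 het flank SNPs
          seq(1.1e6, 1.1e6 + 59 * 49e3, by = 49e3),    # the homozygous run
          seq(4.1e6, 5.05e6, by = 5e4))                # het flank
  x <- c(rep(1L, 20), rep(2L, 60), rep(1L, 20))
  x[20 + 30] <- 1L                                     # one interior het
  g <- toy_geno(matrix(x, 1), bp = round(bp))
  params <- roh_params()
  segs <- call_roh(g, 1, params)
  orc <- roh_oracle(g$calls[1, ], g$variants$bp, params)
  expect_equal(nrow(segs), nrow(orc))
  expect_equal(segs$start_bp, unname(orc[, "start_bp"]))
  expect_equal(segs$end_bp, unname(orc[, "end_bp"]))
  expect_equal(segs$n_snps, unname(orc[, "n_snps"]))
  expect_equal(nrow(segs), 1)   # a single segment spanning the run
  expect_gte(segs$end_bp[1] - segs$start_bp[1], 2.5e6)
  # fully heterozygous sample: no segments
  g_het <- toy_geno(matrix(1L, 1, 120), bp = seq(1e5, 12e6, length.out = 120))
  expect_equal(nrow(call_roh(g_het, 1, params)), 0)
})

test_that("RoH calling equals the oracle on random instances", {
  params <- roh_params()
  for (seed in 1:40) {
    inst <- random_roh_instance(300, seed)
    g <- toy_geno(matrix(inst$x, 1), bp = inst$bp)
    segs <- call_roh(g, 1, params)
    orc <- roh_oracle(inst$x, inst$bp, params)
    expect_equal(nrow(segs), nrow(orc))
    if (nrow(orc)) {
      expect_equal(segs$start_bp, unname(orc[, "start_bp"]))
      expect_equal(segs$end_bp, unname(orc[, "end_bp"]))
      expect_equal(segs$n_snps, unname(orc[, "n_snps"]))
    }
  }
})

test_that("adding heterozygous calls shrinks eligibility and raw run length", {
  # Monotonicity holds at the scanning level (the eligible-SNP set can only
  # shrink) and for the emitted length when the segment-level density and
  # minimum filters are disabled. With those filters active the full
  # algorithm is NOT monotone: splitting a run that failed the density
  # constraint can create passing pieces.
  params_raw <- roh_params(min_kb = 0, min_snp = 1, density_kb = Inf)
  params <- roh_params()
  set.seed(9)
  for (k in 1:15) {
    inst <- random_roh_instance(250, 100 + k)
    x <- inst$x
    elig0 <- isohet:::roh_eligible(x, inst$bp, params)
    g <- toy_geno(matrix(x, 1), bp = inst$bp)
    kb0 <- sum(call_roh(g, 1, params_raw)$length_kb)
    hom_idx <- which(!is.na(x) & x != 1L)
    if (!length(hom_idx)) next
    x2 <- x
    x2[sample(hom_idx, min(5, length(hom_idx)))] <- 1L
    elig2 <- isohet:::roh_eligible(x2, inst$bp, params)
    expect_true(all(!elig2 | elig0))   # eligible set is a subset
    g2 <- toy_geno(matrix(x2, 1), bp = inst$bp)
    expect_lte(sum(call_roh(g2, 1, params_raw)$length_kb), kb0)
  }
})

test_that("RoH summaries count and sum segments, boundary inclusive", {
  segs <- data.frame(sample = c("a", "a", "b"), chrom = "1",
                     start_bp = c(1e6, 5e6, 1e6),
                     end_bp = c(1.6e6, 6.4e6, 1.5e6),
                     n_snps = c(20L, 40L, 15L),
                     length_kb = c(600, 1400, 500))
  expect_equal(roh_summaries(segs, "a"),
               c(roh_nseg = 2, roh_kb = 2000))
  expect_equal(roh_summaries(segs, "b"), c(roh_nseg = 1, roh_kb = 500))
  expect_equal(roh_summaries(segs, "c"), c(roh_nseg = 0, roh_kb = 0))
})

test_that("F_ROH is the masked-genome RoH fraction with truncation", {
  segs <- data.frame(sample = "a", chrom = "1", start_bp = 10e6,
                     end_bp = 20e6, n_snps = 200L, length_kb = 10000)
  expect_equal(f_roh(segs, 100000), 0.1)
  expect_equal(f_roh(segs[0, ], 100000), 0)
  # segment covering the full unmasked extent
  segs_full <- data.frame(sample = "a", chrom = "1", start_bp = 0,
                          end_bp = 1e8, n_snps = 999L, length_kb = 1e5)
  expect_equal(f_roh(segs_full, 100000), 1)
  # mask overlapping the segment truncates it and shrinks the denominator
  mask <- data.frame(chrom = "1", start_bp = 15e6, end_bp = 25e6)
  expect_equal(f_roh(segs, 100000, mask), 5000 / 90000)
})

test_that("implanted autozygosity is recovered by calling, with matching truth", {
  map <- make_map(4, 150)
  set.seed(21)
  sim <- simulate_population(stats::runif(nrow(map), 0.2, 0.8), 12, 0.05,
                             map, seed = 31, population = "ISO",
                             group = "isolated")
  segs <- call_roh_all(sim$geno)
  ext <- genome_extent_kb(sim$geno)
  fr <- vapply(sim$geno$samples$id, function(s)
    f_roh(segs[segs$sample == s, , drop = FALSE], ext), numeric(1))
  expect_gt(mean(fr), 0.03)
  expect_lt(mean(fr), 0.07)
  # called segments overlap the implanted truth (Jaccard on covered length)
  jacc <- vapply(sim$geno$samples$id, function(s) {
    tr <- sim$truth_segments[sim$truth_segments$sample == s, , drop = FALSE]
    sg <- segs[segs$sample == s, , drop = FALSE]
    if (!nrow(tr) && !nrow(sg)) return(NA_real_)
    grid <- map
    in_tr <- rep(FALSE, nrow(grid)); in_sg <- rep(FALSE, nrow(grid))
    for (r in seq_len(nrow(tr)))
      in_tr <- in_tr | (grid$chrom == tr$chrom[r] & grid$cm >= tr$start_cm[r] &
                          grid$cm <= tr$end_cm[r])
    for (r in seq_len(nrow(sg)))
      in_sg <- in_sg | (grid$chrom == sg$chrom[r] & grid$bp >= sg$start_bp[r] &
                          grid$bp <= sg$end_bp[r])
    sum(in_tr & in_sg) / sum(in_tr | in_sg)
  }, numeric(1))
  expect_gte(mean(jacc, na.rm = TRUE), 0.7)
})
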