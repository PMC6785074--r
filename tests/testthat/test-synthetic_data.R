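# The scenario generator: determinism, analytic expectations, and the
# structural properties downstream modules rely on.

test_that("generators are seed-deterministic", {
  fr1 <- simulate_frequencies(500, c(A = 0.05, B = 0.1), seed = 3)
  fr2 <- simulate_frequencies(500, c(A = 0.05, B = 0.1), seed = 3)
  expect_identical(fr1, fr2)
  map <- make_map(1, 50, 300)
  s1 <- simulate_population(fr1$pops[, 1][1:300], 4, 0.02, map, seed = 5)
  s2 <- simulate_population(fr1$pops[, 1][1:300], 4, 0.02, map, seed = 5)
  expect_identical(s1$haps$haps, s2$haps$haps)
  t1 <- simulate_tracts(5, 0.3, c(100, 100), 3, seed = 7)
  t2 <- simulate_tracts(5, 0.3, c(100, 100), 3, seed = 7)
  expect_identical(t1, t2)
})

test_that("Balding-Nichols drift matches its analytic expectation", {
  fr <- simulate_frequencies(10000, c(A = 0.1, B = 0.1, C = 1e-12), seed = 11)
  # drift -> 0 limit: population frequencies equal the ancestral ones
  expect_equal(fr$pops[, "C"], fr$ancestral, tolerance = 1e-9)
  # Nei-style FST between ancestral and a drifted population equals F:
  # E[(p_A - pbar)^2] = F pbar (1 - pbar)
  v <- (fr$pops[, "A"] - fr$ancestral)^2
  expected <- 0.1 * fr$ancestral * (1 - fr$ancestral)
  expect_lt(abs(mean(v) / mean(expected) - 1), 0.2)
  expect_true(all(fr$ancestral >= 0.05 & fr$ancestral <= 0.95))
})

test_that("heterozygosity matches 2p(1-p)(1 - autozygosity)", {
  map <- make_map(2, 150, 1500)
  set.seed(13)
  p <- stats::runif(nrow(map), 0.2, 0.8)
  for (az in c(0, 0.1)) {
    sim <- simulate_population(p, 20, az, map, seed = 17 + round(100 * az))
    het_obs <- mean(sim$geno$calls == 1L)
    het_exp <- mean(2 * p * (1 - p)) * (1 - az)
    expect_lt(abs(het_obs / het_exp - 1), 0.1)
  }
  # autozygosity 0: essentially no RoH are called
  sim0 <- simulate_population(p, 8, 0, map, seed = 19)
  expect_lte(sum(call_roh_all(sim0$geno)$length_kb), 0.005 *
               genome_extent_kb(sim0$geno) * 8)
})

test_that("admixture switch counts match the analytic Markov expectation", {
  # g = 1, alpha = 0.5, L = 35 M: expected 2 g a(1-a) L = 17.5 per haplotype
  tr <- simulate_tracts(1, 0.5, rep(500, 7), 40, seed = 23)
  s <- count_switches(tr)
  expect_lt(abs(mean(s) / 2 / 17.5 - 1), 0.15)   # two haplotypes per sample
  # alpha near 1: almost no source-B tracts
  tr2 <- simulate_tracts(5, 0.95, rep(500, 7), 10, seed = 29)
  b_len <- sum((tr2$end_cm - tr2$start_cm)[tr2$ancestry == "B"])
  expect_lt(b_len / sum(tr2$end_cm - tr2$start_cm), 0.1)
  # generator's own tally is reproduced by count_switches (round trip)
  expect_equal(count_switches(tr), count_switches(ancestry_tracts(tr)))
})

test_that("admixed haplotypes carry the tract alleles they claim", {
  map <- make_map(1, 100, 500)
  fa <- rep(0.99, 500)   # source A nearly fixed for allele 1
  fb <- rep(0.01, 500)   # source B nearly fixed for allele 0
  ad <- simulate_admixed(fa, fb, g = 4, alpha = 0.4, map, 5, seed = 31)
  for (i in 1:5) for (hp in 1:2) {
    tr <- ad$truth_tracts[ad$truth_tracts$sample ==
                            ad$haps$samples$id[i] &
                            ad$truth_tracts$hap == hp, ]
    hap <- ad$haps$haps[2 * (i - 1) + hp, ]
    for (r in seq_len(nrow(tr))) {
      sel <- map$cm >= tr$start_cm[r] & map$cm < tr$end_cm[r]
      if (sum(sel) < 10) next    # tiny tracts are too noisy to classify
      frac1 <- mean(hap[sel])
      if (tr$ancestry[r] == "A") expect_gt(frac1, 0.8) else
        expect_lt(frac1, 0.2)
    }
  }
})

test_that("the default scenario has the documented structure", {
  cfg <- scenario_config(seed = 7, map = make_map(3, 150, 1200))
  sc <- build_scenario(cfg)
  expect_equal(nrow(sc$geno$calls), 8 * 20 + 4 * 24)
  expect_equal(length(sc$truth$admixed_ids), 12)   # half of the 24-strong isolate
  expect_true(all(sc$truth$admixed_ids %in%
                    sc$geno$samples$id[sc$geno$samples$population == "ISO1"]))
  expect_setequal(unique(sc$geno$samples$group), c("open", "isolated"))
  # truth Q rows sum to 1 and pure individuals are (1, 0)
  pure <- setdiff(sc$geno$samples$id, sc$truth$admixed_ids)
  expect_true(all(sc$q[pure, 1] == 1))
  expect_true(all(sc$q[sc$truth$admixed_ids, 2] > 0))
  # deterministic rebuild
  sc2 <- build_scenario(cfg)
  expect_identical(sc$geno$calls, sc2$geno$calls)
  expect_identical(sc$q, sc2$q)
  # config validation names the offending fields
  expect_error(scenario_config(pulse_alpha = 1.5), "pulse_alpha")
  expect_error(scenario_config(open_fst = 0), "open_fst")
})

test_that("a scenario round-trips losslessly through the PLINK writer/reader", {
  cfg <- scenario_config(n_open = 2L, n_isolate = 1L, open_n = 6L,
                         isolate_n = 8L, map = make_map(2, 60, 500),
                         seed = 37)
  sc <- build_scenario(cfg)
  dir <- tempfile()
  write_scenario(sc, dir)
  g2 <- read_plink(file.path(dir, "scenario"),
                   groups = c(OPEN1 = "open", OPEN2 = "open",
                              ISO1 = "isolated"))
  expect_equal(unname(g2$calls), unname(sc$geno$calls))
  expect_equal(g2$samples$id, sc$geno$samples$id)
  expect_equal(g2$samples$population, sc$geno$samples$population)
  expect_equal(g2$samples$group, sc$geno$samples$group)
  expect_equal(g2$variants$bp, sc$geno$variants$bp)
  # haplotypes round-trip through the phased VCF
  rv <- read_vcf(file.path(dir, "scenario.vcf"))
  expect_equal(unname(rv$haps$haps), unname(sc$haps$haps))
  # tracts round-trip through the per-site layout
  tr2 <- read_rfmix_tracts(file.path(dir, "scenario.sites.txt"),
                           sc$geno$variants[, c("chrom", "cm")],
                           sc$geno$samples$id)
  a1 <- ancestry_proportions(sc$truth$tracts, "SRC")
  a2 <- ancestry_proportions(tr2, "SRC")
  expect_equal(unname(a2[names(a1)]), unname(a1), tolerance = 0.05)
})
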