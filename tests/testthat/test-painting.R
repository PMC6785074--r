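# Copying-model painting: forward-backward correctness, conservation
# invariants, EM behaviour, CHR_P reduction and the switch error rate.

test_that("forward-backward equals the path-enumeration oracle", {
  set.seed(59)
  for (k in 1:12) {
    T <- sample(2:6, 1); D <- sample(2:3, 1)
    hap <- sample(0:1, T, TRUE)
    donors <- matrix(sample(0:1, D * T, TRUE), D, T)
    cm <- cumsum(c(0, stats::runif(T - 1, 0.5, 4)))
    Ne <- stats::runif(1, 10, 200); theta <- stats::runif(1, 0.01, 0.2)
    fb <- isohet:::paint_fb(hap, donors, cm, Ne, theta)
    orc <- paint_oracle(hap, donors, cm, Ne, theta)
    expect_lt(max(abs(fb$gamma - orc$gamma)), 1e-10)
    expect_lt(max(abs(rowSums(fb$switch_in) - orc$switch_into)), 1e-10)
    # posteriors sum to one at every site
    expect_lt(max(abs(colSums(fb$gamma) - 1)), 1e-9)
  }
})

test_that("chunk lengths are conserved and counts sum to switches + 1", {
  set.seed(61)
  T <- 120; D <- 6
  donors <- matrix(sample(0:1, D * T, TRUE), D, T)
  hap <- donors[1, ]
  cm <- cumsum(c(0, stats::runif(T - 1, 0.05, 0.5)))
  p <- paint_recipient(hap, donors, cm, Ne = 50, theta = 0.01)
  expect_equal(sum(p$chunk_length_cm), max(cm) - min(cm), tolerance = 1e-6)
  # a recipient identical to donor 1 copies almost everything from it
  expect_gt(p$chunk_length_cm[1] / sum(p$chunk_length_cm), 0.95)
  # uninformative emission: length split uniformly across donors
  pu <- paint_recipient(hap, donors, cm, Ne = 50, theta = 0.5)
  expect_equal(pu$chunk_length_cm, rep(sum(pu$chunk_length_cm) / D, D),
               tolerance = 1e-9)
})

test_that("doubling Ne increases the expected number of switches", {
  set.seed(67)
  T <- 80; D <- 4
  donors <- matrix(sample(0:1, D * T, TRUE), D, T)
  hap <- ifelse(stats::runif(T) < 0.1, 1L - donors[2, ], donors[2, ])
  cm <- seq(0, 40, length.out = T)
  n_switch <- function(Ne) {
    p <- paint_recipient(hap, donors, cm, Ne = Ne, theta = 0.02)
    sum(p$chunk_count) - 1
  }
  expect_gt(n_switch(100), n_switch(50))
  expect_gt(n_switch(200), n_switch(100))
})

test_that("coancestry invariants hold on the copying-pool scenario", {
  cp <- simulate_copying_pool(8, 8, make_map(2, 60, 400), seed = 71)
  co <- coancestry_matrix(cp$haps, Ne = 80, theta = 0.01)
  map_len <- 2 * sum(tapply(cp$haps$variants$cm, cp$haps$variants$chrom, max) -
                       tapply(cp$haps$variants$cm, cp$haps$variants$chrom, min))
  # each recipient's copied length sums to twice the painted map length
  # (two haplotypes)
  row_tot <- rowSums(co$chunk_length_cm, na.rm = TRUE)
  expect_equal(unname(row_tot), rep(map_len, 8), tolerance = 1e-6)
  # diagonal excluded
  expect_true(all(is.na(diag(co$chunk_length_cm))))
  # CHR_P reduction: median over donors
  expect_equal(chrp_individual(list(chunk_length_cm =
    matrix(c(NA, 10, 20, 30), 1, 4,
           dimnames = list("x", c("x", "a", "b", "c")))), "x"), 20)
  v <- chrp_all(co)
  expect_true(all(is.finite(v)))
  # two-member population: the single donor total
  cp2 <- simulate_copying_pool(4, 2, make_map(1, 30, 200), seed = 73)
  co2 <- coancestry_matrix(cp2$haps, Ne = 50, theta = 0.01)
  id <- cp2$haps$samples$id
  expect_equal(chrp_individual(co2, id[1]), co2$chunk_length_cm[id[1], id[2]])
})

test_that("EM is stable at the generating parameters and honours iterations = 0", {
  set.seed(79)
  map <- make_map(2, 300, 1500)
  V <- nrow(map)
  n <- 8
  freqs <- stats::runif(V, 0.1, 0.9)
  haps <- matrix(as.integer(stats::runif(2 * n * V) <
                              rep(freqs, each = 2 * n)), 2 * n, V)
  # regenerate sample 1's haplotypes by copying from samples 2..n under the
  # model itself, so the generating (Ne, theta) are the truth for recipient 1
  Ne_true <- 120; theta_true <- 0.03
  D <- 2 * (n - 1)
  donor_rows <- 3:(2 * n)
  for (r in 1:2) {
    cur <- sample.int(D, 1)
    hap <- integer(V)
    for (t in seq_len(V)) {
      if (t > 1 && map$chrom[t] == map$chrom[t - 1]) {
        rho <- 1 - exp(-Ne_true * (map$cm[t] - map$cm[t - 1]) / 100 / D)
        if (stats::runif(1) < rho) cur <- sample.int(D, 1)
      } else if (t > 1) cur <- sample.int(D, 1)
      hap[t] <- haps[donor_rows[cur], t]
    }
    flip <- stats::runif(V) < theta_true
    hap[flip] <- 1L - hap[flip]
    haps[r, ] <- hap
  }
  h <- hap_matrix(haps, map, data.frame(id = paste0("s", 1:n),
                                        population = "P", group = "isolated"))
  em0 <- em_fit_parameters(h, iterations = 0, Ne0 = Ne_true,
                           theta0 = theta_true)
  expect_equal(em0$Ne, Ne_true)
  expect_equal(em0$theta, theta_true)
  em <- em_fit_parameters(h, iterations = 2, Ne0 = Ne_true,
                          theta0 = theta_true, max_recipients = 1)
  expect_lt(abs(em$Ne - Ne_true) / Ne_true, 0.2)
  expect_lt(abs(em$theta - theta_true) / theta_true, 0.2)
  # likelihood trace is non-decreasing
  expect_true(all(diff(em$loglik) > -1e-6))
})

test_that("switch error rate counts phase flips up to global swap", {
  map <- make_map(1, 50, 400)
  set.seed(83)
  sim <- simulate_population(stats::runif(400, 0.3, 0.7), 4, 0, map,
                             seed = 89, population = "P", group = "open")
  h <- sim$haps
  expect_equal(switch_error_rate(h, h, "P_1"), 0)
  # full haplotype swap: SER still 0
  swapped <- h
  r <- hap_rows(h, "P_1")
  swapped$haps[r, ] <- h$haps[rev(r), ]
  expect_equal(switch_error_rate(h, swapped, "P_1"), 0)
  # constructed flips over 5 het sites: orientation pattern F,T,T,F,F has
  # two phase changes among four adjacent pairs -> 2/4
  v5 <- data.frame(id = paste0("v", 1:5), chrom = "1", bp = 1:5 * 1e6,
                   cm = 1:5, a1 = "A", a2 = "B")
  smp <- data.frame(id = "x", population = "P", group = "open")
  truth <- hap_matrix(rbind(c(0L, 1L, 0L, 1L, 0L),
                            c(1L, 0L, 1L, 0L, 1L)), v5, smp)
  inferred <- hap_matrix(rbind(c(0L, 0L, 1L, 1L, 0L),
                               c(1L, 1L, 0L, 0L, 1L)), v5, smp)
  expect_equal(switch_error_rate(truth, inferred, "x"), 0.5)
  # fully alternating truth vs constant inference: every pair flips
  constant <- hap_matrix(rbind(rep(0L, 5), rep(1L, 5)), v5, smp)
  expect_equal(switch_error_rate(truth, constant, "x"), 1)
})

test_that("chunklength matrices round-trip through the text layout", {
  m <- matrix(c(NA, 1.5, 2.5, NA), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile()
  write_chunklengths(m, f)
  m2 <- read_chunklengths(f)
  expect_equal(m2, m)
})
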