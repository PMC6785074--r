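# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (enumeration / direct-formula / brute force)
# and never share code with the implementation they check.

# --- fixtures ---------------------------------------------------------------

toy_geno <- function(calls, bp = NULL, chrom = NULL, populations = "P1",
                     groups = "open") {
  calls <- as.matrix(calls)
  n <- nrow(calls); V <- ncol(calls)
  bp <- bp %||% (seq_len(V) * 1000)
  chrom <- chrom %||% rep("1", V)
  variants <- data.frame(id = paste0("v", seq_len(V)), chrom = chrom,
                         bp = bp, cm = bp / 1e6, a1 = "A", a2 = "B",
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = paste0("s", seq_len(n)),
                        population = rep_len(populations, n),
                        group = rep_len(groups, n), stringsAsFactors = FALSE)
  geno_matrix(calls, variants, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- HWE enumeration oracle -------------------------------------------------

# full enumeration over heterozygote counts at fixed allele counts, weights
# from log-binomials (independent route from the package's ratio recurrence)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  nA <- 2 * n_AA + n_Aa
  if (na == 0 || nA == 0) return(1)
  rare <- min(na, nA)
  hets <- seq(rare %% 2, rare, by = 2)
  logw <- vapply(hets, function(h) {
    nrr <- (rare - h) / 2
    ncc <- n - (rare + h) / 2
    lfactorial(n) - lfactorial(h) - lfactorial(nrr) - lfactorial(ncc) +
      h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  obs <- p[hets == n_Aa]
  sum(p[p <= obs * (1 + 1e-12)])
}

# --- Mann-Whitney enumeration oracle ---------------------------------------

# exhaustive two-sided p over all group assignments (no ties assumed)
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  U_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  Us <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# --- Brown-Forsythe direct-formula oracle ----------------------------------

# statistic via anova on absolute deviations from group medians
bf_oracle <- function(groups) {
  z <- unlist(lapply(groups, function(v) abs(v - stats::median(v))))
  f <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ f))
  list(statistic = a[1, "F value"], p = a[1, "Pr(>F)"])
}

# --- RoH window-enumeration oracle -----------------------------------------

# literal transcription of the two-phase definition with explicit loops
roh_oracle <- function(x, bp, params) {
  T <- length(x)
  W <- params$window_snp
  elig <- rep(FALSE, T)
  if (T >= W) {
    S <- T - W + 1
    hom_w <- valid_w <- rep(FALSE, S)
    for (s in seq_len(S)) {
      w <- s:(s + W - 1)
      valid_w[s] <- (bp[max(w)] - bp[min(w)]) <= params$window_kb * 1000
      nhet <- sum(x[w] == 1, na.rm = TRUE)
      nmis <- sum(is.na(x[w]))
      hom_w[s] <- valid_w[s] && nhet <= params$window_het &&
        nmis <= params$window_missing
    }
    for (t in seq_len(T)) {
      ws <- intersect(seq_len(S), (t - W + 1):t)
      nv <- sum(valid_w[ws])
      if (nv > 0 && sum(hom_w[ws]) / nv >= params$window_threshold)
        elig[t] <- TRUE
    }
  }
  segs <- list()
  t <- 1
  while (t <= T) {
    if (!elig[t]) { t <- t + 1; next }
    j <- t
    while (j < T && elig[j + 1] && (bp[j + 1] - bp[j]) <=
           params$max_gap_kb * 1000) j <- j + 1
    span_kb <- (bp[j] - bp[t]) / 1000
    nsnp <- if (params$count_mode == "all") j - t + 1 else
      sum(!is.na(x[t:j]) & x[t:j] != 1)
    if (span_kb >= params$min_kb && nsnp >= params$min_snp &&
        span_kb / max(nsnp, 1) <= params$density_kb)
      segs[[length(segs) + 1]] <- c(start_bp = bp[t], end_bp = bp[j],
                                    n_snps = nsnp)
    t <- j + 1
  }
  if (length(segs)) do.call(rbind, segs) else
    matrix(numeric(0), 0, 3,
           dimnames = list(NULL, c("start_bp", "end_bp", "n_snps")))
}

# --- Li & Stephens path-enumeration oracle ----------------------------------

paint_oracle <- function(hap, donors, cm, Ne, theta) {
  D <- nrow(donors); T <- length(hap)
  rho <- 1 - exp(-Ne * diff(cm) / 100 / D)
  paths <- as.matrix(expand.grid(rep(list(seq_len(D)), T)))
  pr <- apply(paths, 1, function(p) {
    w <- 1 / D * (if (donors[p[1], 1] == hap[1]) 1 - theta else theta)
    if (T > 1) for (t in 2:T) {
      a <- if (p[t] == p[t - 1]) 1 - rho[t - 1] + rho[t - 1] / D else
        rho[t - 1] / D
      w <- w * a * (if (donors[p[t], t] == hap[t]) 1 - theta else theta)
    }
    w
  })
  pr <- pr / sum(pr)
  gamma <- matrix(0, D, T)
  for (t in seq_len(T)) for (d in seq_len(D))
    gamma[d, t] <- sum(pr[paths[, t] == d])
  sw <- rep(0, D)
  if (T > 1) for (t in 2:T) for (d in seq_len(D))
    sw[d] <- sw[d] + sum(pr[paths[, t] == d & paths[, t - 1] != d])
  list(gamma = gamma, switch_into = sw)
}

# random small genotype vector for RoH property tests: blocks of homozygous
# stretches interrupted by hets/missing, irregular spacing
random_roh_instance <- function(T = 300, seed = 1) {
  set.seed(seed)
  # spacing ~40 kb so runs can satisfy the 50 kb/SNP density constraint
  bp <- sort(sample.int(12e6, T))
  x <- sample(c(0L, 2L), T, replace = TRUE)
  # sprinkle hets and missing at random density
  nh <- rpois(1, T * runif(1, 0.005, 0.15))
  x[sample.int(T, min(nh, T))] <- 1L
  nm <- rpois(1, T * 0.02)
  x[sample.int(T, min(nm, T))] <- NA_integer_
  list(x = x, bp = bp)
}
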