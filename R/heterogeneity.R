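# Variance-based inter-individual heterogeneity: the central framework.
# Individual diversity values are summarised per population by their sample
# variance; populations are then compared by Brown-Forsythe Levene tests with
# Bonferroni correction, and the open/isolated groups by Mann-Whitney tests.

#' Sample variance of individual values within one population
#'
#' @param values numeric vector of per-individual measures.
#' @param population optional label, used in messages only.
#' @return Unbiased sample variance (n - 1 divisor); `NA` with a warning when
#'   fewer than two non-missing values are available.
#' @export
population_variance <- function(values, population = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    return(undefined_result(sprintf(
      "population %s has fewer than 2 individuals", population %||% "?")))
  stats::var(values)
}

#' Variance table over populations and measures
#'
#' @param data data.frame of per-individual values with a `population` column.
#' @param measures character vector of measure column names.
#' @return Long data.frame: `population`, `measure`, `n`, `variance`.
#' @export
variance_table <- function(data, measures) {
  out <- expand.grid(population = unique(data$population), measure = measures,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$variance <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- data[data$population == out$population[r], out$measure[r]]
    out$n[r] <- sum(!is.na(v))
    out$variance[r] <- suppressWarnings(population_variance(v))
  }
  out
}

#' PCA centroid distances per population
#'
#' For each population the centroid on two ordination axes is the per-axis
#' mean; each sample's heterogeneity contribution is its Euclidean distance
#' \eqn{\sqrt{(x - \bar x)^2 + (y - \bar y)^2}} from its own population's
#' centroid. Per-population median and variance of these distances summarise
#' the scatter.
#'
#' @param coords two-column matrix/data.frame of per-sample axis scores.
#' @param populations population label per sample.
#' @return List with `distances` (per-sample data.frame) and `summary`
#'   (per-population median and variance of distances).
#' @export
pca_centroid_distances <- function(coords, populations) {
  coords <- as.matrix(coords)
  assert_that(ncol(coords) == 2L, "coords must have exactly two axes")
  cx <- stats::ave(coords[, 1], populations)
  cy <- stats::ave(coords[, 2], populations)
  d <- sqrt((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2)
  distances <- data.frame(population = populations, distance = d,
                          stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(d, populations), function(v)
    data.frame(median = stats::median(v),
               variance = if (length(v) > 1) stats::var(v) else NA_real_)))
  summary <- data.frame(population = rownames(summary), summary,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(distances = distances, summary = summary)
}

#' Principal components of a genotype matrix
#'
#' Convenience wrapper: mean-imputes missing calls, centres (optionally
#' scales) and eigen-decomposes via [stats::prcomp()]. Only the downstream
#' centroid statistics are part of this package's analysis surface.
#'
#' @param g a [geno_matrix()].
#' @param n_axes number of components to return.
#' @param scale. divide variants by their standard deviation.
#' @return Matrix of per-sample scores (samples x n_axes).
#' @export
geno_pca <- function(g, n_axes = 4L, scale. = FALSE) {
  X <- g$calls
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  pc$x[, seq_len(min(n_axes, ncol(pc$x))), drop = FALSE]
}

#' Brown-Forsythe Levene test for equality of variances
#'
#' The Levene statistic computed on absolute deviations from each group's
#' median, referred to the F distribution with (k - 1, N - k) degrees of
#' freedom. Robust to non-normality; the workhorse of all pairwise
#' heterogeneity comparisons here.
#'
#' @param groups list of two or more numeric vectors (each of length >= 2).
#' @return List with `statistic`, `p`, `df1`, `df2`. When every group has zero
#'   spread around its median the test is degenerate: `statistic = NA`,
#'   `p = NA`, with a warning.
#' @export
brown_forsythe_levene <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2L,
              "need a list of at least two groups")
  groups <- lapply(groups, function(v) v[!is.na(v)])
  assert_that(all(lengths(groups) >= 2L), "each group needs >= 2 values")
  k <- length(groups)
  z <- lapply(groups, function(v) abs(v - stats::median(v)))
  n <- lengths(z)
  N <- sum(n)
  zbar_g <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(n * (zbar_g - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_g[i])^2),
                          numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ss_within == 0 && ss_between == 0) {
    warning("degenerate Levene test: zero deviation in every group",
            call. = FALSE)
    return(list(statistic = NA_real_, p = NA_real_, df1 = df1, df2 = df2))
  }
  if (ss_within == 0) {
    # all spread is between groups: statistic diverges, p -> 0
    return(list(statistic = Inf, p = 0, df1 = df1, df2 = df2))
  }
  W <- (ss_between / df1) / (ss_within / df2)
  list(statistic = W, p = stats::pf(W, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Pairwise heterogeneity scan across populations
#'
#' Runs [brown_forsythe_levene()] for every unordered pair of populations and
#' every measure, applies Bonferroni correction per measure over the
#' comparisons actually performed, and counts, for each focal population, the
#' comparisons that are both significant and have the focal population's
#' standard deviation larger (`sd_ratio > 1`) — only the larger-SD side of a
#' pair is credited.
#'
#' For pairwise-based measures the per-individual value entering the scan
#' should be the median of the individual's pairwise distribution (use the
#' `ibs_median` / painting median columns).
#'
#' @param data data.frame of per-individual values with a `population` column.
#' @param measures measure column names to scan.
#' @param alpha family-wise significance level before correction; default 0.05.
#' @param family Bonferroni family definition: `"per_measure"` (default)
#'   divides alpha by the number of pairs tested within each measure;
#'   `"all"` divides by the total number of tests across measures.
#' @return List with `tests` (one row per pair x measure: `pop_a`, `pop_b`,
#'   `measure`, `statistic`, `p`, `sd_ratio` (a over b), `n_a`, `n_b`,
#'   `significant_bonferroni`) and `counts` (per population x measure
#'   significant-with-larger-SD counts, plus a `total` column per population).
#' @export
pairwise_heterogeneity_scan <- function(data, measures, alpha = 0.05,
                                        family = c("per_measure", "all")) {
  family <- match.arg(family)
  pops <- unique(data$population)
  assert_that(length(pops) >= 2L, "need at least two populations")
  pairs <- utils::combn(pops, 2L)
  rows <- list()
  for (m in measures) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      va <- data[data$population == a, m]; va <- va[!is.na(va)]
      vb <- data[data$population == b, m]; vb <- vb[!is.na(vb)]
      if (length(va) < 2L || length(vb) < 2L) next
      lt <- suppressWarnings(brown_forsythe_levene(list(va, vb)))
      sda <- stats::sd(va); sdb <- stats::sd(vb)
      rows[[length(rows) + 1L]] <- data.frame(
        pop_a = a, pop_b = b, measure = m, statistic = lt$statistic, p = lt$p,
        sd_ratio = sda / sdb, n_a = length(va), n_b = length(vb),
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  n_per_measure <- table(tests$measure)
  tests$n_comparisons <- if (family == "per_measure")
    as.integer(n_per_measure[tests$measure]) else nrow(tests)
  tests$significant_bonferroni <- !is.na(tests$p) &
    tests$p < alpha / tests$n_comparisons
  counts <- expand.grid(population = pops, measure = measures,
                        stringsAsFactors = FALSE)
  counts$count <- 0L
  for (r in seq_len(nrow(tests))) {
    if (!tests$significant_bonferroni[r]) next
    sdr <- tests$sd_ratio[r]
    if (is.na(sdr) || sdr == 1) next
    winner <- if (sdr > 1) tests$pop_a[r] else tests$pop_b[r]
    hit <- counts$population == winner & counts$measure == tests$measure[r]
    counts$count[hit] <- counts$count[hit] + 1L
  }
  totals <- stats::aggregate(count ~ population, counts, sum)
  names(totals)[2] <- "total"
  list(tests = tests, counts = counts, totals = totals)
}

#' Mann-Whitney comparison of population-level variances between groups
#'
#' Two-sided Mann-Whitney U test comparing the per-population variance values
#' of isolated populations against those of open populations. Exact
#' enumeration is used for combined n <= 20 without ties; otherwise the
#' midrank normal approximation with tie correction (no continuity
#' correction).
#'
#' @param isolated,open numeric vectors of population variance values.
#' @return The two-sided p-value.
#' @export
mann_whitney_group_test <- function(isolated, open) {
  isolated <- isolated[!is.na(isolated)]; open <- open[!is.na(open)]
  assert_that(length(isolated) >= 1L && length(open) >= 1L,
              "both groups must be non-empty")
  n <- length(isolated) + length(open)
  ties <- any(duplicated(c(isolated, open)))
  exact <- n <= 20L && !ties
  res <- suppressWarnings(stats::wilcox.test(isolated, open, exact = exact,
                                             correct = FALSE))
  unname(res$p.value)
}
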