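# Ancestry-proportion heterogeneity from ADMIXTURE-style Q matrices.

#' Construct/validate a Q matrix of ancestry proportions
#'
#' @param q numeric matrix or data.frame, individuals x K clusters; rows must
#'   sum to 1 within 1e-6 and entries lie in \[0, 1\].
#' @param samples sample ids (defaults to existing rownames).
#' @return Numeric matrix of class `q_matrix` with sample rownames.
#' @export
q_matrix <- function(q, samples = NULL) {
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  assert_that(all(q >= -1e-9 & q <= 1 + 1e-9), "proportions must be in [0,1]")
  assert_that(all(abs(rowSums(q) - 1) < 1e-6), "rows must sum to 1")
  rownames(q) <- samples %||% rownames(q) %||% paste0("ind", seq_len(nrow(q)))
  colnames(q) <- paste0("K", seq_len(ncol(q)))
  class(q) <- c("q_matrix", class(q))
  q
}

#' Read an ADMIXTURE-format .Q file
#'
#' Plain text, one row per individual, K whitespace-separated proportions;
#' sample order is supplied separately (e.g. from the .fam file).
#'
#' @param file path to the .Q file.
#' @param samples character vector of sample ids in file order.
#' @return A [q_matrix()].
#' @export
read_q_matrix <- function(file, samples = NULL) {
  q <- as.matrix(utils::read.table(file, header = FALSE))
  q_matrix(q, samples = samples)
}

#' Per-individual ancestry heterogeneity (ADX_HET)
#'
#' For individual i in population P with ancestry proportions
#' \eqn{q_{i1},\dots,q_{iK}}:
#' \deqn{ADX\_HET_i = \frac{1}{K} \sum_k (q_{ik} - \bar q_{Pk})^2}
#' the squared difference between each ancestry proportion and its population
#' mean, averaged over the K clusters. The population-level value is the
#' median of the individual scores.
#'
#' @param q a [q_matrix()].
#' @param populations population label per row of `q`.
#' @return List with `scores` (named per-individual vector) and `medians`
#'   (named per-population vector).
#' @export
adx_het <- function(q, populations) {
  assert_that(length(populations) == nrow(q),
              "one population label per Q row required")
  scores <- rep(NA_real_, nrow(q))
  names(scores) <- rownames(q)
  for (pop in unique(populations)) {
    idx <- which(populations == pop)
    assert_that(length(idx) >= 2L,
                sprintf("population %s has fewer than 2 individuals", pop))
    mu <- colMeans(q[idx, , drop = FALSE])
    dev <- sweep(q[idx, , drop = FALSE], 2L, mu)
    scores[idx] <- rowMeans(dev^2)
  }
  medians <- tapply(scores, populations, stats::median)
  list(scores = scores, medians = medians[unique(populations)])
}

#' Mean/median ratio of per-individual heterogeneity scores
#'
#' A ratio near 1 indicates heterogeneity evenly spread across individuals; a
#' large ratio flags a population whose heterogeneity is driven by a few
#' outlying genomes.
#'
#' @param scores per-individual heterogeneity values for one population.
#' @return mean/median; `NA` with a warning when the median is 0.
#' @export
mean_median_ratio <- function(scores) {
  scores <- scores[!is.na(scores)]
  md <- stats::median(scores)
  if (md == 0) return(undefined_result("median score is zero"))
  mean(scores) / md
}

#' Split a population into village-specific vs heterogeneous ancestry
#'
#' Individuals whose proportion of the focal ("village-specific") cluster
#' reaches `threshold` (default 99%) form the VSA sub-group; the rest form the
#' HTA (heterogeneous-ancestry) sub-group. The focal cluster defaults to the
#' cluster with the highest population-mean proportion.
#'
#' @param q a [q_matrix()].
#' @param populations population label per row.
#' @param population the population to split.
#' @param focal_cluster column index of the focal cluster, or `NULL` to pick
#'   the argmax of the population mean.
#' @param threshold VSA membership threshold; default 0.99.
#' @return List with character vectors `vsa` and `hta` of sample ids, and the
#'   `focal_cluster` used.
#' @export
split_vsa_hta <- function(q, populations, population, focal_cluster = NULL,
                          threshold = 0.99) {
  idx <- which(populations == population)
  assert_that(length(idx) >= 1L, sprintf("unknown population %s", population))
  sub <- q[idx, , drop = FALSE]
  fc <- focal_cluster %||% unname(which.max(colMeans(sub)))
  vsa <- rownames(sub)[sub[, fc] >= threshold]
  hta <- setdiff(rownames(sub), vsa)
  list(vsa = vsa, hta = hta, focal_cluster = fc)
}

#' Correlation between population inbreeding and ancestry heterogeneity
#'
#' Pearson product-moment correlation (with the usual two-sided t-based
#' p-value) between population-level inbreeding rates (e.g. the median F_ROH)
#' and population-level ADX_HET values.
#'
#' @param f_values per-population inbreeding values.
#' @param adx_values per-population ADX_HET values (same order).
#' @return List with `r` and `p`; `NA`s with a warning if either vector has
#'   zero variance.
#' @export
correlate_inbreeding_adxhet <- function(f_values, adx_values) {
  ok <- !is.na(f_values) & !is.na(adx_values)
  f <- f_values[ok]; a <- adx_values[ok]
  assert_that(length(f) >= 3L, "need at least three populations")
  if (stats::sd(f) == 0 || stats::sd(a) == 0) {
    warning("zero variance in one input; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(f, a, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
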