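# Quality control: call-rate filters, exact HWE, relatedness pruning.

#' Filter variants by genotyping call rate
#'
#' Retains exactly the variants whose fraction of non-missing calls is
#' strictly greater than `threshold` (a variant typed in 9 of 10 samples is
#' removed at `threshold = 0.9`). The conventional array-QC SNP filter uses
#' `threshold = 0.90`.
#'
#' @param g a [geno_matrix()].
#' @param threshold call-rate threshold in \[0, 1\]; default 0.90.
#' @return A `geno_matrix` with the surviving variants; a result with zero
#'   variants is returned (with a warning), never an error.
#' @export
filter_variants_by_call_rate <- function(g, threshold = 0.90) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0,1]")
  rate <- 1 - colMeans(is.na(g$calls))
  keep <- rate > threshold
  if (!any(keep)) warning("no variants survive the call-rate filter",
                          call. = FALSE)
  subset_geno(g, variants = which(keep))
}

#' Filter samples by genotyping call rate
#'
#' Row-wise analogue of [filter_variants_by_call_rate()]; the conventional
#' per-individual filter uses `threshold = 0.92`.
#'
#' @inheritParams filter_variants_by_call_rate
#' @param threshold call-rate threshold; default 0.92.
#' @return A `geno_matrix` with the surviving samples.
#' @export
filter_samples_by_call_rate <- function(g, threshold = 0.92) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0,1]")
  rate <- 1 - rowMeans(is.na(g$calls))
  keep <- rate > threshold
  if (!any(keep)) warning("no samples survive the call-rate filter",
                          call. = FALSE)
  subset_geno(g, samples = which(keep))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for one biallelic variant: conditional on the observed
#' allele counts, the probability of each possible heterozygote count is
#' evaluated and the p-value is the sum of probabilities not exceeding that of
#' the observed configuration. Probabilities are computed by the stable
#' ratio recurrence over heterozygote counts. A monomorphic variant returns 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers, not all 0).
#' @return The exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  assert_that(is_count(n_AA) && is_count(n_Aa) && is_count(n_aa),
              "genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  assert_that(n > 0, "at least one genotype count must be positive")
  n_a <- 2L * n_aa + n_Aa
  n_A <- 2L * n_AA + n_Aa
  if (n_a == 0L || n_A == 0L) return(1.0)
  rare <- min(n_a, n_A)
  common <- 2L * n - rare
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # At het count h: rare homozygotes (rare-h)/2, common homozygotes
  # n - (rare+h)/2. Ratio recurrence, anchored near the mode for stability:
  # p(h+2)/p(h) = 4 * n_rr(h) * n_cc(h) / ((h+2)(h+1)).
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * common / (2 * n)))
  probs[mid] <- 1
  if (mid < length(hets)) {
    for (k in mid:(length(hets) - 1L)) {
      h <- hets[k]
      ncc <- n - (rare + h) / 2; nrr <- (rare - h) / 2
      probs[k + 1L] <- probs[k] * 4 * ncc * nrr / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (k in mid:2L) {
      h <- hets[k]
      ncc <- n - (rare + h) / 2 + 1; nrr <- (rare - h) / 2 + 1
      probs[k - 1L] <- probs[k] * h * (h - 1) / (4 * ncc * nrr)
    }
  }
  probs <- probs / sum(probs)
  obs <- match(n_Aa, hets)
  assert_that(!is.na(obs), "heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Apply the HWE exclusion filter
#'
#' Drops variants showing a significant exact-test departure from
#' Hardy-Weinberg equilibrium. By default the test is run within each
#' population and a variant is excluded if it fails in any population
#' (`scope = "population"`); `scope = "cohort"` pools all samples.
#'
#' @param g a [geno_matrix()].
#' @param p_threshold exclusion p-value threshold; default `1e-6`.
#' @param scope `"population"` or `"cohort"`.
#' @return A `geno_matrix` without the failing variants; the removed variant
#'   ids are attached as attribute `"removed"`.
#' @export
filter_hwe <- function(g, p_threshold = 1e-6, scope = c("population", "cohort")) {
  scope <- match.arg(scope)
  groups <- if (scope == "cohort") list(seq_len(nrow(g$calls))) else
    split(seq_len(nrow(g$calls)), g$samples$population)
  fails <- rep(FALSE, ncol(g$calls))
  for (idx in groups) {
    cc <- g$calls[idx, , drop = FALSE]
    n0 <- colSums(cc == 0L, na.rm = TRUE)
    n1 <- colSums(cc == 1L, na.rm = TRUE)
    n2 <- colSums(cc == 2L, na.rm = TRUE)
    test <- !fails & (n0 + n1 + n2) > 0L
    p <- rep(1, ncol(cc))
    p[test] <- mapply(hwe_exact_test, n0[test], n1[test], n2[test])
    fails <- fails | p < p_threshold
  }
  out <- subset_geno(g, variants = which(!fails))
  attr(out, "removed") <- g$variants$id[fails]
  out
}

# per-variant alternate-allele frequencies from non-missing calls
allele_freqs <- function(g) {
  colMeans(g$calls, na.rm = TRUE) / 2
}

# per-pair IBS0/IBS1/IBS2 counts and moment expectations, all pairs at once;
# pairwise-complete in the presence of missing calls.
pihat_components <- function(g, freqs = NULL) {
  p <- freqs %||% allele_freqs(g)
  q <- 1 - p
  usable <- !is.na(p) & p > 0 & p < 1     # monomorphic variants carry no IBD info
  G <- g$calls[, usable, drop = FALSE]
  p <- p[usable]; q <- 1 - p
  A0 <- (!is.na(G) & G == 0L) * 1; A1 <- (!is.na(G) & G == 1L) * 1
  A2 <- (!is.na(G) & G == 2L) * 1
  M <- (!is.na(G)) * 1
  ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  ibs0 <- A0 %*% t(A2) + A2 %*% t(A0)
  nco <- M %*% t(M)
  ibs1 <- nco - ibs2 - ibs0
  # expected IBS-class probabilities given IBD state (method of moments)
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2
  # pair-specific expectation sums restricted to co-typed variants
  Mw <- function(w) M %*% (t(M) * w)  # sum_s w_s over variants co-typed in (i,j)
  list(ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2, nco = nco,
       E0_0 = Mw(e0_ibd0), E1_0 = Mw(e1_ibd0), E2_0 = Mw(e2_ibd0),
       E1_1 = Mw(e1_ibd1), E2_1 = Mw(e2_ibd1))
}

pihat_from_components <- function(cmp, i, j) {
  if (cmp$nco[i, j] == 0) return(NA_real_)
  P0 <- cmp$ibs0[i, j] / cmp$E0_0[i, j]
  P1 <- (cmp$ibs1[i, j] - P0 * cmp$E1_0[i, j]) / cmp$E1_1[i, j]
  P2 <- (cmp$ibs2[i, j] - P0 * cmp$E2_0[i, j] - P1 * cmp$E2_1[i, j]) /
    cmp$nco[i, j]
  ph <- P1 / 2 + P2
  min(1, max(0, ph))
}

#' Method-of-moments relatedness (PI_HAT) for one sample pair
#'
#' Estimates genome-wide identity-by-descent sharing from identity-by-state
#' counts and cohort allele frequencies:
#' \eqn{\hat\pi = P(IBD{=}1)/2 + P(IBD{=}2)}, clipped to \[0, 1\].
#' Frequencies default to the full cohort in `g`; monomorphic variants are
#' skipped and missing genotypes are excluded pairwise.
#'
#' @param g a [geno_matrix()].
#' @param i,j sample ids or row indices.
#' @param freqs optional per-variant alternate-allele frequencies.
#' @return PI_HAT in \[0, 1\], or `NA` (with warning) if the pair shares no
#'   co-typed variant.
#' @export
pairwise_pihat <- function(g, i, j, freqs = NULL) {
  if (is.character(i)) i <- match(i, g$samples$id)
  if (is.character(j)) j <- match(j, g$samples$id)
  sub <- subset_geno(g, samples = c(i, j))
  cmp <- pihat_components(sub, freqs = (freqs %||% allele_freqs(g))[
    match(sub$variants$id, g$variants$id)])
  out <- pihat_from_components(cmp, 1L, 2L)
  if (is.na(out)) return(undefined_result("no co-typed variants for the pair"))
  out
}

#' All pairwise PI_HAT values
#'
#' @inheritParams pairwise_pihat
#' @return A symmetric numeric matrix of PI_HAT estimates (diagonal `NA`).
#' @export
pihat_matrix <- function(g, freqs = NULL) {
  cmp <- pihat_components(g, freqs = freqs)
  n <- nrow(g$calls)
  out <- matrix(NA_real_, n, n, dimnames = list(g$samples$id, g$samples$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- pihat_from_components(cmp, i, j)
  }
  out
}

#' Prune related samples
#'
#' Scans all sample pairs for PI_HAT above `threshold` (default 0.185,
#' relatedness to roughly the third degree) and removes one member of each
#' related pair, chosen at random under `seed`, until no pair exceeds the
#' threshold.
#'
#' @param g a [geno_matrix()].
#' @param threshold PI_HAT cut-off; default 0.185.
#' @param seed integer seed controlling which member of a pair is dropped.
#' @return The pruned `geno_matrix`; the removal log (data.frame with columns
#'   `removed`, `kept`, `pihat`) is attached as attribute `"removal_log"`.
#' @export
prune_related <- function(g, threshold = 0.185, seed = 1L) {
  ph <- pihat_matrix(g)
  keep <- rep(TRUE, nrow(ph))
  log <- list()
  rng <- local({ set.seed(seed); function() runif(1) })
  repeat {
    act <- which(keep)
    sub <- ph[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    hit <- which(!is.na(sub) & sub > threshold, arr.ind = TRUE)
    if (nrow(hit) == 0L) break
    # resolve the worst pair first, then rescan
    worst <- hit[which.max(sub[hit]), , drop = FALSE]
    a <- act[worst[1, 1]]; b <- act[worst[1, 2]]
    drop <- if (rng() < 0.5) a else b
    keepr <- if (drop == a) b else a
    keep[drop] <- FALSE
    log[[length(log) + 1L]] <- data.frame(
      removed = g$samples$id[drop], kept = g$samples$id[keepr],
      pihat = ph[a, b], stringsAsFactors = FALSE)
  }
  out <- subset_geno(g, samples = which(keep))
  attr(out, "removal_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(removed = character(), kept = character(), pihat = numeric())
  out
}

#' Standard QC pipeline
#'
#' Applies, in order: the SNP call-rate filter, the individual call-rate
#' filter, the exact-HWE exclusion and relatedness pruning — the conventional
#' array QC chain for population-structure analyses.
#'
#' @param g a [geno_matrix()].
#' @param geno_rate,mind_rate call-rate thresholds for variants and samples.
#' @param hwe_p HWE exclusion threshold.
#' @param ibd_threshold PI_HAT pruning threshold.
#' @param seed seed for the random member choice in pruning.
#' @param hwe_scope see [filter_hwe()].
#' @return The filtered `geno_matrix` with the pruning `"removal_log"`
#'   attribute.
#' @export
qc_pipeline <- function(g, geno_rate = 0.90, mind_rate = 0.92, hwe_p = 1e-6,
                        ibd_threshold = 0.185, seed = 1L,
                        hwe_scope = "population") {
  g <- filter_variants_by_call_rate(g, geno_rate)
  g <- filter_samples_by_call_rate(g, mind_rate)
  g <- filter_hwe(g, hwe_p, scope = hwe_scope)
  prune_related(g, threshold = ibd_threshold, seed = seed)
}
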