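# Per-individual diversity: homozygosity, IBS, runs of homozygosity, F_ROH.

#' Proportion of homozygous loci for one individual
#'
#' @param g a [geno_matrix()].
#' @param sample sample id or row index.
#' @return Number of calls in {0, 2} over the number of non-missing calls;
#'   `NA` with a warning if the sample has no non-missing call.
#' @export
hom_per_individual <- function(g, sample) {
  if (is.character(sample)) sample <- match(sample, g$samples$id)
  x <- g$calls[sample, ]
  n <- sum(!is.na(x))
  if (n == 0L) return(undefined_result("sample has no non-missing calls"))
  sum(x == 0L | x == 2L, na.rm = TRUE) / n
}

# vectorised over all samples
hom_all <- function(g) {
  n <- rowSums(!is.na(g$calls))
  h <- rowSums(g$calls == 0L | g$calls == 2L, na.rm = TRUE)
  out <- ifelse(n > 0, h / n, NA_real_)
  names(out) <- g$samples$id
  out
}

#' Pairwise identity by state between two individuals
#'
#' Proportion of variants, among those non-missing in both samples, where the
#' two diploid genotype codes are identical.
#'
#' @param g a [geno_matrix()].
#' @param i,j sample ids or row indices.
#' @return IBS proportion in \[0, 1\]; `NA` with a warning if the pair has no
#'   co-typed variant.
#' @export
ibs_pairwise <- function(g, i, j) {
  if (is.character(i)) i <- match(i, g$samples$id)
  if (is.character(j)) j <- match(j, g$samples$id)
  a <- g$calls[i, ]; b <- g$calls[j, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(undefined_result("no co-typed variants for the pair"))
  sum(a[ok] == b[ok]) / sum(ok)
}

#' Summarise an individual's within-population IBS distribution
#'
#' The individual value is the mean (the usual convention) or the median (the
#' convention for variance-based heterogeneity scans of pairwise measures) of
#' the sample's pairwise IBS values against all other members of its
#' population.
#'
#' @param values numeric vector of the individual's pairwise IBS values.
#' @param stat `"mean"` or `"median"`.
#' @return A single summary proportion; `NA` with a warning for a singleton
#'   population (no pairwise values).
#' @export
ibs_individual_summary <- function(values, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    return(undefined_result("singleton population: no pairwise IBS values"))
  if (stat == "mean") mean(values) else stats::median(values)
}

#' Per-individual IBS summaries for every sample
#'
#' Computes all within-population pairwise IBS values and reduces each
#' individual's distribution with [ibs_individual_summary()].
#'
#' @param g a [geno_matrix()].
#' @param stat `"mean"` or `"median"`.
#' @return Named numeric vector, one value per sample (NA in singleton
#'   populations).
#' @export
ibs_per_individual <- function(g, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  out <- rep(NA_real_, nrow(g$calls))
  names(out) <- g$samples$id
  for (pop in unique(g$samples$population)) {
    idx <- which(g$samples$population == pop)
    if (length(idx) < 2L) next
    M <- ibs_matrix(g, idx)
    f <- if (stat == "mean") function(v) mean(v, na.rm = TRUE) else
      function(v) stats::median(v, na.rm = TRUE)
    out[idx] <- apply(M, 1L, function(v) f(v[!is.na(v)]))
  }
  out
}

# pairwise IBS matrix for the given sample rows (diagonal NA)
ibs_matrix <- function(g, idx) {
  G <- g$calls[idx, , drop = FALSE]
  A0 <- (!is.na(G) & G == 0L) * 1; A1 <- (!is.na(G) & G == 1L) * 1
  A2 <- (!is.na(G) & G == 2L) * 1
  M <- (!is.na(G)) * 1
  same <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  nco <- M %*% t(M)
  out <- same / nco
  diag(out) <- NA_real_
  out[nco == 0] <- NA_real_
  dimnames(out) <- list(g$samples$id[idx], g$samples$id[idx])
  out
}

#' RoH calling parameters
#'
#' Defaults are the PLINK-style settings used throughout: a scanning window of
#' 50 SNPs bounded at 5 Mb, allowing 1 heterozygous and 5 missing calls per
#' window, a window hit-fraction threshold of 0.05, and final segments of at
#' least 500 kb and 14 SNPs with at most 50 kb per SNP and gaps up to 1 Mb.
#'
#' @param window_kb maximal physical span (kb) for a scanning window.
#' @param window_snp number of consecutive SNPs per scanning window.
#' @param window_het,window_missing maximal heterozygous/missing calls for a
#'   window to count as homozygous.
#' @param window_threshold minimal fraction of homozygous windows covering a
#'   SNP for it to be RoH-eligible.
#' @param min_kb,min_snp minimal physical span (kb) and SNP count of an
#'   emitted segment.
#' @param density_kb maximal kb per SNP inside a segment.
#' @param max_gap_kb maximal gap (kb) between consecutive eligible SNPs; a
#'   larger gap splits the run.
#' @param count_mode `"all"` counts every SNP in the run towards `n_snps`
#'   (PLINK convention); `"homozygous"` counts homozygous calls only.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_kb = 5000, window_snp = 50, window_het = 1,
                       window_missing = 5, window_threshold = 0.05,
                       min_kb = 500, min_snp = 14, density_kb = 50,
                       max_gap_kb = 1000,
                       count_mode = c("all", "homozygous")) {
  structure(list(window_kb = window_kb, window_snp = window_snp,
                 window_het = window_het, window_missing = window_missing,
                 window_threshold = window_threshold, min_kb = min_kb,
                 min_snp = min_snp, density_kb = density_kb,
                 max_gap_kb = max_gap_kb, count_mode = match.arg(count_mode)),
            class = "roh_params")
}

# core of the scanning phase for one chromosome: returns the logical
# eligibility vector over the chromosome's SNPs
roh_eligible <- function(x, bp, params) {
  T <- length(x)
  W <- params$window_snp
  if (T < W) return(rep(FALSE, T))
  S <- T - W + 1L                     # number of window start positions
  het <- as.integer(!is.na(x) & x == 1L)
  mis <- as.integer(is.na(x))
  cs_h <- c(0L, cumsum(het)); cs_m <- c(0L, cumsum(mis))
  starts <- seq_len(S)
  nhet <- cs_h[starts + W] - cs_h[starts]
  nmis <- cs_m[starts + W] - cs_m[starts]
  valid <- (bp[starts + W - 1L] - bp[starts]) <= params$window_kb * 1000
  homw <- valid & nhet <= params$window_het & nmis <= params$window_missing
  # windows containing SNP t have starts in [t-W+1, t] clipped to [1, S]
  cs_hw <- c(0, cumsum(as.numeric(homw)))
  cs_v <- c(0, cumsum(as.numeric(valid)))
  t <- seq_len(T)
  lo <- pmax(1L, t - W + 1L); hi <- pmin(S, t)
  any_win <- hi >= lo
  hits <- nvalid <- numeric(T)
  hits[any_win] <- cs_hw[hi[any_win] + 1L] - cs_hw[lo[any_win]]
  nvalid[any_win] <- cs_v[hi[any_win] + 1L] - cs_v[lo[any_win]]
  elig <- any_win & nvalid > 0 & hits / pmax(nvalid, 1) >= params$window_threshold
  elig
}

# segment-emission phase: maximal eligible runs split at large gaps, then
# filtered on span, SNP count and density
roh_segments_from_eligible <- function(x, bp, elig, params) {
  segs <- list()
  r <- rle(elig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; j0 <- ends[k]
    # split the run where consecutive eligible SNPs are farther than max_gap
    idx <- i0:j0
    if (length(idx) > 1L) {
      gap_break <- which(diff(bp[idx]) > params$max_gap_kb * 1000)
      piece_start <- c(idx[1], idx[gap_break + 1L])
      piece_end <- c(idx[gap_break], idx[length(idx)])
    } else {
      piece_start <- i0; piece_end <- j0
    }
    for (p in seq_along(piece_start)) {
      i <- piece_start[p]; j <- piece_end[p]
      span_kb <- (bp[j] - bp[i]) / 1000
      nsnp <- if (params$count_mode == "all") j - i + 1L else
        sum(!is.na(x[i:j]) & x[i:j] != 1L)
      if (span_kb >= params$min_kb && nsnp >= params$min_snp &&
          span_kb / max(nsnp, 1L) <= params$density_kb) {
        segs[[length(segs) + 1L]] <- c(i = i, j = j, nsnp = nsnp)
      }
    }
  }
  segs
}

#' Call runs of homozygosity for one individual
#'
#' Two-phase PLINK-style detection. Phase 1 slides a window of
#' `window_snp` consecutive SNPs along each chromosome (windows wider than
#' `window_kb` are skipped); a window is homozygous if it contains at most
#' `window_het` heterozygous and `window_missing` missing calls; each SNP's
#' hit fraction is the proportion of homozygous windows among the valid
#' windows containing it, and the SNP is RoH-eligible when that fraction
#' reaches `window_threshold`. Phase 2 emits maximal runs of eligible SNPs
#' (split at gaps above `max_gap_kb`) that satisfy the `min_kb`, `min_snp` and
#' `density_kb` constraints. Segment boundaries are the first and last
#' eligible SNP positions.
#'
#' @param g a [geno_matrix()] with variants sorted by (chrom, bp) — enforced
#'   by the container.
#' @param sample sample id or row index.
#' @param params a [roh_params()] object.
#' @return A data.frame of segments: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_kb`.
#' @export
call_roh <- function(g, sample, params = roh_params()) {
  if (is.character(sample)) sample <- match(sample, g$samples$id)
  id <- g$samples$id[sample]
  out <- list()
  for (ch in unique(g$variants$chrom)) {
    vi <- which(g$variants$chrom == ch)
    x <- g$calls[sample, vi]
    bp <- g$variants$bp[vi]
    elig <- roh_eligible(x, bp, params)
    segs <- roh_segments_from_eligible(x, bp, elig, params)
    for (s in segs) {
      out[[length(out) + 1L]] <- data.frame(
        sample = id, chrom = ch, start_bp = bp[s[["i"]]], end_bp = bp[s[["j"]]],
        n_snps = s[["nsnp"]],
        length_kb = (bp[s[["j"]]] - bp[s[["i"]]]) / 1000,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(), start_bp = numeric(),
               end_bp = numeric(), n_snps = integer(), length_kb = numeric())
}

#' Call RoH for every sample
#' @inheritParams call_roh
#' @return Row-bound segment data.frame over all samples.
#' @export
call_roh_all <- function(g, params = roh_params()) {
  do.call(rbind, lapply(seq_len(nrow(g$calls)), function(i)
    call_roh(g, i, params)))
}

#' Number and total length of an individual's RoH
#'
#' @param segments a segment data.frame from [call_roh()] / [call_roh_all()].
#' @param sample sample id.
#' @return Named numeric vector `c(roh_nseg, roh_kb)`.
#' @export
roh_summaries <- function(segments, sample) {
  s <- segments[segments$sample == sample, , drop = FALSE]
  c(roh_nseg = nrow(s), roh_kb = sum(s$length_kb))
}

#' RoH-based inbreeding coefficient
#'
#' F_ROH: the proportion of the (unmasked) autosomal extent lying inside runs
#' of homozygosity. Segments overlapping a masked interval (e.g. centromeres)
#' are truncated, not dropped, and the denominator excludes the masked extent.
#'
#' @param segments segment data.frame for one individual.
#' @param genome_extent_kb total autosomal extent in kb before masking (see
#'   [genome_extent_kb()]).
#' @param mask optional data.frame of intervals to exclude: `chrom`,
#'   `start_bp`, `end_bp`.
#' @return F_ROH in \[0, 1\].
#' @export
f_roh <- function(segments, genome_extent_kb, mask = NULL) {
  assert_that(genome_extent_kb > 0, "genome extent must be positive")
  masked_kb <- 0
  roh_kb <- 0
  if (nrow(segments)) {
    for (r in seq_len(nrow(segments))) {
      s <- segments$start_bp[r]; e <- segments$end_bp[r]
      len <- e - s
      if (!is.null(mask)) {
        mm <- mask[mask$chrom == segments$chrom[r], , drop = FALSE]
        if (nrow(mm)) {
          ov <- pmax(0, pmin(e, mm$end_bp) - pmax(s, mm$start_bp))
          len <- len - sum(ov)
        }
      }
      roh_kb <- roh_kb + len / 1000
    }
  }
  if (!is.null(mask) && nrow(mask)) {
    masked_kb <- sum(pmax(0, mask$end_bp - mask$start_bp)) / 1000
  }
  denom <- genome_extent_kb - masked_kb
  assert_that(denom > 0, "mask covers the whole extent")
  min(1, max(0, roh_kb / denom))
}

#' SNP-covered autosomal extent
#'
#' Sum over chromosomes of (last SNP bp - first SNP bp), in kb: the extent
#' actually observable from array data.
#'
#' @param g a [geno_matrix()].
#' @return Extent in kb.
#' @export
genome_extent_kb <- function(g) {
  sum(vapply(unique(g$variants$chrom), function(ch) {
    bp <- g$variants$bp[g$variants$chrom == ch]
    (max(bp) - min(bp)) / 1000
  }, numeric(1)))
}

#' Per-individual diversity table
#'
#' Computes, for every sample: HOM, the mean and median of its
#' within-population pairwise IBS distribution, RoH count and total length,
#' and F_ROH.
#'
#' @param g a [geno_matrix()].
#' @param params a [roh_params()].
#' @param mask optional centromere/assembly mask passed to [f_roh()].
#' @param segments optional precomputed output of [call_roh_all()].
#' @return A data.frame with one row per sample: `sample`, `population`,
#'   `group`, `hom`, `ibs_mean`, `ibs_median`, `roh_nseg`, `roh_kb`, `f_roh`.
#' @export
diversity_table <- function(g, params = roh_params(), mask = NULL,
                            segments = NULL) {
  segments <- segments %||% call_roh_all(g, params)
  ext <- genome_extent_kb(g)
  hom <- hom_all(g)
  ibs_mean <- ibs_per_individual(g, "mean")
  ibs_median <- ibs_per_individual(g, "median")
  res <- data.frame(sample = g$samples$id, population = g$samples$population,
                    group = g$samples$group, hom = unname(hom),
                    ibs_mean = unname(ibs_mean),
                    ibs_median = unname(ibs_median),
                    roh_nseg = NA_integer_, roh_kb = NA_real_,
                    f_roh = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    sm <- roh_summaries(segments, res$sample[i])
    res$roh_nseg[i] <- sm[["roh_nseg"]]
    res$roh_kb[i] <- sm[["roh_kb"]]
    res$f_roh[i] <- f_roh(segments[segments$sample == res$sample[i], ,
                                   drop = FALSE], ext, mask)
  }
  res
}
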