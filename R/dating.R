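# Switch-count dating of pulse admixture from local-ancestry tracts.
#
# Under a single-pulse model g generations ago with admixture proportion
# alpha, ancestry along a haplotype is a two-state Markov process and the
# expected density of ancestry switches is 2 g alpha (1 - alpha) per Morgan
# per haplotype. Inverting this yields the moment estimator
#   g_hat = S / (2 alpha (1 - alpha) L H)
# with S the observed switch count, L the per-haplotype map length in Morgans
# and H the number of haplotypes contributing to S.

#' Construct an ancestry tract set
#'
#' @param tracts data.frame with columns `sample`, `hap` (1 or 2), `chrom`,
#'   `start_cm`, `end_cm`, `ancestry`. Within each (sample, hap, chrom) the
#'   tracts must be contiguous and non-overlapping.
#' @return The validated data.frame with class `ancestry_tracts`.
#' @export
ancestry_tracts <- function(tracts) {
  tracts <- as.data.frame(tracts, stringsAsFactors = FALSE)
  need <- c("sample", "hap", "chrom", "start_cm", "end_cm", "ancestry")
  assert_that(all(need %in% names(tracts)),
              paste("tracts needs columns", paste(need, collapse = ", ")))
  assert_that(all(tracts$end_cm > tracts$start_cm),
              "tract end_cm must exceed start_cm")
  sp <- split(seq_len(nrow(tracts)),
              interaction(tracts$sample, tracts$hap, tracts$chrom, drop = TRUE))
  for (idx in sp) {
    o <- idx[order(tracts$start_cm[idx])]
    if (length(o) > 1L) {
      assert_that(all(abs(tracts$start_cm[o][-1] -
                            tracts$end_cm[o][-length(o)]) < 1e-9),
                  "tracts must be contiguous within a chromosome")
    }
  }
  class(tracts) <- c("ancestry_tracts", class(tracts))
  tracts
}

#' Count ancestry switches per individual
#'
#' A switch is an adjacent pair of tracts with different ancestry labels on
#' the same haplotype and chromosome; chromosome ends are not switches.
#' Counts are summed over both haplotypes and all chromosomes.
#'
#' @param tracts an [ancestry_tracts()] data.frame.
#' @return Named integer vector of switch counts per sample id.
#' @export
count_switches <- function(tracts) {
  samples <- unique(tracts$sample)
  out <- integer(length(samples))
  names(out) <- samples
  sp <- split(seq_len(nrow(tracts)),
              interaction(tracts$sample, tracts$hap, tracts$chrom, drop = TRUE))
  for (idx in sp) {
    o <- idx[order(tracts$start_cm[idx])]
    if (length(o) > 1L) {
      anc <- tracts$ancestry[o]
      out[tracts$sample[o[1]]] <- out[tracts$sample[o[1]]] +
        sum(anc[-1] != anc[-length(anc)])
    }
  }
  out
}

#' Per-individual admixture proportions from tract lengths
#'
#' Map-length-weighted fraction of each individual's genome assigned to
#' `source_a`, over both haplotypes.
#'
#' @param tracts an [ancestry_tracts()] data.frame.
#' @param source_a the ancestry label treated as "A".
#' @return Named numeric vector of proportions per sample.
#' @export
ancestry_proportions <- function(tracts, source_a) {
  len <- tracts$end_cm - tracts$start_cm
  tot <- tapply(len, tracts$sample, sum)
  ina <- tapply(len * (tracts$ancestry == source_a), tracts$sample, sum)
  out <- as.numeric(ina / tot)
  names(out) <- names(tot)
  out
}

#' Single-pulse admixture date from switch counts
#'
#' @param S ancestry switch count.
#' @param alpha admixture proportion, strictly inside (0, 1).
#' @param map_length_morgans per-haplotype total map length L, in Morgans.
#' @param n_haplotypes number of haplotypes contributing to `S` (2 for one
#'   diploid individual).
#' @return Estimated generations since the pulse. `S = 0` returns 0 with a
#'   low-information warning; `alpha` at 0 or 1 is an error (the date is
#'   undefined without both ancestries).
#' @export
estimate_admixture_date <- function(S, alpha, map_length_morgans,
                                    n_haplotypes = 2) {
  assert_that(map_length_morgans > 0, "map length must be positive")
  assert_that(alpha > 0 && alpha < 1,
              "alpha must lie strictly between 0 and 1")
  if (S == 0) {
    warning("zero switches observed: date estimate 0 is low-information",
            call. = FALSE)
    return(0)
  }
  S / (2 * alpha * (1 - alpha) * map_length_morgans * n_haplotypes)
}

#' Date admixture for every individual in a tract set
#'
#' Computes per-individual switch counts, tract-based ancestry proportions and
#' single-pulse date estimates, with the cohort mean and standard deviation.
#'
#' @param tracts an [ancestry_tracts()] data.frame.
#' @param source_a ancestry label used for the proportion (default: first
#'   label encountered); dates are invariant to the choice.
#' @param map_length_morgans per-haplotype map length; default: inferred from
#'   the tract spans of the first individual.
#' @return List with `individuals` (data.frame: `sample`, `alpha`, `S`,
#'   `g_hat`) and `summary` (`mean_g`, `sd_g`, `n`).
#' @export
date_admixture <- function(tracts, source_a = NULL,
                           map_length_morgans = NULL) {
  source_a <- source_a %||% tracts$ancestry[1]
  if (is.null(map_length_morgans)) {
    s1 <- tracts[tracts$sample == tracts$sample[1] & tracts$hap == 1, ]
    map_length_morgans <- sum(s1$end_cm - s1$start_cm) / 100
  }
  S <- count_switches(tracts)
  alpha <- ancestry_proportions(tracts, source_a)[names(S)]
  g_hat <- vapply(seq_along(S), function(i) {
    if (alpha[i] <= 0 || alpha[i] >= 1) return(NA_real_)
    suppressWarnings(estimate_admixture_date(S[i], alpha[i],
                                             map_length_morgans, 2))
  }, numeric(1))
  ind <- data.frame(sample = names(S), alpha = unname(alpha), S = unname(S),
                    g_hat = g_hat, stringsAsFactors = FALSE)
  ok <- !is.na(ind$g_hat)
  list(individuals = ind,
       summary = list(mean_g = mean(ind$g_hat[ok]),
                      sd_g = stats::sd(ind$g_hat[ok]), n = sum(ok)))
}

#' Read RFMix-style per-site ancestry calls into tracts
#'
#' Consumes a plain-text file of per-site Viterbi ancestry calls (one row per
#' variant, one column per haplotype; haplotype columns ordered sample-major:
#' sample1 hap1, sample1 hap2, sample2 hap1, ...) aligned to a variant map,
#' and collapses runs of constant ancestry into maximal tracts. Tract
#' boundaries between differing adjacent calls are placed at the genetic
#' midpoint. Per-individual proportions come from [ancestry_proportions()].
#'
#' @param file path to the per-site calls (whitespace-separated codes).
#' @param map data.frame with columns `chrom` and `cm`, one row per variant,
#'   in file row order.
#' @param samples sample ids, one per pair of haplotype columns.
#' @return An [ancestry_tracts()] data.frame.
#' @export
read_rfmix_tracts <- function(file, map, samples) {
  calls <- as.matrix(utils::read.table(file, header = FALSE,
                                       stringsAsFactors = FALSE))
  assert_that(nrow(calls) > 0, "empty ancestry-call file")
  assert_that(nrow(calls) == nrow(map),
              "site count does not match the variant map")
  assert_that(ncol(calls) == 2L * length(samples),
              "need two haplotype columns per sample")
  rows <- list()
  for (ci in seq_len(ncol(calls))) {
    smp <- samples[ceiling(ci / 2)]
    hapn <- 2L - ci %% 2L
    for (ch in unique(map$chrom)) {
      vi <- which(map$chrom == ch)
      cm <- map$cm[vi]
      anc <- calls[vi, ci]
      r <- rle(anc)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      # boundaries at midpoints between adjacent differing calls
      bounds <- c(cm[1],
                  if (length(ends_i) > 1)
                    (cm[ends_i[-length(ends_i)]] +
                       cm[starts_i[-1]]) / 2,
                  cm[length(cm)])
      keep <- bounds[-1] > bounds[-length(bounds)]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, hap = hapn, chrom = ch,
        start_cm = bounds[-length(bounds)][keep],
        end_cm = bounds[-1][keep], ancestry = r$values[keep],
        stringsAsFactors = FALSE)
    }
  }
  ancestry_tracts(do.call(rbind, rows))
}

#' Write RFMix-style per-site ancestry calls
#'
#' Inverse of [read_rfmix_tracts()] for simulated truth: emits one row per
#' variant with one ancestry code per haplotype column.
#'
#' @param tracts an [ancestry_tracts()] data.frame.
#' @param map variant map (`chrom`, `cm`) defining the sites.
#' @param samples sample ids defining the column order.
#' @param file output path.
#' @export
write_rfmix_sites <- function(tracts, map, samples, file) {
  out <- matrix("", nrow(map), 2L * length(samples))
  for (si in seq_along(samples)) {
    for (hp in 1:2) {
      tr <- tracts[tracts$sample == samples[si] & tracts$hap == hp, ]
      col <- 2L * (si - 1L) + hp
      for (ch in unique(map$chrom)) {
        vi <- which(map$chrom == ch)
        trc <- tr[tr$chrom == ch, ]
        o <- order(trc$start_cm)
        idx <- findInterval(map$cm[vi], trc$start_cm[o],
                            rightmost.closed = FALSE)
        idx[idx < 1L] <- 1L
        out[vi, col] <- trc$ancestry[o][idx]
      }
    }
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
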