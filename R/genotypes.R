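#' Diploid genotype matrix with variant and sample metadata
#'
#' The central data container: an integer matrix of genotype codes (samples in
#' rows, variants in columns) counting copies of the second (alternate) allele,
#' so 0 and 2 are the two homozygotes, 1 the heterozygote and `NA` a missing
#' call. Variant metadata carry physical (bp) and genetic (cM) positions on
#' autosomes; sample metadata carry a population label and an open/isolated
#' group label.
#'
#' @param calls integer matrix, samples x variants, values in {0, 1, 2, NA}.
#' @param variants data.frame with columns `id`, `chrom`, `bp`, `cm`, `a1`,
#'   `a2`. Within each chromosome `bp` must be strictly increasing and `cm`
#'   non-decreasing.
#' @param samples data.frame with columns `id`, `population` and `group`
#'   (`"open"` or `"isolated"`); sample ids must be unique.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  assert_that(all(c("id", "chrom", "bp", "cm") %in% names(variants)),
              "variants needs columns id, chrom, bp, cm")
  if (is.null(variants$a1)) variants$a1 <- "A"
  if (is.null(variants$a2)) variants$a2 <- "B"
  assert_that(all(c("id", "population") %in% names(samples)),
              "samples needs columns id, population")
  if (is.null(samples$group)) samples$group <- NA_character_
  assert_that(nrow(calls) == nrow(samples),
              "calls rows must match number of samples")
  assert_that(ncol(calls) == nrow(variants),
              "calls columns must match number of variants")
  assert_that(!anyDuplicated(samples$id), "duplicated sample ids")
  assert_that(all(is.na(calls) | (calls >= 0L & calls <= 2L)),
              "genotype codes must be 0, 1, 2 or NA")
  assert_that(all(variants$bp >= 1), "bp positions must be >= 1")
  for (ch in unique(variants$chrom)) {
    idx <- variants$chrom == ch
    assert_that(!is.unsorted(variants$bp[idx], strictly = TRUE),
                sprintf("bp not strictly increasing on chromosome %s", ch))
    assert_that(!is.unsorted(variants$cm[idx]),
                sprintf("cM not non-decreasing on chromosome %s", ch))
  }
  rownames(calls) <- samples$id
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants, %d population(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$samples$population))))
  mr <- mean(is.na(x$calls))
  cat(sprintf("  chromosomes: %s; missing rate %.4f\n",
              paste(unique(x$variants$chrom), collapse = ","), mr))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g a `geno_matrix`.
#' @param samples,variants logical/integer/character index vectors.
#' @return A `geno_matrix` restricted to the selected rows/columns.
#' @export
subset_geno <- function(g, samples = NULL, variants = NULL) {
  si <- samples %||% seq_len(nrow(g$calls))
  vi <- variants %||% seq_len(ncol(g$calls))
  if (is.character(si)) si <- match(si, g$samples$id)
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  geno_matrix(g$calls[si, vi, drop = FALSE],
              g$variants[vi, , drop = FALSE],
              g$samples[si, , drop = FALSE])
}

#' Phased haplotype matrix
#'
#' Holds 2N haplotype rows of {0,1} allele codes over the same variants as a
#' companion [geno_matrix()]. Sample `i` owns rows `2i - 1` and `2i`. Summing a
#' sample's two rows reproduces its diploid genotype at every non-missing call,
#' which [validate_haps()] checks.
#'
#' @param haps integer matrix, 2N x variants, values in {0,1}.
#' @param variants variant metadata as in [geno_matrix()].
#' @param samples sample metadata as in [geno_matrix()]; `nrow(haps)` must be
#'   `2 * nrow(samples)`.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(haps, variants, samples) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  assert_that(nrow(haps) == 2L * nrow(samples),
              "each sample must have exactly two haplotype rows")
  assert_that(ncol(haps) == nrow(variants), "haps/variants dimension mismatch")
  assert_that(all(haps %in% c(0L, 1L)), "haplotype codes must be 0/1")
  rownames(haps) <- paste0(rep(samples$id, each = 2L), c("_1", "_2"))
  structure(list(haps = haps, variants = variants, samples = samples),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haps), nrow(x$samples), ncol(x$haps)))
  invisible(x)
}

#' Row indices of a sample's two haplotypes
#' @param h a `hap_matrix`.
#' @param sample sample id.
#' @return Integer vector of length 2.
#' @export
hap_rows <- function(h, sample) {
  i <- match(sample, h$samples$id)
  assert_that(!is.na(i), sprintf("unknown sample '%s'", sample))
  c(2L * i - 1L, 2L * i)
}

#' Check haplotype/genotype consistency
#'
#' Verifies that for every sample the two haplotype rows sum to the diploid
#' genotype at all non-missing calls.
#'
#' @param h a `hap_matrix`.
#' @param g the companion `geno_matrix`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_haps <- function(h, g) {
  assert_that(identical(h$variants$id, g$variants$id), "variant sets differ")
  dip <- h$haps[seq(1L, nrow(h$haps), by = 2L), , drop = FALSE] +
    h$haps[seq(2L, nrow(h$haps), by = 2L), , drop = FALSE]
  ok <- is.na(g$calls) | dip == g$calls
  assert_that(all(ok), "haplotype rows do not sum to diploid genotypes")
  invisible(TRUE)
}

#' Collapse haplotypes to a diploid genotype matrix
#' @param h a `hap_matrix`.
#' @param group optional per-population group labels to attach.
#' @return A `geno_matrix` with no missing calls.
#' @export
haps_to_geno <- function(h, group = NULL) {
  dip <- h$haps[seq(1L, nrow(h$haps), by = 2L), , drop = FALSE] +
    h$haps[seq(2L, nrow(h$haps), by = 2L), , drop = FALSE]
  smp <- h$samples
  if (!is.null(group)) smp$group <- group
  geno_matrix(dip, h$variants, smp)
}
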