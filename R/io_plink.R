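# PLINK bed/bim/fam reading and writing.
#
# The .bed codec (2 bits per genotype, SNP-major) is implemented here
# directly. Allele-order normalisation: genotype codes count copies of the
# second (.bim column 6) allele, so bed code 00 (homozygous first allele)
# maps to 0, 10 (het) to 1, 11 to 2 and 01 to missing.

#' Write a genotype matrix as a PLINK bed/bim/fam triplet
#'
#' The population label is stored in the family id (FID) column of the .fam
#' file; the open/isolated group label is not representable in PLINK metadata
#' and must be re-attached on reading.
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$calls); V <- ncol(g$calls)
  bim <- data.frame(g$variants$chrom, g$variants$id, g$variants$cm,
                    g$variants$bp, g$variants$a1, g$variants$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$samples$population, g$samples$id, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # 2-bit codes: 0 -> 00, het -> 10, 2 -> 11, missing -> 01
  lut <- c(0L, 2L, 3L)
  B <- matrix(1L, n, V)
  ok <- !is.na(g$calls)
  B[ok] <- lut[g$calls[ok] + 1L]
  nb <- ceiling(n / 4)
  Bp <- rbind(B, matrix(0L, 4L * nb - n, V))
  m <- matrix(as.vector(Bp), nrow = 4L)
  bytes <- as.raw(m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triplet
#'
#' @param prefix path prefix of the triplet.
#' @param groups optional named vector mapping population labels (the FID
#'   column) to `"open"`/`"isolated"`.
#' @return A [geno_matrix()]; the FID column supplies the population label.
#' @export
read_plink <- function(prefix, groups = NULL) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "bp",
                                         "a1", "a2"))
  bim$chrom <- as.character(bim$chrom)
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  samples <- data.frame(id = as.character(fam[[2]]),
                        population = as.character(fam[[1]]),
                        group = if (is.null(groups)) NA_character_ else
                          unname(groups[as.character(fam[[1]])]),
                        stringsAsFactors = FALSE)
  n <- nrow(samples); V <- nrow(bim)
  nb <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + nb * V)
  assert_that(length(raw) >= 3L + nb * V, "truncated .bed file")
  assert_that(identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)),
              "not a SNP-major PLINK .bed file")
  ints <- as.integer(raw[-(1:3)])
  m <- rbind(ints %% 4L, (ints %/% 4L) %% 4L, (ints %/% 16L) %% 4L,
             (ints %/% 64L) %% 4L)
  codes <- matrix(as.vector(m), nrow = 4L * nb)[seq_len(n), , drop = FALSE]
  calls <- matrix(NA_integer_, n, V)
  calls[codes == 0L] <- 0L
  calls[codes == 2L] <- 1L
  calls[codes == 3L] <- 2L
  geno_matrix(calls, bim[, c("id", "chrom", "bp", "cm", "a1", "a2")], samples)
}
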