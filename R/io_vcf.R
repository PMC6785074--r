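# VCF input/output. Reading goes through vcfR; phased "|" separators populate
# the haplotype matrix. Writing emits a minimal phased VCFv4.2.

#' Write phased haplotypes as VCF
#'
#' @param h a [hap_matrix()].
#' @param file output path (plain text).
#' @return `file`, invisibly.
#' @export
write_phased_vcf <- function(h, file) {
  n <- nrow(h$samples)
  gt <- matrix("", nrow(h$variants), n)
  for (i in seq_len(n)) {
    gt[, i] <- paste0(h$haps[2L * i - 1L, ], "|", h$haps[2L * i, ])
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", h$samples$id), collapse = "\t"))
  body <- cbind(h$variants$chrom, h$variants$bp, h$variants$id,
                h$variants$a1, h$variants$a2, ".", ".", ".", "GT", gt)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a (phased) VCF
#'
#' Reads diploid GT fields through vcfR. Phased records ("0|1") populate a
#' [hap_matrix()]; the diploid [geno_matrix()] is always returned (alternate
#' allele count, missing as `NA`).
#'
#' @param file VCF path (may be bgzipped).
#' @param samples optional sample metadata data.frame (`id`, `population`,
#'   `group`); defaults to population `"unknown"`.
#' @param cm optional genetic positions per variant; defaults to bp/1e6 (1
#'   cM/Mb) when absent.
#' @return List with `geno` and (if fully phased) `haps`, else `haps = NULL`.
#' @export
read_vcf <- function(file, samples = NULL, cm = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         bp = as.numeric(fix[, "POS"]),
                         a1 = fix[, "REF"], a2 = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  no_id <- is.na(variants$id) | variants$id == "."
  variants$id[no_id] <- paste0(variants$chrom[no_id], ":",
                               variants$bp[no_id])
  variants$cm <- cm %||% variants$bp / 1e6
  ids <- colnames(gt)
  if (is.null(samples)) {
    samples <- data.frame(id = ids, population = "unknown",
                          group = NA_character_, stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(ids, samples$id), , drop = FALSE]
  }
  a1c <- substr(gt, 1, 1); sep <- substr(gt, 2, 2); a2c <- substr(gt, 3, 3)
  to_int <- function(x) suppressWarnings(as.integer(x))
  calls <- matrix(to_int(a1c) + to_int(a2c), nrow(gt), ncol(gt))
  g <- geno_matrix(t(calls), variants[, c("id", "chrom", "bp", "cm",
                                          "a1", "a2")], samples)
  haps <- NULL
  if (all(sep == "|", na.rm = TRUE) && !anyNA(calls)) {
    hm <- matrix(0L, 2L * length(ids), nrow(variants))
    for (i in seq_along(ids)) {
      hm[2L * i - 1L, ] <- to_int(a1c[, i])
      hm[2L * i, ] <- to_int(a2c[, i])
    }
    haps <- hap_matrix(hm, g$variants, samples)
  }
  list(geno = g, haps = haps)
}
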