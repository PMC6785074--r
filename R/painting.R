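# Within-population haplotype painting: a simplified Li & Stephens copying
# model. The recipient haplotype is modelled as a mosaic copied from donor
# haplotypes; a hidden Markov chain over donors with genetic-distance-driven
# switching yields, by forward-backward, the expected number of copied chunks
# and the expected genetic length copied from each donor.

# forward-backward for one chromosome.
# hap: recipient alleles (0/1, length T); donors: D x T matrix; cm: positions.
# Transition over an interval of d Morgans: switch mass rho = 1 - exp(-Ne*d/D)
# spread uniformly over donors; emission 1-theta on match, theta on mismatch.
paint_fb <- function(hap, donors, cm, Ne, theta) {
  D <- nrow(donors); T <- length(hap)
  match_m <- donors == matrix(hap, D, T, byrow = TRUE)
  em <- ifelse(match_m, 1 - theta, theta)
  d_M <- diff(cm) / 100
  if (T > 1 && all(d_M <= 0))
    warning("zero map distance throughout: degenerate transitions",
            call. = FALSE)
  rho <- 1 - exp(-Ne * d_M / D)
  alpha <- matrix(0, D, T)
  cvec <- numeric(T)
  a <- em[, 1] / D
  cvec[1] <- sum(a)
  alpha[, 1] <- a / cvec[1]
  if (T > 1) for (t in 2:T) {
    pred <- (1 - rho[t - 1]) * alpha[, t - 1] + rho[t - 1] / D
    a <- pred * em[, t]
    cvec[t] <- sum(a)
    alpha[, t] <- a / cvec[t]
  }
  beta <- matrix(0, D, T)
  beta[, T] <- 1
  if (T > 1) for (t in (T - 1):1) {
    bb <- beta[, t + 1] * em[, t + 1]
    beta[, t] <- ((1 - rho[t]) * bb + rho[t] * mean(bb)) / cvec[t + 1]
  }
  gamma <- alpha * beta                 # rows x sites; columns sum to 1
  # expected state-change transitions into each donor at each interval:
  # sum_{i != j} xi_t(i,j) = (rho/D) * em_j(t+1) * beta_{t+1}(j)
  #                          * (1 - alpha_t(j)) / c_{t+1}
  sw_in <- matrix(0, D, max(T - 1, 0))
  if (T > 1) for (t in 1:(T - 1)) {
    sw_in[, t] <- (rho[t] / D) * em[, t + 1] * beta[, t + 1] *
      (1 - alpha[, t]) / cvec[t + 1]
  }
  # genetic length weights: half of each flanking interval per site
  w <- numeric(T)
  if (T > 1) {
    dd <- diff(cm)
    w <- (c(0, dd) + c(dd, 0)) / 2
  }
  list(gamma = gamma, switch_in = sw_in, weights_cm = w,
       loglik = sum(log(cvec)),
       mismatch_mass = sum(gamma[!match_m]),
       n_sites = T)
}

#' Paint one recipient haplotype against a donor panel
#'
#' Runs the copying-model forward-backward over one or more chromosomes and
#' returns the expected number of copied chunks and the expected copied
#' genetic length (cM) attributed to each donor haplotype. The per-chromosome
#' chunk count is the expected number of donor switches plus one, apportioned
#' by posterior mass; expected lengths over donors sum to the painted map
#' length.
#'
#' @param recipient_hap integer vector of 0/1 alleles.
#' @param donors matrix of donor haplotypes (donors x variants).
#' @param cm genetic positions (cM) of the variants.
#' @param chrom optional chromosome label per variant; painting is performed
#'   independently per chromosome and summed.
#' @param Ne scaled switch-rate parameter of the copying model.
#' @param theta miscopy (mutation) probability per site.
#' @return data.frame with one row per donor: `chunk_count`,
#'   `chunk_length_cm`; the total model log-likelihood is attached as
#'   attribute `"loglik"`.
#' @export
paint_recipient <- function(recipient_hap, donors, cm, chrom = NULL,
                            Ne = 100, theta = 0.01) {
  donors <- as.matrix(donors)
  assert_that(nrow(donors) >= 2L, "need at least two donor haplotypes")
  assert_that(ncol(donors) == length(recipient_hap),
              "donors and recipient must share the variant set")
  chrom <- chrom %||% rep(1L, length(recipient_hap))
  D <- nrow(donors)
  cc <- cl <- numeric(D)
  ll <- 0
  for (ch in unique(chrom)) {
    vi <- which(chrom == ch)
    fb <- paint_fb(recipient_hap[vi], donors[, vi, drop = FALSE], cm[vi],
                   Ne, theta)
    cc <- cc + fb$gamma[, 1] +
      (if (ncol(fb$switch_in)) rowSums(fb$switch_in) else 0)
    cl <- cl + as.numeric(fb$gamma %*% fb$weights_cm)
    ll <- ll + fb$loglik
  }
  out <- data.frame(donor = rownames(donors) %||% paste0("d", seq_len(D)),
                    chunk_count = cc, chunk_length_cm = cl,
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- ll
  out
}

#' Within-population coancestry matrices by haplotype painting
#'
#' Paints each individual's two haplotypes using every other individual of the
#' same population as donors (both donor haplotypes), and accumulates expected
#' chunk counts and chunk lengths per recipient-donor individual pair.
#' Chromosomes are painted independently and summed.
#'
#' @param h a [hap_matrix()].
#' @param Ne,theta copying-model parameters (see [paint_recipient()]; fix them
#'   from [em_fit_parameters()] for real analyses).
#' @return List with square matrices `chunk_count` and `chunk_length_cm`
#'   (recipients in rows, donor individuals in columns, diagonal `NA`), for
#'   each population stitched into cohort-wide matrices.
#' @export
coancestry_matrix <- function(h, Ne = 100, theta = 0.01) {
  n <- nrow(h$samples)
  ids <- h$samples$id
  CC <- CL <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (pop in unique(h$samples$population)) {
    idx <- which(h$samples$population == pop)
    if (length(idx) < 2L) next
    for (i in idx) {
      donors_idx <- setdiff(idx, i)
      drows <- as.vector(vapply(donors_idx, function(k) c(2L * k - 1L, 2L * k),
                                integer(2)))
      donors <- h$haps[drows, , drop = FALSE]
      tot_cc <- numeric(length(drows)); tot_cl <- numeric(length(drows))
      for (r in c(2L * i - 1L, 2L * i)) {
        p <- paint_recipient(h$haps[r, ], donors, h$variants$cm,
                             chrom = h$variants$chrom, Ne = Ne, theta = theta)
        tot_cc <- tot_cc + p$chunk_count
        tot_cl <- tot_cl + p$chunk_length_cm
      }
      # collapse donor haplotypes to donor individuals
      per_ind_cc <- tot_cc[seq(1, length(drows), 2)] +
        tot_cc[seq(2, length(drows), 2)]
      per_ind_cl <- tot_cl[seq(1, length(drows), 2)] +
        tot_cl[seq(2, length(drows), 2)]
      CC[i, donors_idx] <- per_ind_cc
      CL[i, donors_idx] <- per_ind_cl
    }
  }
  list(chunk_count = CC, chunk_length_cm = CL)
}

#' EM estimation of the copying-model parameters
#'
#' Alternates forward-backward expectations with closed-form/1-D updates of
#' the miscopy probability theta (expected mismatch mass over painted sites)
#' and the switch parameter Ne (maximising the expected transition
#' log-likelihood over intervals). By convention a fixed small set of
#' chromosomes and 10 iterations are used, and the fitted values are then held
#' fixed for all chromosomes.
#'
#' @param h a [hap_matrix()].
#' @param chromosomes chromosome labels to fit on (default: all).
#' @param iterations EM iterations; default 10. `0` returns the initial
#'   values.
#' @param Ne0,theta0 initial values.
#' @param max_recipients cap on the number of recipient haplotypes per
#'   population per iteration (subsampled deterministically) to bound cost.
#' @return List with `Ne`, `theta` and the `loglik` trace. A non-increasing
#'   likelihood step triggers a warning, not an error.
#' @export
em_fit_parameters <- function(h, chromosomes = NULL, iterations = 10L,
                              Ne0 = 100, theta0 = 0.01,
                              max_recipients = 20L) {
  chromosomes <- chromosomes %||% unique(h$variants$chrom)
  vi <- which(h$variants$chrom %in% chromosomes)
  Ne <- Ne0; theta <- theta0
  trace <- numeric(0)
  if (iterations == 0L) return(list(Ne = Ne, theta = theta, loglik = trace))
  for (it in seq_len(iterations)) {
    ll <- 0; mis <- 0; nsite <- 0
    sw_list <- list(); d_list <- list(); D_used <- integer(0)
    for (pop in unique(h$samples$population)) {
      idx <- which(h$samples$population == pop)
      if (length(idx) < 2L) next
      rec <- idx[seq_len(min(length(idx), max_recipients))]
      for (i in rec) {
        donors_idx <- setdiff(idx, i)
        drows <- as.vector(vapply(donors_idx,
                                  function(k) c(2L * k - 1L, 2L * k),
                                  integer(2)))
        D <- length(drows)
        for (r in c(2L * i - 1L, 2L * i)) {
          for (ch in intersect(chromosomes, unique(h$variants$chrom))) {
            cvi <- which(h$variants$chrom == ch)
            fb <- paint_fb(h$haps[r, cvi], h$haps[drows, cvi, drop = FALSE],
                           h$variants$cm[cvi], Ne, theta)
            ll <- ll + fb$loglik
            mis <- mis + fb$mismatch_mass
            nsite <- nsite + fb$n_sites
            if (ncol(fb$switch_in)) {
              sw_list[[length(sw_list) + 1L]] <- colSums(fb$switch_in)
              d_list[[length(d_list) + 1L]] <- diff(h$variants$cm[cvi]) / 100
              D_used <- c(D_used, rep(D, ncol(fb$switch_in)))
            }
          }
        }
      }
    }
    trace <- c(trace, ll)
    if (it > 1L && ll < trace[it - 1L] - 1e-8)
      warning("EM log-likelihood decreased", call. = FALSE)
    theta <- max(1e-6, min(0.5, mis / nsite))
    s <- unlist(sw_list); dM <- unlist(d_list)
    q_ne <- function(logNe) {
      rho <- 1 - exp(-exp(logNe) * dM / D_used)
      rho <- pmin(pmax(rho, 1e-12), 1 - 1e-12)
      # expected transition log-lik: changes vs stays
      sum(s * log(rho / D_used) + (1 - pmin(s, 1)) *
            log(1 - rho * (D_used - 1) / D_used))
    }
    Ne <- exp(stats::optimize(q_ne, c(log(1e-3), log(1e7)),
                              maximum = TRUE)$maximum)
  }
  list(Ne = Ne, theta = theta, loglik = trace)
}

#' Per-individual haplotype-sharing value (CHR_P)
#'
#' Reduces an individual's row of the within-population chunk-length
#' coancestry matrix to a single value: the median (default; the convention
#' for pairwise measures entering variance-based scans) or the mean over
#' donors of the total genetic length copied.
#'
#' @param coancestry output of [coancestry_matrix()] (or a compatible list
#'   with a `chunk_length_cm` matrix).
#' @param sample sample id.
#' @param stat `"median"` or `"mean"`.
#' @return The individual's CHR_P value in cM.
#' @export
chrp_individual <- function(coancestry, sample, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  v <- coancestry$chunk_length_cm[sample, ]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    return(undefined_result("no donors painted for this sample"))
  if (stat == "median") stats::median(v) else mean(v)
}

#' CHR_P for every painted sample
#' @inheritParams chrp_individual
#' @return Named numeric vector over the recipients of the coancestry matrix.
#' @export
chrp_all <- function(coancestry, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  ids <- rownames(coancestry$chunk_length_cm)
  out <- vapply(ids, function(s)
    suppressWarnings(chrp_individual(coancestry, s, stat)), numeric(1))
  names(out) <- ids
  out
}

#' Switch error rate between two phasings
#'
#' Fraction of consecutive heterozygous-site pairs whose relative phase
#' differs between a truth and an inferred haplotype pair, counted up to a
#' global haplotype swap (a completely swapped phasing has SER 0).
#'
#' @param truth,inferred [hap_matrix()] objects over the same variants.
#' @param sample sample id.
#' @return SER in \[0, 1\]; `NA` with a warning when the sample has fewer than
#'   two heterozygous sites.
#' @export
switch_error_rate <- function(truth, inferred, sample) {
  assert_that(identical(truth$variants$id, inferred$variants$id),
              "variant sets differ")
  rt <- hap_rows(truth, sample); ri <- hap_rows(inferred, sample)
  t1 <- truth$haps[rt[1], ]; t2 <- truth$haps[rt[2], ]
  i1 <- inferred$haps[ri[1], ]; i2 <- inferred$haps[ri[2], ]
  het <- which(t1 != t2)
  assert_that(all((i1 + i2)[het] == 1L),
              "inferred genotypes disagree with truth at heterozygous sites")
  if (length(het) < 2L)
    return(undefined_result("fewer than two heterozygous sites"))
  m <- t1[het] != i1[het]               # per-het-site phase orientation
  sum(m[-1] != m[-length(m)]) / (length(het) - 1L)
}

#' Write a coancestry matrix in ChromoPainter chunklengths layout
#'
#' Square tab-separated matrix with a `Recipient` leading column, so that
#' externally produced matrices can be ingested interchangeably via
#' [read_chunklengths()].
#'
#' @param mat square matrix (recipients x donors).
#' @param file output path.
#' @export
write_chunklengths <- function(mat, file) {
  df <- data.frame(Recipient = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a ChromoPainter-style chunklengths matrix
#' @param file path written by [write_chunklengths()] or by ChromoPainter
#'   tooling.
#' @return Numeric matrix with recipient rownames.
#' @export
read_chunklengths <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
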