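# Seed-deterministic synthetic data: drift-differentiated populations,
# inbred isolates with implanted autozygosity, recently introgressed
# sub-groups with known pulse parameters, and mosaic haplotypes for painting.
#
# All stochastic operations take an explicit seed. Sites are drawn
# independently given ancestry (no background LD) except in the copying-pool
# generator, which exists precisely to create chunk structure for painting.

#' Build a uniform variant map
#'
#' Evenly spaced SNPs at a constant 1 cM/Mb recombination rate.
#'
#' @param n_chrom number of autosomes.
#' @param chrom_cm genetic length of each chromosome (cM); physical length is
#'   `chrom_cm` Mb.
#' @param snps_per_chrom SNPs per chromosome.
#' @return Variant data.frame (`id`, `chrom`, `bp`, `cm`, `a1`, `a2`).
#' @export
make_map <- function(n_chrom = 6L, chrom_cm = 150, snps_per_chrom = 3000L) {
  spacing_bp <- chrom_cm * 1e6 / snps_per_chrom
  do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    bp <- round(spacing_bp * seq_len(snps_per_chrom))
    data.frame(id = sprintf("snp%d_%d", ch, seq_len(snps_per_chrom)),
               chrom = as.character(ch), bp = bp, cm = bp / 1e6,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }))
}

#' Balding-Nichols population allele frequencies
#'
#' Ancestral frequencies are uniform on \[0.05, 0.95\]; each population's
#' frequencies are Beta-distributed around the ancestral value with
#' variance `F p (1 - p)` given its drift parameter F.
#'
#' @param n_variants number of variants.
#' @param fst named numeric vector of per-population drift parameters in
#'   (0, 1); values below 1e-8 return the ancestral frequencies unchanged.
#' @param seed integer seed.
#' @return List with `ancestral` and matrix `pops` (variants x populations).
#' @export
simulate_frequencies <- function(n_variants, fst, seed) {
  set.seed(seed)
  anc <- stats::runif(n_variants, 0.05, 0.95)
  pops <- vapply(fst, function(F) {
    if (F < 1e-8) return(anc)
    a <- anc * (1 - F) / F
    b <- (1 - anc) * (1 - F) / F
    stats::rbeta(n_variants, a, b)
  }, numeric(n_variants))
  colnames(pops) <- names(fst) %||% paste0("pop", seq_along(fst))
  list(ancestral = anc, pops = pops)
}

# Draw per-individual autozygous segments to hit an expected genome fraction.
# Segment lengths are Exp(mean_cm); their number follows a debiased stopping
# rule so the expected total equals target_cm; positions uniform on the map,
# with light rejection of overlaps.
draw_autozygous_segments <- function(target_cm, map, mean_cm = 5) {
  if (target_cm <= 0) return(NULL)
  lens <- numeric(0)
  if (target_cm < mean_cm) {
    if (stats::runif(1) < target_cm / mean_cm)
      lens <- stats::rexp(1, 1 / mean_cm)
  } else {
    tot <- 0
    while (tot < target_cm - mean_cm) {
      l <- stats::rexp(1, 1 / mean_cm)
      lens <- c(lens, l); tot <- tot + l
    }
  }
  if (!length(lens)) return(NULL)
  chroms <- unique(map$chrom)
  clen <- vapply(chroms, function(ch) max(map$cm[map$chrom == ch]),
                 numeric(1))
  segs <- list()
  for (l in lens) {
    placed <- FALSE
    for (try in 1:20) {
      ch <- sample(chroms, 1L, prob = clen)
      L <- clen[ch]
      l2 <- min(l, L)
      s <- stats::runif(1, 0, L - l2)
      e <- s + l2
      clash <- any(vapply(segs, function(sg)
        sg$chrom == ch && s < sg$end_cm && e > sg$start_cm, logical(1)))
      if (!clash) {
        segs[[length(segs) + 1L]] <- list(chrom = ch, start_cm = s, end_cm = e)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      segs[[length(segs) + 1L]] <- list(chrom = ch, start_cm = s, end_cm = e)
  }
  do.call(rbind, lapply(segs, function(sg)
    data.frame(chrom = sg$chrom, start_cm = sg$start_cm, end_cm = sg$end_cm,
               stringsAsFactors = FALSE)))
}

#' Simulate one population with implanted autozygosity
#'
#' Haplotypes are drawn site-wise from the population's allele frequencies.
#' Each individual receives an inbreeding level F_i (truncated normal around
#' `autozygosity` with coefficient of variation `f_cv`) realised as autozygous
#' segments — intervals where the two haplotypes are forced identical — with
#' exponential lengths (mean `seg_mean_cm`) whose expected total fraction of
#' the map equals F_i.
#'
#' @param freqs per-variant allele frequencies for this population.
#' @param n_samples number of diploid individuals.
#' @param autozygosity expected fraction of the genome autozygous (the
#'   population mean of F_i).
#' @param map variant data.frame from [make_map()].
#' @param seed integer seed.
#' @param ids sample ids; default `pop_1..n`.
#' @param population,group metadata labels.
#' @param f_cv coefficient of variation of F_i across individuals.
#' @param seg_mean_cm mean autozygous segment length in cM.
#' @return List with `haps` ([hap_matrix()]), `geno` ([geno_matrix()]) and
#'   `truth_segments` (per-individual autozygous intervals, cM).
#' @export
simulate_population <- function(freqs, n_samples, autozygosity, map, seed,
                                ids = NULL, population = "pop",
                                group = "open", f_cv = 0.35,
                                seg_mean_cm = 5) {
  set.seed(seed)
  ids <- ids %||% paste0(population, "_", seq_len(n_samples))
  V <- nrow(map)
  haps <- matrix(0L, 2L * n_samples, V)
  truth <- list()
  for (i in seq_len(n_samples)) {
    h1 <- as.integer(stats::runif(V) < freqs)
    h2 <- as.integer(stats::runif(V) < freqs)
    Fi <- if (autozygosity > 0)
      max(0, stats::rnorm(1, autozygosity, f_cv * autozygosity)) else 0
    segs <- draw_autozygous_segments(Fi * sum(tapply(map$cm, map$chrom, max)),
                                     map, seg_mean_cm)
    if (!is.null(segs)) {
      for (r in seq_len(nrow(segs))) {
        in_seg <- map$chrom == segs$chrom[r] & map$cm >= segs$start_cm[r] &
          map$cm <= segs$end_cm[r]
        h2[in_seg] <- h1[in_seg]
      }
      truth[[length(truth) + 1L]] <- data.frame(sample = ids[i], segs,
                                                stringsAsFactors = FALSE)
    }
    haps[2L * i - 1L, ] <- h1
    haps[2L * i, ] <- h2
  }
  samples <- data.frame(id = ids, population = population, group = group,
                        stringsAsFactors = FALSE)
  h <- hap_matrix(haps, map, samples)
  list(haps = h, geno = haps_to_geno(h),
       truth_segments = if (length(truth)) do.call(rbind, truth) else
         data.frame(sample = character(), chrom = character(),
                    start_cm = numeric(), end_cm = numeric()))
}

# two-state ancestry Markov process along one chromosome (continuous, exact):
# rate out of A is g*(1-alpha), out of B is g*alpha, per Morgan; stationary
# start. Returns tracts in cM.
simulate_tracts_chrom <- function(chrom, len_cm, g, alpha,
                                  labels = c("A", "B")) {
  state <- if (stats::runif(1) < alpha) 1L else 2L
  pos <- 0
  starts <- ends <- numeric(0)
  states <- integer(0)
  while (pos < len_cm) {
    rate_per_cm <- (if (state == 1L) g * (1 - alpha) else g * alpha) / 100
    jump <- if (rate_per_cm > 0) stats::rexp(1, rate_per_cm) else Inf
    end <- min(len_cm, pos + jump)
    starts <- c(starts, pos); ends <- c(ends, end); states <- c(states, state)
    pos <- end
    state <- 3L - state
  }
  data.frame(chrom = chrom, start_cm = starts, end_cm = ends,
             ancestry = labels[states], stringsAsFactors = FALSE)
}

#' Simulate pulse-admixture ancestry tracts only
#'
#' The tract layer of [simulate_admixed()] without drawing alleles: per
#' haplotype a stationary two-state Markov process along the map with switch
#' rates `g (1 - alpha)` out of source A and `g alpha` out of source B per
#' Morgan, giving expected switch density `2 g alpha (1 - alpha)` per Morgan.
#'
#' @param g generations since the pulse.
#' @param alpha stationary source-A proportion in (0, 1).
#' @param chrom_lengths_cm named (or unnamed) vector of chromosome lengths in
#'   cM.
#' @param n_samples number of diploid individuals.
#' @param seed integer seed.
#' @param ids sample ids.
#' @param labels the two ancestry labels.
#' @return An [ancestry_tracts()] data.frame.
#' @export
simulate_tracts <- function(g, alpha, chrom_lengths_cm, n_samples, seed,
                            ids = NULL, labels = c("A", "B")) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(g >= 1, "g must be >= 1")
  set.seed(seed)
  ids <- ids %||% paste0("adm_", seq_len(n_samples))
  chroms <- names(chrom_lengths_cm) %||% as.character(seq_along(chrom_lengths_cm))
  out <- list()
  for (i in seq_len(n_samples)) for (hp in 1:2) {
    tr <- do.call(rbind, lapply(seq_along(chroms), function(k)
      simulate_tracts_chrom(chroms[k], chrom_lengths_cm[[k]], g, alpha,
                            labels)))
    out[[length(out) + 1L]] <- data.frame(sample = ids[i], hap = hp, tr,
                                          stringsAsFactors = FALSE)
  }
  ancestry_tracts(do.call(rbind, out))
}

#' Simulate pulse-admixed haplotypes with known ancestry tracts
#'
#' Per haplotype, ancestry along the map follows the two-state Markov process
#' implied by a single admixture pulse `g` generations ago with proportion
#' `alpha` of `source_a` ancestry (switch rates `g(1-alpha)` out of A and
#' `g alpha` out of B per Morgan, stationary start), so the expected switch
#' density is `2 g alpha (1-alpha)` per Morgan. Alleles are drawn site-wise
#' from the tract's source frequencies.
#'
#' @param freq_a,freq_b per-variant allele frequencies of the two sources.
#' @param g generations since the pulse (>= 1).
#' @param alpha stationary proportion of source-A ancestry, in (0, 1).
#' @param map variant data.frame.
#' @param n_samples number of diploid individuals.
#' @param seed integer seed.
#' @param ids,population,group sample metadata.
#' @param labels ancestry labels for the two sources.
#' @return List with `haps` ([hap_matrix()]), `geno`, and `truth_tracts`
#'   (an [ancestry_tracts()] data.frame).
#' @export
simulate_admixed <- function(freq_a, freq_b, g, alpha, map, n_samples, seed,
                             ids = NULL, population = "adm", group = "open",
                             labels = c("A", "B")) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(g >= 1, "g must be >= 1")
  set.seed(seed)
  ids <- ids %||% paste0(population, "_", seq_len(n_samples))
  V <- nrow(map)
  chroms <- unique(map$chrom)
  clen <- vapply(chroms, function(ch) max(map$cm[map$chrom == ch]), numeric(1))
  haps <- matrix(0L, 2L * n_samples, V)
  tracts <- list()
  for (i in seq_len(n_samples)) for (hp in 1:2) {
    tr <- do.call(rbind, lapply(seq_along(chroms), function(k)
      simulate_tracts_chrom(chroms[k], clen[k], g, alpha, labels)))
    tr <- data.frame(sample = ids[i], hap = hp, tr, stringsAsFactors = FALSE)
    tracts[[length(tracts) + 1L]] <- tr
    hap <- integer(V)
    for (r in seq_len(nrow(tr))) {
      in_tr <- map$chrom == tr$chrom[r] & map$cm >= tr$start_cm[r] &
        (map$cm < tr$end_cm[r] |
           (tr$end_cm[r] == clen[match(tr$chrom[r], chroms)] &
              map$cm <= tr$end_cm[r]))
      f <- if (tr$ancestry[r] == labels[1]) freq_a else freq_b
      hap[in_tr] <- as.integer(stats::runif(sum(in_tr)) < f[in_tr])
    }
    haps[2L * (i - 1L) + hp, ] <- hap
  }
  samples <- data.frame(id = ids, population = population, group = group,
                        stringsAsFactors = FALSE)
  h <- hap_matrix(haps, map, samples)
  list(haps = h, geno = haps_to_geno(h),
       truth_tracts = ancestry_tracts(do.call(rbind, tracts)))
}

#' Mosaic haplotypes from a shared copying pool
#'
#' Generates chunk structure for painting tests: a pool of founder haplotypes
#' is simulated site-wise, then each sample haplotype is built by copying from
#' a randomly switching pool member (switch probability per interval
#' `1 - exp(-rate * d_cM)`) with a per-site miscopy probability.
#'
#' @param n_pool number of founder haplotypes.
#' @param n_samples diploid samples to build.
#' @param map variant data.frame.
#' @param seed integer seed.
#' @param switch_rate_cm switch rate per cM along the mosaic.
#' @param miscopy per-site miscopy probability.
#' @param population,group metadata labels.
#' @return List with `haps` ([hap_matrix()]), `geno`, and `pool` (the founder
#'   haplotypes).
#' @export
simulate_copying_pool <- function(n_pool, n_samples, map, seed,
                                  switch_rate_cm = 0.05, miscopy = 0.005,
                                  population = "pool_pop", group = "isolated") {
  set.seed(seed)
  V <- nrow(map)
  freqs <- stats::runif(V, 0.1, 0.9)
  pool <- matrix(as.integer(stats::runif(n_pool * V) <
                              rep(freqs, each = n_pool)), n_pool, V)
  haps <- matrix(0L, 2L * n_samples, V)
  for (r in seq_len(2L * n_samples)) {
    cur <- sample.int(n_pool, 1L)
    hap <- integer(V)
    for (t in seq_len(V)) {
      if (t > 1L) {
        same_chrom <- map$chrom[t] == map$chrom[t - 1L]
        d <- if (same_chrom) map$cm[t] - map$cm[t - 1L] else Inf
        if (stats::runif(1) < 1 - exp(-switch_rate_cm * d))
          cur <- sample.int(n_pool, 1L)
      }
      hap[t] <- pool[cur, t]
    }
    flip <- stats::runif(V) < miscopy
    hap[flip] <- 1L - hap[flip]
    haps[r, ] <- hap
  }
  ids <- paste0(population, "_", seq_len(n_samples))
  samples <- data.frame(id = ids, population = population, group = group,
                        stringsAsFactors = FALSE)
  h <- hap_matrix(haps, map, samples)
  list(haps = h, geno = haps_to_geno(h), pool = pool)
}

#' Scenario configuration
#'
#' The default scenario emulates a continental sampling of open populations
#' plus a set of small inbred isolates, one of which harbours a recently
#' introgressed sub-group: 8 open populations (n = 20, drift 0.02,
#' autozygosity 0.005) and 4 isolates (n = 24, drift 0.08, autozygosity 0.04),
#' with half of the first isolate carrying a pulse of outside ancestry
#' (g = 5 generations, alpha = 0.3) from the lineage of the first open
#' population.
#'
#' @param n_open,n_isolate numbers of open and isolated populations.
#' @param open_n,isolate_n samples per population in each group.
#' @param open_fst,isolate_fst drift parameters.
#' @param open_autozygosity,isolate_autozygosity expected autozygous
#'   fractions.
#' @param introgressed_fraction fraction of the first isolate's individuals
#'   carrying introgressed ancestry.
#' @param pulse_g,pulse_alpha single-pulse parameters for those individuals.
#' @param admixed_autozygosity autozygosity of the introgressed individuals
#'   (recent outbreeding largely erases autozygosity).
#' @param map variant map; default [make_map()].
#' @param seed integer seed (mandatory for every stochastic operation).
#' @return A validated config list of class `scenario_config`.
#' @export
scenario_config <- function(n_open = 8L, n_isolate = 4L, open_n = 20L,
                            isolate_n = 24L, open_fst = 0.02,
                            isolate_fst = 0.08, open_autozygosity = 0.005,
                            isolate_autozygosity = 0.04,
                            introgressed_fraction = 0.5, pulse_g = 5,
                            pulse_alpha = 0.3, admixed_autozygosity = 0,
                            map = make_map(), seed = 1L) {
  cfg <- list(n_open = n_open, n_isolate = n_isolate, open_n = open_n,
              isolate_n = isolate_n, open_fst = open_fst,
              isolate_fst = isolate_fst,
              open_autozygosity = open_autozygosity,
              isolate_autozygosity = isolate_autozygosity,
              introgressed_fraction = introgressed_fraction,
              pulse_g = pulse_g, pulse_alpha = pulse_alpha,
              admixed_autozygosity = admixed_autozygosity,
              map = map, seed = seed)
  checks <- c(
    n_open = cfg$n_open >= 1, n_isolate = cfg$n_isolate >= 1,
    open_n = cfg$open_n >= 2, isolate_n = cfg$isolate_n >= 2,
    open_fst = cfg$open_fst > 0 && cfg$open_fst < 1,
    isolate_fst = cfg$isolate_fst > 0 && cfg$isolate_fst < 1,
    open_autozygosity = cfg$open_autozygosity >= 0 &&
      cfg$open_autozygosity < 1,
    isolate_autozygosity = cfg$isolate_autozygosity >= 0 &&
      cfg$isolate_autozygosity < 1,
    introgressed_fraction = cfg$introgressed_fraction >= 0 &&
      cfg$introgressed_fraction <= 1,
    pulse_g = cfg$pulse_g >= 1,
    pulse_alpha = cfg$pulse_alpha > 0 && cfg$pulse_alpha < 1,
    seed = is_count(abs(cfg$seed)))
  if (!all(checks))
    stop_isohet(paste("invalid scenario config field(s):",
                      paste(names(checks)[!checks], collapse = ", ")))
  structure(cfg, class = "scenario_config")
}

#' Build the full synthetic scenario
#'
#' Simulates allele frequencies, every population's haplotypes and genotypes,
#' the introgressed sub-group of the first isolate (with truth tracts from the
#' pulse model), and the truth Q matrix derived from tract-based ancestry
#' fractions (K = 2: own vs introgressing-source ancestry). All downstream
#' modules consume the pieces of the returned list.
#'
#' @param config a [scenario_config()].
#' @return List with `geno` ([geno_matrix()] over all samples), `haps`
#'   ([hap_matrix()]), `q` (truth [q_matrix()]), `truth` (list:
#'   `autozygous_segments`, `tracts`, `admixed_ids`, `introgressed_population`,
#'   `frequencies`) and `config`.
#' @export
build_scenario <- function(config = scenario_config()) {
  cfg <- config
  map <- cfg$map
  pops <- c(paste0("OPEN", seq_len(cfg$n_open)),
            paste0("ISO", seq_len(cfg$n_isolate)))
  fst <- c(rep(cfg$open_fst, cfg$n_open), rep(cfg$isolate_fst, cfg$n_isolate))
  names(fst) <- pops
  fr <- simulate_frequencies(nrow(map), fst, seed = cfg$seed)
  intro_pop <- paste0("ISO", 1L)
  source_pop <- paste0("OPEN", 1L)
  hap_list <- list(); smp_list <- list(); seg_list <- list()
  tract_list <- list(); q_rows <- list()
  pure_tract <- function(ids, anc) {
    chroms <- unique(map$chrom)
    clen <- vapply(chroms, function(ch) max(map$cm[map$chrom == ch]),
                   numeric(1))
    do.call(rbind, lapply(ids, function(id)
      do.call(rbind, lapply(1:2, function(hp)
        data.frame(sample = id, hap = hp, chrom = chroms, start_cm = 0,
                   end_cm = unname(clen), ancestry = anc,
                   stringsAsFactors = FALSE)))))
  }
  admixed_ids <- character(0)
  for (k in seq_along(pops)) {
    pop <- pops[k]
    isolate <- k > cfg$n_open
    n <- if (isolate) cfg$isolate_n else cfg$open_n
    az <- if (isolate) cfg$isolate_autozygosity else cfg$open_autozygosity
    grp <- if (isolate) "isolated" else "open"
    n_adm <- if (pop == intro_pop)
      round(cfg$introgressed_fraction * n) else 0L
    n_pure <- n - n_adm
    ids <- paste0(pop, "_", seq_len(n))
    sim <- simulate_population(fr$pops[, pop], n_pure, az, map,
                               seed = cfg$seed + 1000L + k,
                               ids = ids[seq_len(n_pure)],
                               population = pop, group = grp)
    hp <- sim$haps$haps
    if (nrow(sim$truth_segments)) seg_list[[pop]] <- sim$truth_segments
    tract_list[[paste0(pop, "_pure")]] <-
      pure_tract(ids[seq_len(n_pure)], "OWN")
    for (id in ids[seq_len(n_pure)])
      q_rows[[id]] <- c(1, 0)
    if (n_adm > 0L) {
      adm <- simulate_admixed(fr$pops[, source_pop], fr$pops[, pop],
                              g = cfg$pulse_g, alpha = cfg$pulse_alpha, map,
                              n_samples = n_adm,
                              seed = cfg$seed + 2000L + k,
                              ids = ids[n_pure + seq_len(n_adm)],
                              population = pop, group = grp,
                              labels = c("SRC", "OWN"))
      if (cfg$admixed_autozygosity > 0) {
        # not implemented as segments for admixed genomes; kept at 0 by
        # default: a recent pulse breaks up inbreeding loops
        warning("admixed_autozygosity > 0 is ignored", call. = FALSE)
      }
      hp <- rbind(hp, adm$haps$haps)
      tract_list[[paste0(pop, "_adm")]] <- adm$truth_tracts
      a <- ancestry_proportions(adm$truth_tracts, "SRC")
      for (id in names(a)) q_rows[[id]] <- c(1 - a[[id]], a[[id]])
      admixed_ids <- c(admixed_ids, ids[n_pure + seq_len(n_adm)])
    }
    hap_list[[pop]] <- hp
    smp_list[[pop]] <- data.frame(id = ids, population = pop, group = grp,
                                  stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, smp_list)
  rownames(samples) <- NULL
  haps <- hap_matrix(do.call(rbind, hap_list), map, samples)
  geno <- haps_to_geno(haps)
  tracts <- ancestry_tracts(do.call(rbind, c(tract_list,
                                             make.row.names = FALSE)))
  qm <- q_matrix(do.call(rbind, q_rows[samples$id]), samples = samples$id)
  list(geno = geno, haps = haps, q = qm,
       truth = list(
         autozygous_segments = if (length(seg_list))
           do.call(rbind, c(seg_list, make.row.names = FALSE)) else NULL,
         tracts = tracts, admixed_ids = admixed_ids,
         introgressed_population = intro_pop,
         source_population = source_pop, frequencies = fr),
       config = cfg)
}

#' Write a scenario to disk
#'
#' Emits the genotypes as a PLINK bed/bim/fam triplet, the haplotypes as a
#' phased VCF, the truth Q matrix in ADMIXTURE .Q layout (plus a sample-order
#' file), the truth ancestry tracts as RFMix-style per-site calls, and the
#' truth autozygous segments and scenario metadata as tab-separated/JSON
#' files.
#'
#' @param scenario output of [build_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(scenario$geno, file.path(dir, "scenario"))
  write_phased_vcf(scenario$haps, file.path(dir, "scenario.vcf"))
  utils::write.table(unclass(scenario$q), file.path(dir, "scenario.Q"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(rownames(scenario$q), file.path(dir, "scenario.Q.samples"))
  map <- scenario$geno$variants[, c("chrom", "cm")]
  write_rfmix_sites(scenario$truth$tracts, map,
                    scenario$geno$samples$id,
                    file.path(dir, "scenario.sites.txt"))
  if (!is.null(scenario$truth$autozygous_segments))
    utils::write.table(scenario$truth$autozygous_segments,
                       file.path(dir, "truth_autozygous_segments.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- scenario$config[setdiff(names(scenario$config), "map")]
    jsonlite::write_json(meta, file.path(dir, "scenario_config.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
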