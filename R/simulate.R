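#' Simulation configuration for two-population haplotype data
#'
#' The generator emulates a reduced-representation SNP dataset for two
#' diverged populations: a focal population (default `"PAG"`) and a
#' reference (`"GO"`). Ancestral allele frequencies are Beta(0.8, 0.8)
#' truncated to [0.05, 0.95]; population frequencies follow the
#' Balding-Nichols model at divergence `F`; haplotypes are founder mosaics
#' (switching between `K` founders at rate `rho` per bp, which produces LD
#' decaying over tens of kb) with site-wise mutation flips at `mu`. An
#' optional hard sweep collapses focal-population haplotypes inside an
#' interval onto founder 1 with probability `sweep_f`, mutating residually
#' at `sweep_mu` -- directly producing a dominant haplotype near frequency
#' `sweep_f`, a collapse of nucleotide diversity, elevated differentiation,
#' and extended haplotypes.
#'
#' Defaults give 2 x 20 diploids over a 2 Mb scaffold (4000 SNPs) plus a
#' 200 kb scaffold (400 SNPs) that deliberately fails the XP-EHH scaffold
#' filters, with the sweep spanning 0.9-1.1 Mb of the long scaffold.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_diploids Diploids per population (default 20).
#' @param scaffolds Named numeric vector of scaffold lengths in bp.
#' @param snp_per_mb SNP density per Mb (default 2000).
#' @param founders Founder haplotypes per population `K` (default 12).
#' @param F_div Balding-Nichols divergence in (0, 1) (default 0.1).
#' @param rho Founder copy-switch rate per bp (default 1e-5).
#' @param mu Per-site allele flip probability (default 5e-4).
#' @param pops Population labels, focal first.
#' @param sweep `NULL` for neutral data, or a list with elements `scaffold`,
#'   `start`, `end`, and optionally `pop` (focal), `f` (dominant-founder
#'   frequency, default 0.85) and `mu_s` (residual flip rate, default 1e-4).
#' @return A validated config of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_diploids = 20L,
                       scaffolds = c(scaffold_1 = 2e6, scaffold_2 = 2e5),
                       snp_per_mb = 2000, founders = 12L, F_div = 0.1,
                       rho = 1e-5, mu = 5e-4, pops = c("PAG", "GO"),
                       sweep = list(scaffold = "scaffold_1",
                                    start = 9e5, end = 1.1e6)) {
  if (!is.null(sweep)) {
    sweep$pop <- sweep$pop %||% pops[1]
    sweep$f <- sweep$f %||% 0.85
    sweep$mu_s <- sweep$mu_s %||% 1e-4
    if (!(sweep$scaffold %in% names(scaffolds))) {
      stop("sweep scaffold not in scaffold list")
    }
    if (sweep$start < 1 || sweep$end > scaffolds[[sweep$scaffold]] ||
          sweep$start > sweep$end) {
      stop("sweep interval outside scaffold")
    }
    if (sweep$f <= 0 || sweep$f > 1) stop("sweep f must be in (0, 1]")
    if (sweep$mu_s < 0) stop("rates must be >= 0")
  }
  if (F_div <= 0 || F_div >= 1) stop("F_div must be in (0, 1)")
  if (rho < 0 || mu < 0) stop("rates must be >= 0")
  if (n_diploids < 2L) stop("need at least 2 diploids per population")
  structure(list(seed = as.integer(seed), n_diploids = as.integer(n_diploids),
                 scaffolds = scaffolds, snp_per_mb = snp_per_mb,
                 founders = as.integer(founders), F_div = F_div, rho = rho,
                 mu = mu, pops = pops, sweep = sweep),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbeta_trunc <- function(n, shape1, shape2, lo = 0.05, hi = 0.95) {
  x <- stats::rbeta(n, shape1, shape2)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rbeta(length(bad), shape1[bad], shape2[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

mosaic_haplotype <- function(founders_mat, pos, rho, mu) {
  S <- length(pos)
  K <- nrow(founders_mat)
  if (S > 1L) {
    switch_here <- stats::runif(S - 1L) < 1 - exp(-rho * diff(pos))
    seg <- cumsum(c(TRUE, switch_here))
  } else {
    seg <- 1L
  }
  n_seg <- seg[S]
  founder_ids <- sample.int(K, n_seg, replace = TRUE)
  al <- founders_mat[cbind(founder_ids[seg], seq_len(S))]
  flip <- stats::runif(S) < mu
  as.integer(xor(al, flip))
}

#' Simulate a two-population phased SNP dataset
#'
#' Fully deterministic given the config seed: identical configs reproduce
#' byte-identical output. See [sim_config()] for the generative model.
#'
#' @param config A [sim_config()].
#' @return List with `variants`, `haplotypes` ([hap_set()]), `genotypes`
#'   (dosage matrix), `pm` (popmap), `scaffolds`, and `truth` (`NULL` for
#'   neutral runs, else a one-row `data.frame` with the sweep interval and
#'   parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_hap <- 2L * config$n_diploids
  pop_names <- config$pops
  sample_ids <- unlist(lapply(pop_names, function(p) {
    sprintf("%s_%02d", p, seq_len(config$n_diploids))
  }))
  pm <- popmap(sample_ids, rep(pop_names, each = config$n_diploids))

  all_scaffold <- character(0)
  all_pos <- integer(0)
  all_ref <- character(0)
  all_alt <- character(0)
  hap_blocks <- list()
  nt <- c("A", "C", "G", "T")

  for (sc in names(config$scaffolds)) {
    L <- config$scaffolds[[sc]]
    S <- max(2L, round(config$snp_per_mb * L / 1e6))
    if (S > L) stop("snp count exceeds available positions on ", sc)
    pos <- sort(sample.int(L, S))
    p_anc <- rbeta_trunc(S, rep(0.8, S), rep(0.8, S))
    ref <- nt[sample.int(4L, S, replace = TRUE)]
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
    shp <- (1 - config$F_div) / config$F_div
    block <- matrix(0L, nrow = 2L * n_hap, ncol = S)
    row0 <- 0L
    for (ip in seq_along(pop_names)) {
      p_pop <- stats::rbeta(S, p_anc * shp, (1 - p_anc) * shp)
      founders <- matrix(stats::rbinom(config$founders * S, 1L,
                                       rep(p_pop, each = config$founders)),
                         nrow = config$founders, ncol = S)
      for (h in seq_len(n_hap)) {
        block[row0 + h, ] <- mosaic_haplotype(founders, pos, config$rho,
                                              config$mu)
      }
      sw <- config$sweep
      if (!is.null(sw) && sw$scaffold == sc && pop_names[ip] == sw$pop) {
        in_sweep <- which(pos >= sw$start & pos <= sw$end)
        is_copy <- stats::runif(n_hap) < sw$f
        for (h in which(is_copy)) {
          flips <- stats::runif(length(in_sweep)) < sw$mu_s
          block[row0 + h, in_sweep] <-
            as.integer(xor(founders[1L, in_sweep], flips))
        }
      }
      row0 <- row0 + n_hap
    }
    all_scaffold <- c(all_scaffold, rep(sc, S))
    all_pos <- c(all_pos, pos)
    all_ref <- c(all_ref, ref)
    all_alt <- c(all_alt, unname(alt))
    hap_blocks[[sc]] <- block
  }

  variants <- variant_table(all_scaffold, all_pos, all_ref, all_alt)
  # block rows: population 1 haplotypes then population 2, two consecutive
  # rows per sample in sample order -- already the hap_set layout
  full <- do.call(cbind, hap_blocks)
  haps <- hap_set(full, sample_ids)
  truth <- NULL
  if (!is.null(config$sweep)) {
    truth <- data.frame(scaffold = config$sweep$scaffold,
                        start = config$sweep$start, end = config$sweep$end,
                        pop = config$sweep$pop, f = config$sweep$f,
                        stringsAsFactors = FALSE)
  }
  list(variants = variants, haplotypes = haps, genotypes = hap_dosage(haps),
       pm = pm, scaffolds = config$scaffolds, truth = truth)
}

#' Simulate a CpG-intactness and methylation fixture
#'
#' Builds per-haplotype locus sequences carrying `"CG"` at each designated
#' site with a population-specific intactness probability (else `"TG"`),
#' plus a per-position mean-methylation table: the mean for a population is
#' its expected intact fraction times a site-level methylation propensity
#' shared across populations, plus seeded Gaussian noise (clamped to
#' [0, 1]).
#'
#' @param seed Integer seed.
#' @param n_hap Haplotypes per population (default 20).
#' @param n_sites Number of CpG sites (default 7, as in a small multi-intron
#'   amplicon panel).
#' @param intact_prob Length-2 vector (focal, reference) or 2 x `n_sites`
#'   matrix of per-site intactness probabilities (default `c(0.9, 0.05)`).
#' @param pops Population labels, focal first.
#' @param noise_sd SD of methylation noise (default 0; zero noise makes the
#'   two populations' mean-methylation vectors exactly proportional).
#' @param spacing Base pairs between consecutive CpG sites (default 20).
#' @return List with `seqs` (named character vector, `"<sample>_<phase>"`),
#'   `cpg_positions`, `meth` (`data.frame`: `position`, `mean_focal`,
#'   `mean_ref`), `pm`, and `truth_intact` (the probabilities used).
#' @export
simulate_cpg_fixture <- function(seed = 1L, n_hap = 20L, n_sites = 7L,
                                 intact_prob = c(0.9, 0.05),
                                 pops = c("PAG", "GO"), noise_sd = 0,
                                 spacing = 20L) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (is.matrix(intact_prob)) {
    stopifnot(nrow(intact_prob) == 2L, ncol(intact_prob) == n_sites)
  } else {
    stopifnot(length(intact_prob) == 2L)
    intact_prob <- matrix(rep(intact_prob, n_sites), nrow = 2L)
  }
  if (any(intact_prob < 0 | intact_prob > 1)) stop("probabilities must be in [0, 1]")
  set.seed(seed)
  cpg_positions <- spacing * seq_len(n_sites)
  len <- spacing * (n_sites + 1L)
  backbone <- sample(c("A", "C", "T"), len, replace = TRUE) # no accidental CG
  n_dip <- ceiling(n_hap / 2)
  seqs <- character(0)
  pm_samples <- character(0)
  pm_pops <- character(0)
  for (ip in 1:2) {
    samples <- sprintf("%s_%02d", pops[ip], seq_len(n_dip))
    pm_samples <- c(pm_samples, samples)
    pm_pops <- c(pm_pops, rep(pops[ip], n_dip))
    for (h in seq_len(n_hap)) {
      s <- backbone
      intact <- stats::runif(n_sites) < intact_prob[ip, ]
      for (j in seq_len(n_sites)) {
        di <- if (intact[j]) c("C", "G") else c("T", "G")
        s[cpg_positions[j] + 0:1] <- di
      }
      nm <- paste0(samples[ceiling(h / 2)], "_", 2L - h %% 2L)
      seqs[nm] <- paste(s, collapse = "")
    }
  }
  propensity <- stats::runif(n_sites, 0.4, 0.9)
  clamp <- function(x) pmin(1, pmax(0, x))
  meth <- data.frame(
    position = cpg_positions,
    mean_focal = clamp(intact_prob[1, ] * propensity +
                         stats::rnorm(n_sites, 0, noise_sd)),
    mean_ref = clamp(intact_prob[2, ] * propensity +
                       stats::rnorm(n_sites, 0, noise_sd)))
  pm <- popmap(pm_samples, pm_pops)
  list(seqs = seqs, cpg_positions = cpg_positions, meth = meth, pm = pm,
       truth_intact = intact_prob)
}
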