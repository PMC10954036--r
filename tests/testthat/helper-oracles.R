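# Independent oracles used to cross-check the estimators. Each is coded by
# a different route than the implementation it checks.

# Weir-Cockerham theta via the nested allele-indicator ANOVA: mean squares
# for populations / individuals-within-populations / alleles-within-
# individuals, then variance components. Independent of the closed-form
# a/b/c route used by fst_per_site().
wc_fst_anova_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  gl <- list(g1, g2)
  r <- 2
  n <- vapply(gl, length, 1)
  N <- sum(n)
  p <- vapply(gl, function(g) mean(g) / 2, 1)
  pbar <- sum(2 * n * p) / sum(2 * n)
  SSG <- sum(vapply(gl, function(g) sum(g == 1) * 0.5, 1))
  SSI <- sum(vapply(seq_len(r), function(i) 2 * sum((gl[[i]] / 2 - p[i])^2), 1))
  SSP <- sum(2 * n * (p - pbar)^2)
  MSG <- SSG / N
  MSI <- SSI / (N - r)
  MSP <- SSP / (r - 1)
  nc <- (2 * N - sum((2 * n)^2) / (2 * N)) / (r - 1)
  s2A <- (MSP - MSI) / nc
  s2B <- (MSI - MSG) / 2
  s2C <- MSG
  s2A / (s2A + s2B + s2C)
}

# pi as the literal mean pairwise difference over all C(n,2) allele pairs
pi_pairwise_oracle <- function(alleles) {
  n <- length(alleles)
  diff <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diff <- diff + as.integer(alleles[i] != alleles[j])
  }
  diff / choose(n, 2)
}

# EHH by exhaustive pair enumeration: fraction of haplotype pairs identical
# over the closed span of columns
ehh_pair_oracle <- function(al, span) {
  n <- nrow(al)
  str <- apply(al[, span, drop = FALSE], 1, paste, collapse = "")
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) same <- same + as.integer(str[i] == str[j])
  }
  same / choose(n, 2)
}

# exact two-sided Fisher p by direct hypergeometric summation over the
# feasible range (the reference stats::fisher.test route is used in tests
# as a second, fully external check)
fisher_hyper_oracle <- function(tab) {
  m1 <- sum(tab[1, ])
  m2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  xs <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(xs, m1, m2, k)
  sum(pr[pr <= pr[xs == tab[1, 1]] * (1 + 1e-7)])
}

# small builders ------------------------------------------------------------

toy_variants <- function(pos, scaffold = "s1") {
  variant_table(rep(scaffold, length(pos)), pos,
                rep("A", length(pos)), rep("T", length(pos)))
}

toy_haps <- function(mat, prefix = "S") {
  n <- nrow(mat) / 2
  hap_set(mat, sprintf("%s%02d", prefix, seq_len(n)))
}

# a smoothed_track built directly (for functions that consume smoothed
# values rather than produce them)
fake_smoothed <- function(values, pos = NULL, scaffold = "s1",
                          sigma_bp = 25000) {
  n <- length(values)
  if (is.null(pos)) pos <- seq_len(n) * 10000L
  df <- data.frame(scaffold = scaffold, pos = pos, value = values,
                   smoothed = values, win_lo = seq_len(n),
                   win_hi = seq_len(n), stringsAsFactors = FALSE)
  attr(df, "sigma_bp") <- sigma_bp
  class(df) <- c("smoothed_track", "data.frame")
  df
}

toy_popmap <- function(n1, n2, pops = c("PAG", "GO"), prefix = "S") {
  popmap(sprintf("%s%02d", prefix, seq_len(n1 + n2)),
         rep(pops, c(n1, n2)))
}

# run the in-memory scan used by end-to-end tests: simulator -> three tests
# -> regions -> intersection, with the thresholds given
run_scan_memory <- function(sim, B_max = 1e6, alpha = 1e-5, z_cut = 5,
                            top_fraction = 0.01, merge_gap = 5e4,
                            sigma_bp = 25000, boot_seed = 1L) {
  fst <- fst_per_site(sim$variants, sim$genotypes, sim$pm, c("PAG", "GO"))
  sm_fst <- gaussian_smooth(fst[fst$defined, c("scaffold", "pos", "value")],
                            sigma_bp = sigma_bp)
  sm_fst <- bootstrap_outlier_pvalues(sm_fst, B_max = B_max, alpha = alpha,
                                      seed = boot_seed)
  pi_f <- pi_variant_site(sim$variants, sim$genotypes, sim$pm, "PAG")
  pi_r <- pi_variant_site(sim$variants, sim$genotypes, sim$pm, "GO")
  both <- pi_f$defined & pi_r$defined
  sm_pi_f <- gaussian_smooth(pi_f[both, c("scaffold", "pos", "value")],
                             sigma_bp = sigma_bp)
  sm_pi_r <- gaussian_smooth(pi_r[both, c("scaffold", "pos", "value")],
                             sigma_bp = sigma_bp)
  z <- pi_ratio_zscore(sm_pi_f, sm_pi_r, z_cut = z_cut)
  hf <- hap_subset(sim$haplotypes, samples = sim$pm$sample[sim$pm$pop == "PAG"])
  hr <- hap_subset(sim$haplotypes, samples = sim$pm$sample[sim$pm$pop == "GO"])
  xp <- xpehh_scan(hf, hr, sim$variants, sim$scaffolds,
                   top_fraction = top_fraction)
  reg_fst <- call_regions(sm_fst[sm_fst$outlier, c("scaffold", "pos")],
                          merge_gap = merge_gap)
  reg_pi <- call_regions(z[z$outlier, c("scaffold", "pos")],
                         merge_gap = merge_gap)
  reg_xp <- call_regions(xp[xp$outlier, c("scaffold", "pos")],
                         merge_gap = merge_gap)
  list(fst = sm_fst, pi_focal = sm_pi_f, pi_ref = sm_pi_r, z = z, xpehh = xp,
       regions_fst = reg_fst, regions_pi = reg_pi, regions_xpehh = reg_xp,
       combined = intersect_tests(reg_fst, reg_pi, reg_xp))
}
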