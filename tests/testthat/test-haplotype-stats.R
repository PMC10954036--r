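test_that("EHH is 1 everywhere for identical haplotypes and collapses to the
           crossing value when haplotypes separate", {
  v <- toy_variants((1:10) * 1000L)
  al <- matrix(rep(c(0L, 1L), each = 10), nrow = 4, ncol = 10, byrow = TRUE)
  al[] <- rep(c(0L, 0L, 0L, 0L), 10) # all identical
  haps <- toy_haps(al)
  p <- ehh_profile(haps, v, core = 5, direction = "downstream")
  expect_true(all(p$ehh == 1))
  expect_equal(attr(p, "truncation"), "scaffold_end")
  # four haplotypes fully separated two SNPs from the core
  al2 <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L))
  haps2 <- toy_haps(al2)
  p2 <- ehh_profile(haps2, toy_variants((1:3) * 100L), core = 1)
  expect_equal(p2$ehh, c(1, 1 / 3, 0)) # pairs: 6 -> 2 -> 0 of C(4,2)
  expect_equal(attr(p2, "truncation"), "cutoff")
})

test_that("EHH equals exhaustive pair enumeration and is monotone", {
  set.seed(53)
  for (rep in 1:5) {
    al <- matrix(rbinom(8 * 20, 1, 0.5), nrow = 8)
    v <- toy_variants(sort(sample.int(1e5, 20)))
    haps <- toy_haps(al)
    core <- sample(3:18, 1)
    for (dir in c("downstream", "upstream")) {
      p <- ehh_profile(haps, v, core, dir, cutoff = 0) # full profile
      step <- if (dir == "downstream") 1L else -1L
      for (i in seq_len(nrow(p))) {
        span <- core:(core + step * (i - 1L))
        expect_identical(p$ehh[i], ehh_pair_oracle(al, span))
      }
      expect_true(all(diff(p$ehh) <= 1e-15))
      expect_true(all(p$ehh >= 0 & p$ehh <= 1))
    }
  }
})

test_that("core EHH equals core-site homozygosity and errors are raised", {
  al <- rbind(c(0L, 1L), c(0L, 0L), c(1L, 1L), c(1L, 0L))
  haps <- toy_haps(al)
  v <- toy_variants(c(100L, 200L))
  p <- ehh_profile(haps, v, core = 1)
  expect_equal(p$ehh[1], 2 * choose(2, 2) / choose(4, 2)) # two groups of 2
  expect_error(ehh_profile(haps, v, core = 5), "out of range")
})

test_that("iHH is the trapezoidal area, scales with distance, and censors
           boundary-limited profiles", {
  # 8 identical haplotypes except the last SNP where they split 4/4
  al <- cbind(matrix(0L, 8, 5), c(rep(0L, 4), rep(1L, 4)))
  pos <- c(0L, 1000L, 2000L, 3000L, 4000L, 5000L)
  # profile downstream from core 1: EHH 1 over 0..4000, drops at 5000
  haps <- toy_haps(al)
  v <- toy_variants(pos + 1L)
  up <- ehh_profile(haps, v, core = 1, "downstream")
  dn <- ehh_profile(haps, v, core = 1, "upstream")
  ehh_last <- ehh_pair_oracle(al, 1:6)
  expect_equal(ihh(up, dn)$ihh, 4000 + (1 + ehh_last) / 2 * 1000)
  # single trapezoid: EHH {1, 0.5 at 1000 bp} gives area 750: haplotypes
  # split 2/2 heterozygous at second SNP...
  al2 <- cbind(rep(0L, 4), c(0L, 0L, 1L, 1L))
  h2 <- toy_haps(al2)
  v2 <- toy_variants(c(1L, 1001L))
  pr <- ehh_profile(h2, v2, 1, "downstream", cutoff = 0.05)
  expect_equal(pr$ehh, c(1, 1 / 3))
  expect_equal(ihh(pr, ehh_profile(h2, v2, 1, "upstream"))$ihh,
               (1 + 1 / 3) / 2 * 1000)
  # doubling inter-SNP distances doubles the area
  v3 <- toy_variants(c(1L, 2001L))
  pr2 <- ehh_profile(h2, v3, 1, "downstream")
  expect_equal(ihh(pr2, ehh_profile(h2, v3, 1, "upstream"))$ihh,
               2 * (1 + 1 / 3) / 2 * 1000)
  # both directions boundary-censored single-point profiles
  one <- toy_haps(matrix(0L, 4, 1))
  vo <- toy_variants(10L)
  io <- ihh(ehh_profile(one, vo, 1, "downstream"),
            ehh_profile(one, vo, 1, "upstream"))
  expect_equal(io$ihh, 0)
  expect_true(io$censored)
})

test_that("XP-EHH raw scores are zero for identical populations and exactly
           antisymmetric under population swap", {
  set.seed(61)
  sim <- simulate_dataset(sim_config(seed = 61, n_diploids = 6,
                                     scaffolds = c(sA = 4e5),
                                     snp_per_mb = 500, sweep = NULL))
  hf <- hap_subset(sim$haplotypes, sim$pm$sample[sim$pm$pop == "PAG"])
  hr <- hap_subset(sim$haplotypes, sim$pm$sample[sim$pm$pop == "GO"])
  expect_warning(same <- xpehh_scan(hf, hf, sim$variants, sim$scaffolds,
                                    min_snps = 10), "constant raw")
  expect_true(all(same$raw[same$defined] == 0))
  a <- xpehh_scan(hf, hr, sim$variants, sim$scaffolds, min_snps = 10)
  b <- xpehh_scan(hr, hf, sim$variants, sim$scaffolds, min_snps = 10)
  expect_identical(a$raw, -b$raw)
  expect_equal(mean(a$normalized, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(a$normalized, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("scaffold filters exclude short or SNP-poor scaffolds and report
           counts when nothing passes", {
  sim <- simulate_dataset(sim_config(seed = 3, n_diploids = 4,
                                     scaffolds = c(long = 5e5, short = 1e5),
                                     snp_per_mb = 400, sweep = NULL))
  hf <- hap_subset(sim$haplotypes, sim$pm$sample[sim$pm$pop == "PAG"])
  hr <- hap_subset(sim$haplotypes, sim$pm$sample[sim$pm$pop == "GO"])
  xp <- xpehh_scan(hf, hr, sim$variants, sim$scaffolds, min_snps = 10)
  expect_setequal(unique(xp$scaffold), "long")
  expect_error(xpehh_scan(hf, hr, sim$variants, sim$scaffolds,
                          min_len = 1e6), "no scaffolds pass")
})

test_that("neutral data flag at most the top fraction, split between signs", {
  sim <- simulate_dataset(sim_config(seed = 71, sweep = NULL))
  hf <- hap_subset(sim$haplotypes, sim$pm$sample[sim$pm$pop == "PAG"])
  hr <- hap_subset(sim$haplotypes, sim$pm$sample[sim$pm$pop == "GO"])
  xp <- xpehh_scan(hf, hr, sim$variants, sim$scaffolds)
  n_def <- sum(xp$defined)
  expect_lte(sum(xp$outlier), ceiling(0.01 * n_def))
  top <- abs(xp$normalized) >= attr(xp, "outlier_threshold")
  expect_gt(sum(top & xp$normalized > 0, na.rm = TRUE), 0)
  expect_gt(sum(top & xp$normalized < 0, na.rm = TRUE), 0)
})

test_that("haplotype spectrum counts exact strings per population", {
  # 10 focal haplotypes, 8 identical; 10 reference haplotypes half/half
  alf <- rbind(matrix(0L, 8, 4), matrix(1L, 2, 4))
  alr <- rbind(matrix(0L, 5, 4), matrix(1L, 5, 4))
  haps <- hap_set(rbind(alf, alr), sprintf("S%02d", 1:10))
  pm <- toy_popmap(5, 5)
  v <- toy_variants(c(100L, 200L, 300L, 400L))
  sp <- haplotype_spectrum(haps, pm, v, "s1", 100, 400)
  expect_equal(unname(sp$dominant["PAG"]), 0.8)
  expect_equal(unname(sp$dominant["GO"]), 0.5)
  expect_equal(sum(sp$haplotypes$count_PAG), 10L)
  expect_equal(sum(sp$haplotypes$freq_GO), 1)
  expect_error(haplotype_spectrum(haps, pm, v, "s1", 500, 600), "no SNPs")
})

test_that("spectrum grouping agrees with a transitive pairwise-identity
           oracle", {
  set.seed(83)
  al <- matrix(rbinom(16 * 6, 1, 0.5), nrow = 16)
  haps <- hap_set(al, sprintf("S%02d", 1:8))
  pm <- toy_popmap(4, 4)
  v <- toy_variants((1:6) * 50L)
  sp <- haplotype_spectrum(haps, pm, v, "s1", 1, 300)
  # oracle: group haplotypes by all-pairs identity, transitive closure
  n <- nrow(al)
  grp <- seq_len(n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (all(al[i, ] == al[j, ])) grp[grp == grp[j]] <- grp[i]
    }
  }
  expect_equal(nrow(sp$haplotypes), length(unique(grp)))
  expect_setequal(as.integer(table(grp)),
                  sp$haplotypes$count_PAG + sp$haplotypes$count_GO)
})

test_that("bifurcation trees split by the next allele and conserve weights", {
  al <- cbind(rep(0L, 8), c(rep(0L, 6), 1L, 1L), rep(0L, 8))
  haps <- toy_haps(al)
  v <- toy_variants(c(100L, 200L, 300L))
  tr <- bifurcation_tree(haps, v, core = 1, max_extent = 2)
  expect_length(tr$roots, 1L)
  kids <- tr$roots[[1]]$children
  expect_equal(sort(vapply(kids, `[[`, 1L, "weight")), c(2L, 6L))
  # no variation beyond the core -> path graph
  al2 <- matrix(0L, 8, 3)
  tr2 <- bifurcation_tree(toy_haps(al2), v, core = 1, max_extent = 2)
  expect_length(tr2$roots[[1]]$children, 1L)
  # weight conservation on random input, truncation flag on overrun
  set.seed(97)
  al3 <- matrix(rbinom(12 * 5, 1, 0.5), nrow = 12)
  tr3 <- bifurcation_tree(hap_set(al3, sprintf("S%02d", 1:6)),
                          toy_variants((1:5) * 10L), core = 2,
                          max_extent = 10)
  expect_true(attr(tr3, "truncated"))
  leaf_sum <- function(node) {
    if (!length(node$children)) return(node$weight)
    sum(vapply(node$children, leaf_sum, 1L))
  }
  expect_equal(sum(vapply(tr3$roots, leaf_sum, 1L)), 12L)
})
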