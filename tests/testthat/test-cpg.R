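make_seqs <- function(intact1, intact2, pos = 5L, len = 12L,
                      pops = c("PAG", "GO")) {
  # one CpG site at `pos`; intact1/intact2 are logical vectors, one entry
  # per haplotype in each population
  base <- strrep("A", len)
  mk <- function(intact) {
    vapply(seq_along(intact), function(i) {
      s <- strsplit(base, "")[[1]]
      s[pos + 0:1] <- if (intact[i]) c("C", "G") else c("T", "G")
      paste(s, collapse = "")
    }, "")
  }
  s1 <- mk(intact1)
  s2 <- mk(intact2)
  n1 <- ceiling(length(intact1) / 2)
  n2 <- ceiling(length(intact2) / 2)
  names(s1) <- paste0(rep(sprintf("%s_%02d", pops[1], 1:n1), each = 2),
                      "_", 1:2)[seq_along(s1)]
  names(s2) <- paste0(rep(sprintf("%s_%02d", pops[2], 1:n2), each = 2),
                      "_", 1:2)[seq_along(s2)]
  pm <- popmap(c(sprintf("%s_%02d", pops[1], 1:n1),
                 sprintf("%s_%02d", pops[2], 1:n2)),
               rep(pops, c(n1, n2)))
  list(seqs = c(s1, s2), pm = pm)
}

test_that("CpG intactness counts CG versus disrupted dinucleotides per
           population", {
  all_cg <- make_seqs(rep(TRUE, 6), rep(TRUE, 6))
  tab <- cpg_intactness(all_cg$seqs, 5L, all_cg$pm)
  expect_equal(tab$intact, c(6L, 6L))
  expect_equal(tab$disrupted, c(0L, 0L))
  # constructed 0.9 vs 0.05 at n = 20 haplotypes: counts (18,2) vs (1,19)
  mix <- make_seqs(rep(c(TRUE, FALSE), c(18, 2)),
                   rep(c(TRUE, FALSE), c(1, 19)))
  tab2 <- cpg_intactness(mix$seqs, 5L, mix$pm)
  expect_equal(tab2$intact, c(18L, 1L))
  expect_equal(tab2$disrupted, c(2L, 19L))
  expect_error(cpg_intactness(mix$seqs, 50L, mix$pm), "beyond sequence end")
})

test_that("ambiguous bases leave the denominator with a message", {
  x <- make_seqs(rep(TRUE, 4), rep(TRUE, 4))
  x$seqs[1] <- sub("CG", "NG", x$seqs[1])
  expect_message(tab <- cpg_intactness(x$seqs, 5L, x$pm), "ambiguous")
  expect_equal(tab$n, c(3L, 4L))
})

test_that("exact 2x2 test matches hand enumeration, margins and oracles", {
  expect_equal(fisher_exact_2x2(rbind(c(2, 0), c(0, 2))), 1 / 3)
  # any zero margin -> single feasible table -> p = 1
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 5))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(3, 0), c(5, 0))), 1)
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(1, 1))), "non-negative")
  set.seed(37)
  for (i in 1:200) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)
    expect_lt(abs(p - fisher_hyper_oracle(tab)), 1e-10)
    expect_lt(abs(p - stats::fisher.test(tab)$p.value), 1e-10)
    expect_gt(p, 0)
    expect_lte(p, 1)
    # invariance under transposition and simultaneous row/column swap
    expect_equal(fisher_exact_2x2(t(tab)), p)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p)
  }
})

test_that("one-sided alternatives follow the hypergeometric tails", {
  tab <- rbind(c(18, 2), c(1, 19))
  expect_equal(fisher_exact_2x2(tab, "greater"),
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tab, "less"),
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-12)
})

test_that("per-site CpG selection tests pair populations correctly", {
  mix <- make_seqs(rep(c(TRUE, FALSE), c(18, 2)),
                   rep(c(TRUE, FALSE), c(1, 19)))
  tab <- cpg_intactness(mix$seqs, 5L, mix$pm)
  res <- cpg_selection_test(tab)
  expect_equal(res$intact_frac_PAG, 0.9)
  expect_equal(res$intact_frac_GO, 0.05)
  expect_lt(res$p, 1e-6)
})

test_that("methylation screen: correlation, fold outliers, and guards", {
  same <- data.frame(position = 1:5, mean_focal = c(.1, .3, .5, .7, .9),
                     mean_ref = c(.1, .3, .5, .7, .9))
  r <- methylation_outliers(same)
  expect_equal(r$r2, 1)
  expect_equal(sum(r$table$outlier), 0L)
  one <- data.frame(position = 1:3, mean_focal = c(.8, .2, .4),
                    mean_ref = c(.1, .2, .4))
  r2 <- methylation_outliers(one)
  expect_identical(r2$table$outlier, c(TRUE, FALSE, FALSE))
  # r^2 against an explicit least-squares oracle
  set.seed(43)
  x <- runif(20)
  y <- pmin(1, pmax(0, 0.3 * x + rnorm(20, 0, 0.1)))
  m <- data.frame(position = 1:20, mean_focal = x, mean_ref = y)
  fit <- lm(y ~ x)
  expect_equal(methylation_outliers(m)$r2, summary(fit)$r.squared,
               tolerance = 1e-12)
  # zero reference mean with positive focal mean is an outlier
  zr <- data.frame(position = 1:3, mean_focal = c(.5, .2, .1),
                   mean_ref = c(0, .2, .1))
  expect_true(methylation_outliers(zr)$table$outlier[1])
  expect_error(methylation_outliers(data.frame(position = 1:3,
                                               mean_focal = rep(.5, 3),
                                               mean_ref = c(.1, .2, .3))),
               "constant")
  expect_error(methylation_outliers(same[1:2, ]), "at least 3")
})

test_that("the CpG fixture generator reproduces its design parameters", {
  fx <- simulate_cpg_fixture(seed = 2, n_hap = 20, n_sites = 7,
                             intact_prob = c(1, 1))
  tab <- cpg_intactness(fx$seqs, fx$cpg_positions, fx$pm)
  expect_true(all(tab$intact == 20L))
  res <- cpg_selection_test(tab)
  expect_true(all(res$p == 1))
  # zero-noise methylation means are exactly proportional across populations
  expect_equal(methylation_outliers(fx$meth, fold = 4)$r2, 1,
               tolerance = 1e-12)
  # deterministic given the seed
  fx2 <- simulate_cpg_fixture(seed = 2, n_hap = 20, n_sites = 7,
                              intact_prob = c(1, 1))
  expect_identical(fx, fx2)
  expect_error(simulate_cpg_fixture(n_sites = 0), "n_sites")
})
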