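#' Per-SNP Weir-Cockerham FST between two populations
#'
#' Computes the two-population Weir-Cockerham (1984) theta per site from
#' diploid genotypes: the among-population variance component `a` over the
#' total `a + b + c`, with sample-size correction and the heterozygosity
#' terms of the full diploid hierarchy. This is the two-level
#' AMOVA-consistent estimator of the fixation index.
#'
#' Sites monomorphic across both populations have no variance to partition
#' and are flagged undefined. Negative estimates are retained by default so
#' that downstream smoothing and the bootstrap null are not distorted;
#' `clamp_negative = TRUE` truncates them at zero.
#'
#' @param variants A [variant_table()].
#' @param genotypes Dosage matrix (sites x samples, entries 0/1/2/NA).
#' @param pm Population map from [popmap()]/[read_popmap()].
#' @param pop_pair Character vector of length 2: focal then reference
#'   population label.
#' @param clamp_negative Truncate negative theta at 0 (default `FALSE`).
#' @return `data.frame`: `scaffold`, `pos`, `value` (theta), `n_focal`,
#'   `n_ref` (non-missing allele copies), `defined`.
#' @export
fst_per_site <- function(variants, genotypes, pm, pop_pair,
                         clamp_negative = FALSE) {
  stopifnot(length(pop_pair) == 2L, nrow(genotypes) == nrow(variants))
  g1 <- genotypes[, pm$sample[pm$pop == pop_pair[1]], drop = FALSE]
  g2 <- genotypes[, pm$sample[pm$pop == pop_pair[2]], drop = FALSE]
  if (ncol(g1) < 2L || ncol(g2) < 2L) stop("population too small: need >= 2 samples in each of ",
                                           paste(pop_pair, collapse = ", "))
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  if (all(n1 < 2L) || all(n2 < 2L)) stop("population too small: a population has < 2 genotyped samples at every site")
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  defined <- n1 >= 2L & n2 >= 2L & !is.na(theta) & denom != 0
  theta[!defined] <- NA_real_
  if (clamp_negative) theta <- pmax(theta, 0)
  data.frame(scaffold = variants$scaffold, pos = variants$pos,
             value = theta, n_focal = 2L * n1, n_ref = 2L * n2,
             defined = defined, stringsAsFactors = FALSE)
}

#' Per-site variant nucleotide diversity within one population
#'
#' pi per variant site with sample-size correction:
#' \eqn{\pi = \frac{n}{n-1}\,(1 - \sum_a p_a^2)}, where `n` is the number of
#' non-missing allele copies at the site. For a biallelic site this equals
#' \eqn{2pq\,n/(n-1)}, which is identically the mean pairwise difference over
#' all haplotype pairs. Sites with `n < 2` are undefined (not zero); there is
#' no per-bp normalization by locus length.
#'
#' @inheritParams fst_per_site
#' @param pop Population label.
#' @return `data.frame`: `scaffold`, `pos`, `value` (pi), `n` (allele
#'   copies), `defined`.
#' @export
pi_variant_site <- function(variants, genotypes, pm, pop) {
  g <- genotypes[, pm$sample[pm$pop == pop], drop = FALSE]
  if (ncol(g) == 0L) stop("unknown population: ", pop)
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n
  pi <- ifelse(n >= 2, (n / (n - 1)) * (1 - p^2 - (1 - p)^2), NA_real_)
  data.frame(scaffold = variants$scaffold, pos = variants$pos,
             value = pi, n = as.integer(n), defined = n >= 2,
             stringsAsFactors = FALSE)
}
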