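#' Tabulate CpG-site intactness across populations
#'
#' For each designated CpG position, counts haplotypes carrying an intact
#' CG dinucleotide versus a disrupted one in each population. A haplotype is
#' intact at a site iff the dinucleotide at `(pos, pos + 1)` of its aligned
#' locus sequence is exactly `"CG"` (methylated cytosines are hypermutable
#' toward thymine, so the typical disruption is a C-to-T transition giving
#' `"TG"`). Sequences with an ambiguous base at either position are excluded
#' from that site's denominator, with a message.
#'
#' @param seqs Locus sequences, one per haplotype: a named character vector
#'   or `Biostrings::DNAStringSet` with names `"<sample>_<phase>"`, all
#'   aligned to the same locus reference.
#' @param cpg_positions Integer vector: reference coordinate of the C of
#'   each CpG site (1-based).
#' @param pm Population map (sample -> population).
#' @param locus Optional locus/intron identifier recorded in the output.
#' @return `data.frame` with one row per (site, population): `locus`,
#'   `position`, `pop`, `intact`, `disrupted`, `n`.
#' @export
cpg_intactness <- function(seqs, cpg_positions, pm, locus = "locus") {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) stop("sequences must be named <sample>_<phase>")
  samp <- sub("_[0-9]+$", "", names(seqs))
  pop <- pm$pop[match(samp, pm$sample)]
  if (anyNA(pop)) {
    stop("sequence sample(s) missing from popmap: ",
         paste(unique(samp[is.na(pop)]), collapse = ", "))
  }
  if (any(cpg_positions < 1L) || any(cpg_positions + 1L > nchar(seqs[1]))) {
    stop("CpG position beyond sequence end")
  }
  pops <- attr(pm, "populations")
  out <- list()
  n_ambig <- 0L
  for (ps in cpg_positions) {
    di <- toupper(substr(seqs, ps, ps + 1L))
    ok <- grepl("^[ACGT][ACGT]$", di)
    n_ambig <- n_ambig + sum(!ok)
    for (p in pops) {
      use <- ok & pop == p
      out[[length(out) + 1L]] <- data.frame(
        locus = locus, position = ps, pop = p,
        intact = sum(di[use] == "CG"),
        disrupted = sum(di[use] != "CG"),
        n = sum(use), stringsAsFactors = FALSE)
    }
  }
  if (n_ambig > 0L) {
    message("cpg_intactness: excluded ", n_ambig,
            " ambiguous-base observation(s)")
  }
  do.call(rbind, out)
}

#' Exact test of a 2x2 contingency table
#'
#' Fisher's exact test computed by full enumeration over the feasible cell
#' range under fixed margins. The two-sided p-value sums the hypergeometric
#' point probabilities of every table at most as probable as the observed
#' one (relative tie tolerance 1e-12). Any zero margin admits a single
#' feasible table, so p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = populations, columns = intact/disrupted).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the `[1,1]` cell.
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  m1 <- sum(tab[1, ])  # row 1 margin
  m2 <- sum(tab[2, ])
  k <- sum(tab[, 1])   # column 1 margin
  if (m1 + m2 == 0) stop("empty table")
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  if (lo == hi) return(1) # zero margin: single feasible table
  xs <- lo:hi
  probs <- stats::dhyper(xs, m1, m2, k)
  p_obs <- probs[match(tab[1, 1], xs)]
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-12)]),
              less = sum(probs[xs <= tab[1, 1]]),
              greater = sum(probs[xs >= tab[1, 1]]))
  min(1, p) # guard against summation roundoff just above 1

}

#' Per-site exact tests of CpG intactness between two populations
#'
#' @param cpg_table Output of [cpg_intactness()] for exactly two
#'   populations.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return `data.frame` with one row per site: intact fractions per
#'   population and the exact p-value.
#' @export
cpg_selection_test <- function(cpg_table, alternative = "two.sided") {
  pops <- unique(cpg_table$pop)
  if (length(pops) != 2L) stop("need exactly two populations")
  sites <- unique(cpg_table[, c("locus", "position")])
  res <- lapply(seq_len(nrow(sites)), function(i) {
    sub <- cpg_table[cpg_table$locus == sites$locus[i] &
                       cpg_table$position == sites$position[i], ]
    sub <- sub[match(pops, sub$pop), ]
    tab <- rbind(c(sub$intact[1], sub$disrupted[1]),
                 c(sub$intact[2], sub$disrupted[2]))
    data.frame(locus = sites$locus[i], position = sites$position[i],
               intact_frac_1 = sub$intact[1] / sub$n[1],
               intact_frac_2 = sub$intact[2] / sub$n[2],
               p = fisher_exact_2x2(tab, alternative = alternative),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[3:4] <- paste0("intact_frac_", pops)
  out
}

#' Methylation correlation and fold-change outlier screen
#'
#' Computes the squared Pearson correlation of per-position mean methylation
#' between the two populations and flags positions where the focal mean is
#' at least `fold` times the reference mean (a reference mean of zero with a
#' positive focal mean is also an outlier). This screens for mutable CpG
#' positions whose methylation is population-specifically lost.
#'
#' @param meth `data.frame` with columns `position`, `mean_focal`,
#'   `mean_ref` (methylation fractions in `[0, 1]`); at least 3 positions.
#' @param fold Fold-change threshold (default 4).
#' @return List with `r2` and `table` (the input plus `ratio` and `outlier`
#'   columns).
#' @export
methylation_outliers <- function(meth, fold = 4) {
  if (nrow(meth) < 3L) stop("need at least 3 positions for correlation")
  if (any(meth$mean_focal < 0 | meth$mean_focal > 1 |
            meth$mean_ref < 0 | meth$mean_ref > 1)) {
    stop("methylation fractions must lie in [0, 1]")
  }
  if (stats::sd(meth$mean_focal) == 0 || stats::sd(meth$mean_ref) == 0) {
    stop("constant methylation vector: correlation undefined")
  }
  r2 <- stats::cor(meth$mean_focal, meth$mean_ref)^2
  ratio <- ifelse(meth$mean_ref == 0,
                  ifelse(meth$mean_focal > 0, Inf, NA_real_),
                  meth$mean_focal / meth$mean_ref)
  out <- meth
  out$ratio <- ratio
  out$outlier <- !is.na(ratio) & ratio >= fold
  list(r2 = r2, table = out)
}
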