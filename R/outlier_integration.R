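#' Merge flagged SNP positions into candidate regions
#'
#' Consecutive flagged SNPs on the same scaffold are merged while the gap
#' between neighbors is at most `merge_gap`; region bounds snap to the first
#' and last member SNP positions (intervals are reported SNP-bounded,
#' 1-based inclusive). The default gap of 50 kb is twice the smoothing
#' sigma, keeping regions consistent with the kernel scale.
#'
#' @param flagged `data.frame` with columns `scaffold`, `pos` of flagged
#'   SNPs (any order).
#' @param merge_gap Maximum within-region gap in bp (default 5e4).
#' @return `data.frame`: `scaffold`, `start`, `end`, `n_snps`.
#' @export
call_regions <- function(flagged, merge_gap = 5e4) {
  if (nrow(flagged) == 0L) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  flagged <- flagged[order(flagged$scaffold, flagged$pos), , drop = FALSE]
  out <- lapply(split(flagged$pos, flagged$scaffold), function(pos) {
    brk <- cumsum(c(0L, as.integer(diff(pos) > merge_gap)))
    do.call(rbind, lapply(split(pos, brk), function(p) {
      data.frame(start = min(p), end = max(p), n_snps = length(p))
    }))
  })
  res <- do.call(rbind, Map(function(s, df) {
    cbind(data.frame(scaffold = s, stringsAsFactors = FALSE), df)
  }, names(out), out))
  rownames(res) <- NULL
  res[order(match(res$scaffold, unique(flagged$scaffold)), res$start), ]
}

ranges_of <- function(regions, scaffold) {
  r <- regions[regions$scaffold == scaffold, , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(start = r$start, end = r$end))
}

#' Intersect candidate regions from the three selection tests
#'
#' Combined regions are the maximal intervals simultaneously covered by at
#' least one region from each of the three test-specific sets (interval
#' union per test, then three-way intersection). The operation is symmetric
#' in its arguments.
#'
#' @param regions_fst,regions_pi,regions_xpehh Region `data.frame`s from
#'   [call_regions()].
#' @return `data.frame`: `scaffold`, `start`, `end`, `support` (always
#'   `"fst,pi,xpehh"` for combined regions). Empty when no triple overlap
#'   exists.
#' @export
intersect_tests <- function(regions_fst, regions_pi, regions_xpehh) {
  sc <- intersect(intersect(unique(regions_fst$scaffold),
                            unique(regions_pi$scaffold)),
                  unique(regions_xpehh$scaffold))
  out <- lapply(sc, function(s) {
    r <- IRanges::intersect(
      IRanges::intersect(ranges_of(regions_fst, s), ranges_of(regions_pi, s)),
      ranges_of(regions_xpehh, s))
    if (!length(r)) return(NULL)
    data.frame(scaffold = s, start = IRanges::start(r), end = IRanges::end(r),
               support = "fst,pi,xpehh", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), support = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarize a candidate sweep region
#'
#' Collects the headline observables for one region: maxima of smoothed and
#' per-SNP FST, minimum diversity-ratio Z, maximum normalized XP-EHH over
#' member SNPs; the percent reduction of focal-population smoothed diversity
#' inside the region relative to the same scaffold outside it (genome-wide
#' baseline as fallback, with a warning, when the region covers the whole
#' scaffold); and the dominant haplotype frequency per population over the
#' region SNPs.
#'
#' @param region One-row `data.frame` with `scaffold`, `start`, `end`.
#' @param fst_sm `smoothed_track` of FST (with or without bootstrap columns).
#' @param pi_focal_sm,pi_ref_sm Smoothed pi tracks.
#' @param z_track Output of [pi_ratio_zscore()].
#' @param xp_track Output of [xpehh_scan()], or `NULL`.
#' @param haps,pm,variants Haplotypes, popmap and variant table for the
#'   haplotype spectrum (any of them `NULL` to skip it).
#' @return One-row `data.frame` of summary statistics.
#' @export
summarize_region <- function(region, fst_sm, pi_focal_sm, pi_ref_sm,
                             z_track = NULL, xp_track = NULL,
                             haps = NULL, pm = NULL, variants = NULL) {
  s <- region$scaffold[1]
  a <- region$start[1]
  b <- region$end[1]
  inside <- function(tr) tr$scaffold == s & tr$pos >= a & tr$pos <= b
  in_f <- inside(fst_sm)
  if (!any(inside(pi_focal_sm))) stop("region has no member SNPs")
  out_pi <- pi_focal_sm$scaffold == s & !inside(pi_focal_sm)
  if (!any(out_pi)) {
    warning("no outside baseline on scaffold ", s,
            "; using genome-wide baseline")
    out_pi <- !inside(pi_focal_sm)
    if (!any(out_pi)) stop("no outside baseline")
  }
  mean_in <- mean(pi_focal_sm$smoothed[inside(pi_focal_sm)])
  mean_out <- mean(pi_focal_sm$smoothed[out_pi])
  res <- data.frame(
    scaffold = s, start = a, end = b,
    n_snps = sum(inside(pi_focal_sm)),
    max_smoothed_fst = if (any(in_f)) max(fst_sm$smoothed[in_f]) else NA_real_,
    max_point_fst = if (any(in_f)) max(fst_sm$value[in_f]) else NA_real_,
    min_p = if (!is.null(fst_sm$p) && any(in_f)) min(fst_sm$p[in_f]) else NA_real_,
    pi_reduction_pct = 100 * (1 - mean_in / mean_out),
    min_z = if (!is.null(z_track) && any(inside(z_track)))
      min(z_track$z[inside(z_track)]) else NA_real_,
    max_xpehh = if (!is.null(xp_track) && any(inside(xp_track)))
      suppressWarnings(max(xp_track$normalized[inside(xp_track)],
                           na.rm = TRUE)) else NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(haps) && !is.null(pm) && !is.null(variants)) {
    spec <- haplotype_spectrum(haps, pm, variants, s, a, b)
    for (p in names(spec$dominant)) {
      res[[paste0("dominant_freq_", p)]] <- spec$dominant[[p]]
    }
  }
  res
}

#' Jaccard overlap of two scaffold intervals
#'
#' @param a,b One-row `data.frame`s with `scaffold`, `start`, `end`.
#' @return Intersection length over union length (0 when scaffolds differ).
#' @export
region_jaccard <- function(a, b) {
  if (a$scaffold[1] != b$scaffold[1]) return(0)
  inter <- max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]) + 1)
  uni <- max(a$end[1], b$end[1]) - min(a$start[1], b$start[1]) + 1
  inter / uni
}
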