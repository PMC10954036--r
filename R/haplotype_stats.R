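#' EHH decay profile from a core SNP
#'
#' Extended haplotype homozygosity at extension `k` is the probability that
#' two randomly drawn haplotypes are identical over the closed SNP span from
#' the core to `k`: grouping haplotypes by identity over the span,
#' \eqn{EHH_k = \sum_h \binom{n_h}{2} / \binom{n}{2}}. The profile starts at
#' the core (where EHH equals the haplotype homozygosity of the core site)
#' and is recorded until it first drops below `cutoff` (that crossing value
#' is included) or the scaffold end is reached.
#'
#' @param haps A [hap_set()] restricted to one population; no missing
#'   alleles are allowed.
#' @param variants [variant_table()] for the same sites (used for positions;
#'   the profile never crosses scaffold boundaries).
#' @param core Site index (row of `variants`, 1-based) of the core SNP.
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param cutoff EHH decay cutoff (default 0.05).
#' @return `data.frame` with columns `site` (row index into `variants`),
#'   `pos`, `distance_bp`, `ehh`; attribute `truncation` is `"cutoff"` or
#'   `"scaffold_end"`.
#' @export
ehh_profile <- function(haps, variants, core,
                        direction = c("downstream", "upstream"),
                        cutoff = 0.05) {
  direction <- match.arg(direction)
  if (core < 1L || core > nrow(variants)) stop("core index out of range")
  if (nrow(haps$alleles) < 2L) stop("need at least 2 haplotypes")
  sc <- variants$scaffold[core]
  span <- which(variants$scaffold == sc)
  al <- haps$alleles[, span, drop = FALSE]
  pos <- variants$pos[span]
  core_l <- match(core, span)
  step <- if (direction == "downstream") 1L else -1L
  prof <- ehh_profile_cpp(al, as.numeric(pos), core_l - 1L, step, cutoff)
  cols <- prof$cols + 1L
  out <- data.frame(site = span[cols], pos = pos[cols],
                    distance_bp = abs(pos[cols] - pos[core_l]),
                    ehh = prof$ehh)
  attr(out, "truncation") <- if (prof$boundary) "scaffold_end" else "cutoff"
  attr(out, "core") <- core
  out
}

#' Integrated EHH (iHH) from a pair of decay profiles
#'
#' Trapezoidal integral of EHH over physical distance, upstream and
#' downstream summed. Integration stops at the first profile point below the
#' decay cutoff (the final trapezoid up to that point is included). If a
#' profile ended at a scaffold boundary while still above the cutoff the
#' result is flagged boundary-censored; a profile of length one in both
#' directions yields `ihh = 0`, censored.
#'
#' @param up,down Profiles from [ehh_profile()] sharing the same core.
#' @return List with `ihh` (bp-weighted area) and `censored` (logical).
#' @export
ihh <- function(up, down) {
  if (!identical(attr(up, "core"), attr(down, "core"))) {
    stop("profiles do not share a core")
  }
  area <- function(p) {
    if (nrow(p) < 2L) return(0)
    sum(diff(p$distance_bp) * (head(p$ehh, -1) + tail(p$ehh, -1)) / 2)
  }
  censored <- attr(up, "truncation") == "scaffold_end" ||
    attr(down, "truncation") == "scaffold_end" ||
    (nrow(up) == 1L && nrow(down) == 1L && up$ehh[1] >= 0.05)
  list(ihh = area(up) + area(down), censored = censored)
}

#' Cross-population XP-EHH scan
#'
#' For every core SNP on scaffolds passing the length and SNP-count filters,
#' computes pooled iHH in the focal and reference population and the raw
#' score \eqn{\ln(iHH_{focal}/iHH_{ref})}. Raw scores are normalized by the
#' genome-wide mean and standard deviation to account for genome-wide
#' differences in haplotype length between the populations. A core is an
#' outlier when its |normalized| score reaches the empirical
#' `1 - top_fraction` quantile of |normalized| *and* the score is positive
#' (extended haplotypes in the focal population). Cores whose integration
#' hit a scaffold end before the EHH cutoff are kept but flagged
#' boundary-censored (`strict = TRUE` drops them); cores with zero iHH in
#' either population are undefined and excluded from normalization.
#'
#' @param haps_focal,haps_ref [hap_set()]s over the same sites.
#' @param variants [variant_table()] for those sites.
#' @param scaffolds Named vector of scaffold lengths in bp.
#' @param cutoff EHH decay cutoff ending integration (default 0.05).
#' @param min_len Minimum scaffold length; scaffolds must exceed this
#'   (default 3e5, i.e. > 300 kb).
#' @param min_snps Minimum SNP count; scaffolds must exceed this
#'   (default 20).
#' @param top_fraction Outlier tail fraction of |normalized| (default 0.01).
#' @param strict Drop boundary-censored cores before normalization.
#' @return `data.frame`: `scaffold`, `pos`, `site`, `ihh_focal`, `ihh_ref`,
#'   `raw`, `normalized`, `outlier`, `censored`, `defined`. Attribute
#'   `outlier_threshold` records the empirical |normalized| quantile used.
#' @export
xpehh_scan <- function(haps_focal, haps_ref, variants, scaffolds,
                       cutoff = 0.05, min_len = 3e5, min_snps = 20,
                       top_fraction = 0.01, strict = FALSE) {
  check_scaffolds(scaffolds, variants)
  counts <- table(variants$scaffold)
  sc_all <- unique(variants$scaffold)
  pass <- sc_all[scaffolds[sc_all] > min_len & counts[sc_all] > min_snps]
  if (!length(pass)) {
    stop("no scaffolds pass filters (length > ", min_len, ": ",
         sum(scaffolds[sc_all] > min_len), "/", length(sc_all),
         "; SNPs > ", min_snps, ": ",
         sum(counts[sc_all] > min_snps), "/", length(sc_all), ")")
  }
  res <- lapply(pass, function(s) {
    span <- which(variants$scaffold == s)
    pos <- as.numeric(variants$pos[span])
    f <- ihh_scan_cpp(haps_focal$alleles[, span, drop = FALSE], pos, cutoff)
    r <- ihh_scan_cpp(haps_ref$alleles[, span, drop = FALSE], pos, cutoff)
    data.frame(scaffold = s, pos = variants$pos[span], site = span,
               ihh_focal = f$ihh, ihh_ref = r$ihh,
               censored = f$censored | r$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (strict) out <- out[!out$censored, , drop = FALSE]
  out$defined <- out$ihh_focal > 0 & out$ihh_ref > 0
  # log difference rather than log of the ratio: exactly antisymmetric
  # under population swap
  out$raw <- ifelse(out$defined, log(out$ihh_focal) - log(out$ihh_ref),
                    NA_real_)
  d <- out$defined
  if (sum(d) < 2L) stop("fewer than 2 defined XP-EHH cores")
  out$normalized <- NA_real_
  s <- stats::sd(out$raw[d])
  if (s == 0) {
    warning("constant raw XP-EHH track (identical haplotype structure?); ",
            "normalized scores set to 0, no outliers")
    out$normalized[d] <- 0
    out$outlier <- FALSE
    attr(out, "outlier_threshold") <- NA_real_
    return(out)
  }
  out$normalized[d] <- (out$raw[d] - mean(out$raw[d])) / s
  thr <- stats::quantile(abs(out$normalized[d]), 1 - top_fraction,
                         names = FALSE)
  out$outlier <- !is.na(out$normalized) &
    abs(out$normalized) >= thr & out$normalized > 0
  attr(out, "outlier_threshold") <- thr
  out
}

#' Haplotype spectrum over a scaffold interval
#'
#' Groups haplotypes by exact allele-string identity over the SNPs inside an
#' interval and tabulates counts and frequencies per population, including
#' the dominant (modal) haplotype frequency.
#'
#' @param haps A [hap_set()] (all populations together).
#' @param pm Population map.
#' @param variants [variant_table()].
#' @param scaffold,start,end Interval (1-based inclusive) containing at
#'   least one SNP.
#' @return List with `haplotypes` (`data.frame`: `haplotype` string, one
#'   count/frequency column pair per population) and `dominant` (named
#'   vector of per-population dominant haplotype frequencies).
#' @export
haplotype_spectrum <- function(haps, pm, variants, scaffold, start, end) {
  sel <- which(variants$scaffold == scaffold & variants$pos >= start &
                 variants$pos <= end)
  if (!length(sel)) stop("interval contains no SNPs")
  al <- haps$alleles[, sel, drop = FALSE]
  if (anyNA(al)) stop("missing alleles in interval")
  str <- apply(al, 1L, paste, collapse = "")
  hap_pop <- pm$pop[match(haps$haplotype_of_sample$sample, pm$sample)]
  if (anyNA(hap_pop)) stop("haplotype sample(s) missing from popmap")
  pops <- attr(pm, "populations")
  uniq <- unique(str)
  tab <- data.frame(haplotype = uniq, stringsAsFactors = FALSE)
  dominant <- stats::setNames(numeric(length(pops)), pops)
  for (p in pops) {
    cnt <- as.integer(table(factor(str[hap_pop == p], levels = uniq)))
    tab[[paste0("count_", p)]] <- cnt
    tab[[paste0("freq_", p)]] <- cnt / sum(cnt)
    dominant[p] <- max(cnt) / sum(cnt)
  }
  list(haplotypes = tab[order(-rowSums(tab[grep("^count_", names(tab))])), ],
       dominant = dominant)
}

#' Haplotype bifurcation tree from a core SNP
#'
#' Nested tree of allele-string prefixes extending from the core: the root
#' level splits haplotypes by core allele; each subsequent level splits by
#' the next SNP's allele in the chosen direction. Leaf weights sum to the
#' number of haplotypes. The structure backs bifurcation diagrams in which
#' branch thickness is proportional to haplotype count.
#'
#' @inheritParams ehh_profile
#' @param max_extent Maximum number of SNPs beyond the core to include; if
#'   it overruns the scaffold the tree is truncated and flagged.
#' @return Nested list: each node has `allele_prefix`, `weight`, `site`,
#'   and `children`; attribute `truncated` indicates scaffold overrun.
#' @export
bifurcation_tree <- function(haps, variants, core,
                             direction = c("downstream", "upstream"),
                             max_extent = 10L) {
  direction <- match.arg(direction)
  if (anyNA(haps$alleles)) stop("missing alleles")
  sc <- variants$scaffold[core]
  span <- which(variants$scaffold == sc)
  core_l <- match(core, span)
  step <- if (direction == "downstream") 1L else -1L
  want <- core_l + step * seq_len(max_extent)
  ok <- want >= 1L & want <= length(span)
  truncated <- any(!ok)
  sites <- span[c(core_l, want[ok])]
  al <- haps$alleles[, sites, drop = FALSE]
  build <- function(rows, depth) {
    prefix <- paste(al[rows[1], seq_len(depth)], collapse = "")
    node <- list(allele_prefix = prefix, weight = length(rows),
                 site = sites[depth], children = list())
    if (depth < length(sites)) {
      for (a in sort(unique(al[rows, depth + 1L]))) {
        sub <- rows[al[rows, depth + 1L] == a]
        node$children[[length(node$children) + 1L]] <- build(sub, depth + 1L)
      }
    }
    node
  }
  roots <- lapply(sort(unique(al[, 1L])), function(a) {
    build(which(al[, 1L] == a), 1L)
  })
  structure(list(core = core, direction = direction, roots = roots),
            truncated = truncated, class = "bifurcation_tree")
}

#' @export
print.bifurcation_tree <- function(x, ...) {
  rec <- function(node, indent) {
    cat(strrep(" ", indent), node$allele_prefix, " (", node$weight, ")\n",
        sep = "")
    for (ch in node$children) rec(ch, indent + 2L)
  }
  cat("bifurcation tree from site", x$core, "(", x$direction, ")\n")
  for (r in x$roots) rec(r, 1L)
  invisible(x)
}
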