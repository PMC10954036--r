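#' Gaussian-kernel smoothing of a per-SNP track
#'
#' Smooths a per-site statistic along each scaffold with a Gaussian weight
#' function centered on each SNP:
#' \deqn{s_c = \sum_j w_j x_j / \sum_j w_j,\qquad
#'       w_j = \exp(-(pos_j - pos_c)^2 / 2\sigma^2)}
#' over all sites within 3 sigma of the center on the same scaffold (weights
#' below \eqn{e^{-4.5}} are discarded; the center itself has weight 1).
#' Smoothing never crosses scaffold boundaries.
#'
#' @param track `data.frame` with columns `scaffold`, `pos`, `value`; rows
#'   must be defined (finite) values sorted by position within scaffold.
#'   Tracks from [fst_per_site()]/[pi_variant_site()] should be subset to
#'   `defined` rows first.
#' @param sigma_bp Kernel standard deviation in bp (default 25000, i.e. the
#'   25 kb scale suited to fragmented assemblies).
#' @return The input with columns `smoothed`, `win_lo`, `win_hi` (row index
#'   range of each window) added; class `smoothed_track`, attribute
#'   `sigma_bp`.
#' @export
gaussian_smooth <- function(track, sigma_bp = 25000) {
  if (nrow(track) == 0L) stop("empty track")
  if (anyNA(track$value) || any(!is.finite(track$value))) {
    stop("track contains undefined values; subset to defined sites first")
  }
  sc <- factor(track$scaffold, levels = unique(track$scaffold))
  if (any(unlist(tapply(track$pos, sc, function(p) diff(p) <= 0)))) {
    stop("track positions must be strictly increasing within scaffold")
  }
  n <- nrow(track)
  smoothed <- numeric(n)
  win_lo <- integer(n)
  win_hi <- integer(n)
  offset <- 0L
  for (s in levels(sc)) {
    idx <- which(sc == s)
    pos <- track$pos[idx]
    val <- track$value[idx]
    m <- length(idx)
    lo <- findInterval(pos - 3 * sigma_bp, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + 3 * sigma_bp, pos)
    for (i in seq_len(m)) {
      j <- lo[i]:hi[i]
      w <- exp(-((pos[j] - pos[i])^2) / (2 * sigma_bp^2))
      smoothed[offset + i] <- sum(w * val[j]) / sum(w)
    }
    win_lo[idx] <- offset + lo
    win_hi[idx] <- offset + hi
    offset <- offset + m
  }
  out <- track
  out$smoothed <- smoothed
  out$win_lo <- win_lo
  out$win_hi <- win_hi
  attr(out, "sigma_bp") <- sigma_bp
  class(out) <- c("smoothed_track", class(track))
  out
}

window_weights <- function(sm) {
  sigma <- attr(sm, "sigma_bp")
  lapply(seq_len(nrow(sm)), function(i) {
    j <- sm$win_lo[i]:sm$win_hi[i]
    w <- exp(-((sm$pos[j] - sm$pos[i])^2) / (2 * sigma^2))
    w / sum(w)
  })
}

#' Bootstrap outlier p-values for a smoothed track
#'
#' Tests each smoothed window against a null distribution of genome-wide
#' values resampled into the observed window geometry: `|window|` values are
#' drawn with replacement from the genome-wide pool of per-site statistics
#' and combined with the window's own Gaussian weights; the upper-tail
#' p-value is \eqn{p = (1 + k)/(1 + B)} with `k` the number of resampled
#' smoothed values at or above the observed one (never exactly zero, so a
#' claim of `p < 1e-5` requires at least a million replicates).
#'
#' Replicates escalate through B = 1e2, 1e3, ..., up to `B_max`; a window
#' moves to the next level only while its current estimate satisfies
#' `p <= 100/B`, concentrating effort on the tail.
#'
#' @param sm A `smoothed_track` from [gaussian_smooth()].
#' @param pool Genome-wide pool of defined per-site raw values (defaults to
#'   the track's own raw `value` column).
#' @param B_max Maximum replicates per window (default 1e7).
#' @param alpha Outlier threshold on p (default 1e-5).
#' @param seed Optional integer; if given, `set.seed(seed)` is applied
#'   before resampling.
#' @param indep_budget Per-level total-draw budget below which every window
#'   draws its own independent replicates; above it one replicate draw
#'   matrix is shared across the windows at that level (each window's p
#'   remains an exact marginal bootstrap estimate).
#' @return `sm` with columns `p`, `B_used` and `outlier` added.
#' @export
bootstrap_outlier_pvalues <- function(sm, pool = NULL, B_max = 1e7,
                                      alpha = 1e-5, seed = NULL,
                                      indep_budget = 3e8) {
  stopifnot(inherits(sm, "smoothed_track"))
  if (is.null(pool)) pool <- sm$value
  if (any(!is.finite(pool))) stop("non-finite values in bootstrap pool")
  if (B_max < 100) stop("B_max below the first escalation level (100)")
  if (!is.null(seed)) set.seed(seed)
  levels_B <- 10^(2:7)
  levels_B <- c(levels_B[levels_B < B_max], B_max)
  wts <- window_weights(sm)
  obs <- sm$smoothed
  n <- nrow(sm)
  p <- rep(NA_real_, n)
  B_used <- rep(NA_real_, n)
  active <- seq_len(n)
  tol <- 1e-9
  for (B in levels_B) {
    msize <- vapply(wts[active], length, 1L)
    cost <- B * sum(msize)
    if (cost <= indep_budget) {
      k <- boot_indep_cpp(pool, wts[active], obs[active], as.integer(B), tol)
    } else {
      mmax <- max(msize)
      W <- matrix(0, nrow = mmax, ncol = length(active))
      for (i in seq_along(active)) W[seq_len(msize[i]), i] <- wts[[active[i]]]
      chunk <- max(1L, as.integer(min(B, floor(1.5e7 / mmax))))
      k <- boot_shared_cpp(pool, W, obs[active], B, chunk, tol)
    }
    p[active] <- (1 + k) / (1 + B)
    B_used[active] <- B
    if (B >= B_max) break
    active <- active[p[active] <= 100 / B]
    if (!length(active)) break
  }
  sm$p <- p
  sm$B_used <- B_used
  sm$outlier <- p < alpha
  sm
}

#' Nucleotide-diversity ratio Z-score scan
#'
#' Standardizes the per-window log2 ratio of smoothed diversity,
#' \eqn{x_i = \log_2(\pi_{focal}/\pi_{ref})}, into
#' \eqn{Z = (x_i - \bar x)/\mathrm{s.d.}(x)} over all windows genome-wide.
#' Windows where either smoothed pi is zero use a floor of half the smallest
#' positive smoothed pi genome-wide, keeping the log finite while preserving
#' rank order. Outliers are windows in the lower tail -- diversity loss in
#' the focal population -- at `Z <= -z_cut`.
#'
#' @param sm_focal,sm_ref `smoothed_track`s of per-site pi for the focal and
#'   reference population, smoothed on identical centers.
#' @param z_cut Outlier threshold in standard deviations (default 5).
#' @return `data.frame`: `scaffold`, `pos`, `x` (log2 ratio), `z`,
#'   `outlier`, `direction` (`"focal_loss"`/`"focal_gain"`/`"none"`).
#' @export
pi_ratio_zscore <- function(sm_focal, sm_ref, z_cut = 5) {
  if (nrow(sm_focal) != nrow(sm_ref) ||
      !all(sm_focal$scaffold == sm_ref$scaffold) ||
      !all(sm_focal$pos == sm_ref$pos)) {
    stop("pi tracks must be smoothed on identical centers")
  }
  f <- sm_focal$smoothed
  r <- sm_ref$smoothed
  if (any(f < 0) || any(r < 0)) stop("negative smoothed pi")
  pos_min <- min(c(f[f > 0], r[r > 0]))
  eps <- pos_min / 2
  f[f == 0] <- eps
  r[r == 0] <- eps
  x <- log2(f / r)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate ratio track: constant log2 pi ratio")
  z <- (x - mean(x)) / s
  data.frame(scaffold = sm_focal$scaffold, pos = sm_focal$pos, x = x, z = z,
             outlier = z <= -z_cut,
             direction = ifelse(x < 0, "focal_loss",
                                ifelse(x > 0, "focal_gain", "none")),
             stringsAsFactors = FALSE)
}
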