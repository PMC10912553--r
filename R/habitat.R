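#' Spatially thin occurrences to a minimum spacing
#'
#' Greedy retention in input order: a record is kept iff it lies at least
#' `min_spacing` from every record already kept. The result is a maximal
#' subset under that order, and thinning an already-thinned set is a no-op.
#' A 1 km spacing keeps any single population from dominating the data.
#'
#' @param occ An `occurrence_set`.
#' @param min_spacing Minimum pairwise distance in metres (>= 0).
#' @return Thinned `occurrence_set` (a subset of the input rows).
#' @export
thin_occurrences <- function(occ, min_spacing = 1000) {
  if (min_spacing < 0) stop("min_spacing must be >= 0")
  if (nrow(occ) == 0L || min_spacing == 0) return(occ)
  keep <- logical(nrow(occ))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(occ))) {
    if (!length(kx) ||
        all((kx - occ$x[i])^2 + (ky - occ$y[i])^2 >= min_spacing^2)) {
      keep[i] <- TRUE
      kx <- c(kx, occ$x[i]); ky <- c(ky, occ$y[i])
    }
  }
  occ[keep, , drop = FALSE]
}

#' Thin occurrences, relaxing the spacing for sparse species
#'
#' Applies [thin_occurrences()] at `spacing`; if fewer than `min_n` records
#' survive, the spacing is halved and thinning retried until `min_n` records
#' remain or the spacing falls below one cell width. Species with limited
#' distributions keep a workable sample this way while widespread species are
#' still thinned at the full spacing.
#'
#' @param occ An `occurrence_set`.
#' @param spacing Starting minimum spacing in metres (default 1000).
#' @param min_n Minimum retained records before the spacing is relaxed
#'   (default 20).
#' @param floor_spacing Spacing below which no further relaxation happens
#'   (default 30, one cell).
#' @return Thinned `occurrence_set` with attribute `spacing` = the spacing
#'   actually used.
#' @export
adaptive_thin_occurrences <- function(occ, spacing = 1000, min_n = 20,
                                      floor_spacing = 30) {
  s <- spacing
  th <- thin_occurrences(occ, s)
  while (nrow(th) < min_n && s / 2 >= floor_spacing) {
    s <- s / 2
    th <- thin_occurrences(occ, s)
  }
  attr(th, "spacing") <- s
  th
}

#' Maximum sensitivity-plus-specificity (MSSS) threshold
#'
#' Scans the unique observed scores as candidate cutoffs and returns the one
#' maximizing sensitivity(t) + specificity(t), where sensitivity is the
#' fraction of presence scores >= t and specificity the fraction of
#' background scores < t. Ties go to the smallest candidate, which retains
#' the most habitat — the conservative choice for rare species. Equivalent to
#' maximizing the true skill statistic.
#'
#' @param presence_scores,background_scores Numeric vectors in \[0, 1\].
#' @return List of class `threshold_result`: `threshold`, `rule`,
#'   `sensitivity`, `specificity`.
#' @export
msss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("presence and background scores must be non-empty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(cand, function(t) mean(background_scores < t), 0)
  best <- which.max(sens + spec)  # first index = smallest candidate on ties
  structure(list(threshold = cand[best], rule = "MSSS",
                 sensitivity = sens[best], specificity = spec[best]),
            class = "threshold_result")
}

#' Presence-percentile training threshold
#'
#' The linear-interpolation quantile of the presence scores, e.g. the
#' 10th-percentile threshold used when MSSS is too restrictive.
#'
#' @param presence_scores Numeric vector in \[0, 1\].
#' @param percentile Percentile in \[0, 100\].
#' @return A `threshold_result` (sensitivity/specificity relative to the
#'   presence scores themselves; no background is involved).
#' @export
presence_percentile_threshold <- function(presence_scores, percentile = 10) {
  if (!length(presence_scores)) stop("presence scores must be non-empty")
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  t <- stats::quantile(presence_scores, percentile / 100, names = FALSE,
                       type = 7)
  structure(list(threshold = t, rule = "presence-percentile",
                 sensitivity = mean(presence_scores >= t),
                 specificity = NA_real_),
            class = "threshold_result")
}

#' Binarize continuous suitability into habitat / non-habitat
#'
#' @param suitability A `grid_raster`.
#' @param t Threshold; cells with suitability >= t become habitat (1).
#'   A `threshold_result` is also accepted.
#' @return Binary `grid_raster`; `NA` cells propagate.
#' @export
binarize <- function(suitability, t) {
  if (inherits(t, "threshold_result")) t <- t$threshold
  out <- suitability
  out$values <- (suitability$values >= t) + 0
  out
}

#' Continuous Boyce index
#'
#' Moving-window predicted-to-expected ratio curve: for each window over the
#' suitability range, F = (fraction of presences with scores inside) /
#' (fraction of landscape cells inside); the index is the Spearman rank
#' correlation of F against the window midpoints. Windows with zero expected
#' fraction are dropped, and runs of consecutive duplicated F values are
#' collapsed to one before correlating (the standard continuous-Boyce
#' treatment, without which flat stretches of the curve degrade a perfectly
#' calibrated model below 1).
#'
#' @param suitability A `grid_raster`.
#' @param presences An `occurrence_set`; each point is scored by the
#'   suitability of its containing cell.
#' @param n_windows Number of moving windows (default 101).
#' @param window_width Window width as a fraction of the suitability range
#'   (default 0.1).
#' @param rm_duplicate Collapse consecutive duplicate F values (default TRUE).
#' @return List of class `boyce_result`: `index`, `window_width` (score
#'   units), `midpoints`, `F`.
#' @export
boyce_index <- function(suitability, presences, n_windows = 101,
                        window_width = 0.1, rm_duplicate = TRUE) {
  v <- suitability$values[is.finite(suitability$values)]
  rc <- xy_cell(suitability, presences$x, presences$y)
  ok <- !is.na(rc[, 1])
  if (!any(ok)) stop("all presences fall outside the raster")
  ps <- suitability$values[rc[ok, , drop = FALSE]]
  ps <- ps[is.finite(ps)]
  lo <- min(v); hi <- max(v)
  w <- window_width * (hi - lo)
  if (w <= 0) stop("suitability surface is constant: Boyce undefined")
  mids <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  P <- vapply(mids, function(m) mean(ps >= m - w / 2 & ps <= m + w / 2), 0)
  E <- vapply(mids, function(m) mean(v >= m - w / 2 & v <= m + w / 2), 0)
  keep <- E > 0
  if (sum(keep) < 2) stop("fewer than 2 windows with nonzero expected fraction")
  f <- P[keep] / E[keep]
  m2 <- mids[keep]
  if (rm_duplicate) {
    first <- c(TRUE, diff(f) != 0)
    f <- f[first]; m2 <- m2[first]
  }
  b <- if (length(f) < 2) NA_real_ else
    suppressWarnings(stats::cor(f, m2, method = "spearman"))
  structure(list(index = b, window_width = w, midpoints = m2, F = f),
            class = "boyce_result")
}
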