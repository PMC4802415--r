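# Abundance-space stability scans (multi-dimensional dynamics analysis).

#' Random stability scan of abundance space
#'
#' Samples the five protein totals (Rac1, RhoA, PAK, GEF-H1, 14-3-3)
#' uniformly within a box and classifies the dynamics of every sampled set
#' via [dynamics_class()]. Sampling is uniform by default; a Latin
#' hypercube design is available behind a flag.
#'
#' @param ranges named list of `c(lo, hi)` ranges (nM) per sampled axis
#'   (defaults to 0-1000 nM on all five axes, the physiologically sensible
#'   range).
#' @param n number of sampled sets (>= 0).
#' @param kinetics kinetic constants used for every set.
#' @param seed RNG seed; identical inputs and seed give identical output.
#' @param base_abundances abundances supplying the fixed, non-sampled Rac
#'   GAP total (and defaults for any axis not in `ranges`).
#' @param u clamped inhibitor level at which sets are classified.
#' @param lhs use a Latin hypercube instead of uniform sampling.
#' @param n_starts multi-start budget per classification.
#' @return Data frame of class `rr_scan`: one row per set with the sampled
#'   totals, `label` and `sample` index; the seed and box are attached as
#'   attributes.
#' @export
scan_abundance_space <- function(ranges = NULL, n, kinetics, seed = 1,
                                 base_abundances = default_abundances(),
                                 u = 0, lhs = FALSE, n_starts = 8) {
  axes <- sampled_axes()
  if (is.null(ranges)) {
    ranges <- setNames(rep(list(c(0, 1000)), length(axes)), axes)
  }
  if (!all(names(ranges) %in% axes)) {
    stop("ranges may only cover the sampled axes: ",
         paste(axes, collapse = ", "))
  }
  for (a in names(ranges)) {
    r <- ranges[[a]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] < 0 || r[2] < r[1]) {
      stop("invalid range for axis '", a, "'")
    }
  }
  if (n < 0) stop("n must be >= 0")
  set.seed(seed)
  ax <- names(ranges)
  X <- if (n == 0) {
    matrix(numeric(0), 0, length(ax), dimnames = list(NULL, ax))
  } else if (lhs) {
    L <- lhs::randomLHS(n, length(ax))
    colnames(L) <- ax
    for (a in ax) L[, a] <- ranges[[a]][1] + L[, a] * diff(ranges[[a]])
    L
  } else {
    m <- vapply(ax, function(a) runif(n, ranges[[a]][1], ranges[[a]][2]),
                numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, ax))
  }
  labels <- character(n)
  for (i in seq_len(n)) {
    ab <- unclass(base_abundances)
    ab[ax] <- X[i, ax]
    nw <- build_network(structure(ab, class = "rr_abundances"),
                        kinetics, u = u)
    labels[i] <- dynamics_class(nw, n_starts = n_starts, seed = seed + i)
  }
  out <- as.data.frame(X)
  out$label <- labels
  out$sample <- seq_len(max(n, 0))
  attr(out, "ranges") <- ranges
  attr(out, "seed") <- seed
  class(out) <- c("rr_scan", class(out))
  out
}

#' Bistable-versus-monostable abundance contrasts
#'
#' For every sampled axis, reports the median abundance among bistable sets
#' minus the median among monostable sets (nM, signed) together with a
#' rank-based two-sample statistic (Wilcoxon/Mann-Whitney). Sets labelled
#' `other` are excluded and their count reported.
#'
#' @param classifications an `rr_scan` data frame.
#' @param min_n minimum class size required per label.
#' @return Data frame with one row per axis: `axis`, `median_bistable`,
#'   `median_monostable`, `contrast`, `sign`, `wilcox_W`, `p_value`;
#'   attribute `n_other` counts excluded sets.
#' @export
association_summary <- function(classifications, min_n = 30) {
  axes <- intersect(sampled_axes(), names(classifications))
  bi <- classifications$label == "bistable"
  mo <- classifications$label == "monostable"
  if (sum(bi) < min_n || sum(mo) < min_n) {
    stop("need >= ", min_n, " sets per class (got ", sum(bi), " bistable, ",
         sum(mo), " monostable); increase the scan size n")
  }
  rows <- lapply(axes, function(a) {
    xb <- classifications[[a]][bi]
    xm <- classifications[[a]][mo]
    wt <- suppressWarnings(wilcox.test(xb, xm))
    mb <- median(xb); mm <- median(xm)
    data.frame(axis = a, median_bistable = mb, median_monostable = mm,
               contrast = mb - mm, sign = sign(mb - mm),
               wilcox_W = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_other") <- sum(classifications$label == "other")
  out
}

#' Normalized parallel-coordinates table
#'
#' Min-max normalizes every sampled axis to \[0, 1\] over the sampling box
#' (not over the realized sample), preserving row order; this is the table
#' behind parallel-coordinate plots of bistable versus monostable sets.
#'
#' @param classifications an `rr_scan` data frame (its sampling box is
#'   taken from the `ranges` attribute).
#' @param ranges optional explicit box overriding the attribute.
#' @return Data frame with the normalized axes plus the `label` column;
#'   the box is attached as attribute `ranges` (used by
#'   [denormalize_coords()]).
#' @export
parallel_coords_table <- function(classifications, ranges = NULL) {
  if (nrow(classifications) == 0) stop("empty classification table")
  if (is.null(ranges)) ranges <- attr(classifications, "ranges")
  if (is.null(ranges)) stop("no sampling box available")
  axes <- intersect(names(ranges), names(classifications))
  out <- classifications[, c(axes, "label"), drop = FALSE]
  for (a in axes) {
    r <- ranges[[a]]
    if (diff(r) <= 0) stop("degenerate axis '", a, "' (lo = hi)")
    out[[a]] <- (classifications[[a]] - r[1]) / diff(r)
  }
  attr(out, "ranges") <- ranges
  rownames(out) <- NULL
  out
}

#' Invert the parallel-coordinates normalization
#'
#' @param normalized output of [parallel_coords_table()].
#' @param ranges optional explicit box.
#' @return Data frame on the original nM scale.
#' @export
denormalize_coords <- function(normalized, ranges = NULL) {
  if (is.null(ranges)) ranges <- attr(normalized, "ranges")
  out <- normalized
  for (a in intersect(names(ranges), names(normalized))) {
    r <- ranges[[a]]
    out[[a]] <- normalized[[a]] * diff(r) + r[1]
  }
  out
}
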