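# One- and two-parameter bifurcation analysis.

.settable_params <- function() {
  c(abundance_names(), "u", kinetics_names())
}

# return a copy of the network with one parameter replaced
set_param <- function(network, param_name, value) {
  if (!param_name %in% .settable_params()) {
    stop("unknown parameter '", param_name, "'")
  }
  if (!is.finite(value) || value < 0) {
    stop("parameter '", param_name, "' must be finite and >= 0")
  }
  if (param_name == "u") {
    network$u <- value
  } else if (param_name %in% abundance_names()) {
    ab <- unclass(network$abundances)
    ab[[param_name]] <- value
    network$abundances <- structure(ab, class = "rr_abundances")
  } else {
    kin <- unclass(network$kinetics)
    kin[[param_name]] <- value
    network$kinetics <- as_kinetics(kin)
  }
  network
}

#' One-parameter steady-state sweep with state carry-over
#'
#' Sweeps a parameter along a grid, relaxing the system to steady state at
#' each point and using that state as the initial condition for the next
#' point (continuation by state carry-over). This history dependence is what
#' exposes hysteresis: forward and backward traverses follow different
#' stable branches between the switching thresholds.
#'
#' @param network an `rr_network`.
#' @param param_name parameter to sweep: any abundance field, `"u"`, or any
#'   kinetic constant.
#' @param grid monotone increasing numeric grid of parameter values.
#' @param direction `"forward"` (ascending) or `"backward"` (descending).
#' @param state0 optional initial state at the first traversed grid point;
#'   default is the relaxed state from the all-inactive corner.
#' @param readouts species reported per grid point.
#' @param t_max maximum relaxation time per grid point (min).
#' @return Data frame with the parameter column, one column per readout and
#'   a logical `converged` column; rows in traversal order. Non-convergent
#'   points are recorded as `NA` and the sweep continues.
#' @export
sweep1d <- function(network, param_name, grid,
                    direction = c("forward", "backward"), state0 = NULL,
                    readouts = c("RhoA_GTP", "Rac1_GTP"), t_max = 2e4) {
  direction <- match.arg(direction)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  ord <- if (direction == "forward") seq_along(grid) else rev(seq_along(grid))
  nw <- set_param(network, param_name, grid[ord[1]])
  state <- if (is.null(state0)) {
    .relax(nw, state_inactive(nw), t_max = t_max)$state
  } else {
    validate_state(state0)
  }
  out <- matrix(NA_real_, length(grid), length(readouts),
                dimnames = list(NULL, readouts))
  converged <- logical(length(grid))
  for (k in ord) {
    nw <- set_param(network, param_name, grid[k])
    state <- project_state(state, nw)
    rl <- .relax(nw, state, t_max = t_max)
    pol <- .polish(rl$state, nw)
    if (!is.null(pol)) {
      state <- pol
      out[k, ] <- state[readouts]
      converged[k] <- TRUE
    } else if (rl$converged) {
      state <- rl$state
      out[k, ] <- state[readouts]
      converged[k] <- TRUE
    } else {
      state <- rl$state  # carry the last iterate, record missing
    }
  }
  df <- data.frame(param = grid, out, converged = converged)
  names(df)[1] <- param_name
  attr(df, "direction") <- direction
  df
}

# detect a single jump in a branch: intervals whose step exceeds 5x the
# median inter-point step (with a floor of 5% of the branch range, so flat
# branches with numerically tiny steps are not flagged). Contiguous
# flagged intervals are one jump; two separate clusters are an error.
.detect_jump <- function(grid, values) {
  ok <- is.finite(values)
  d <- diff(values)
  ad <- abs(d)
  rng <- diff(range(values[ok]))
  if (rng <= 0) return(NULL)
  thr <- max(5 * median(ad, na.rm = TRUE), 0.05 * rng)
  cand <- which(ad > thr)
  if (length(cand) == 0) return(NULL)
  clusters <- split(cand, cumsum(c(1, diff(cand) != 1)))
  if (length(clusters) > 1) {
    stop("multiple jumps detected in one sweep direction: ",
         "grid too coarse or dynamics class 'other'")
  }
  idx <- cand[which.max(ad[cand])]
  list(location = (grid[idx] + grid[idx + 1]) / 2,
       interval = c(grid[idx], grid[idx + 1]),
       size = d[idx])
}

#' Hysteresis analysis of a one-parameter sweep
#'
#' Runs [sweep1d()] in both directions and detects the up-switch threshold
#' T1 (forward traverse) and down-switch threshold T2 (backward traverse)
#' as the midpoints of the grid intervals where the readout jumps by more
#' than five times the median inter-point step. The system is flagged
#' bistable when jumps are detected in both directions at distinct
#' locations; hysteresis then implies T2 < T1.
#'
#' @inheritParams sweep1d
#' @param readouts species tracked; thresholds are detected on the first
#'   readout and jump locations of the others are reported alongside.
#' @return Object of class `rr_hysteresis`: list with `param_name`, `grid`,
#'   `forward` and `backward` branch data frames, `T1`, `T2` (NA when not
#'   bistable), `bistable`, and per-readout jump details.
#' @export
#' @examples
#' \donttest{
#' nw <- build_network(default_abundances(), default_kinetics(), u = 0)
#' h <- hysteresis(nw, "u", seq(0, 1500, length.out = 40))
#' c(h$T2, h$T1, h$bistable)
#' }
hysteresis <- function(network, param_name, grid,
                       readouts = c("RhoA_GTP", "Rac1_GTP"), t_max = 2e4) {
  if (length(grid) < 20) stop("hysteresis grid must have >= 20 points")
  fw <- sweep1d(network, param_name, grid, "forward", readouts = readouts,
                t_max = t_max)
  # the backward traverse starts from the state relaxed at the top grid
  # point (the all-inactive corner relaxes onto the high branch there)
  bw <- sweep1d(network, param_name, grid, "backward", readouts = readouts,
                t_max = t_max)
  jumps <- list()
  for (r in readouts) {
    jumps[[r]] <- list(forward = .detect_jump(grid, fw[[r]]),
                       backward = .detect_jump(grid, bw[[r]]))
  }
  jf <- jumps[[readouts[1]]]$forward
  jb <- jumps[[readouts[1]]]$backward
  step <- median(diff(grid))
  bistable <- !is.null(jf) && !is.null(jb) &&
    abs(jf$location - jb$location) > step / 2
  T1 <- if (bistable) jf$location else NA_real_
  T2 <- if (bistable) jb$location else NA_real_
  if (bistable && T2 >= T1) {
    warning("backward threshold not below forward threshold; ",
            "flagging as not bistable")
    bistable <- FALSE; T1 <- NA_real_; T2 <- NA_real_
  }
  structure(list(param_name = param_name, grid = grid, forward = fw,
                 backward = bw, T1 = T1, T2 = T2, bistable = bistable,
                 jumps = jumps),
            class = "rr_hysteresis")
}

#' @export
print.rr_hysteresis <- function(x, ...) {
  cat("Hysteresis sweep over '", x$param_name, "' (", length(x$grid),
      " points)\n", sep = "")
  if (x$bistable) {
    cat(sprintf("  bistable: T1 (up-switch) = %.4g, T2 (down-switch) = %.4g\n",
                x$T1, x$T2))
  } else {
    cat("  not bistable (branches coincide)\n")
  }
  invisible(x)
}

#' Tidy branch table of a hysteresis result
#'
#' @param x an `rr_hysteresis`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Data frame with one row per grid point, branch and readout.
#' @export
as.data.frame.rr_hysteresis <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  readouts <- setdiff(names(x$forward), c(x$param_name, "converged"))
  rows <- list()
  for (br in c("forward", "backward")) {
    b <- x[[br]]
    for (r in readouts) {
      rows[[paste(br, r)]] <- data.frame(
        param_name = x$param_name, param_value = b[[x$param_name]],
        branch = br, readout = r, value = b[[r]],
        converged = b$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Refine the bistable parameter range by bisection on stable-state count
#'
#' Independent of the sweep-based thresholds, finds the parameter interval
#' over which the network has two stable steady states, by bisecting on the
#' stable-state count from [find_steady_states()]. Used to cross-check the
#' sweep thresholds T1/T2.
#'
#' @param network an `rr_network`.
#' @param param_name parameter name.
#' @param lo,hi search interval; `lo` must be outside the bistable range on
#'   the low side and `hi` outside on the high side (or at most equal).
#' @param rtol relative parameter resolution of the bisection.
#' @param n_starts,seed forwarded to [find_steady_states()].
#' @return Numeric vector `c(lower, upper)` of the bistable interval, or
#'   `NULL` if no bistable point is found on the scan grid.
#' @export
bistable_range <- function(network, param_name, lo, hi, rtol = 1e-3,
                           n_starts = 8, seed = 1) {
  n_stable <- function(v) {
    nw <- set_param(network, param_name, v)
    ss <- find_steady_states(nw, n_starts = n_starts, seed = seed,
                             t_max = 2e4)
    sum(vapply(ss, function(s) s$stability == "stable", logical(1)))
  }
  probe <- seq(lo, hi, length.out = 17)
  counts <- vapply(probe, n_stable, numeric(1))
  inside <- which(counts >= 2)
  if (length(inside) == 0) return(NULL)
  span <- max(hi - lo, 1e-12)
  bisect <- function(a, b, want_inside_right) {
    # invariant: exactly one boundary crossing between a and b
    while ((b - a) / span > rtol) {
      m <- (a + b) / 2
      if ((n_stable(m) >= 2) == want_inside_right) b <- m else a <- m
    }
    (a + b) / 2
  }
  i1 <- inside[1]; i2 <- inside[length(inside)]
  lower <- if (i1 == 1) lo else bisect(probe[i1 - 1], probe[i1], TRUE)
  upper <- if (i2 == length(probe)) hi else bisect(probe[i2], probe[i2 + 1], FALSE)
  c(lower = lower, upper = upper)
}

#' Two-parameter bistability region map
#'
#' Evaluates [dynamics_class()] on every cell of a 2D parameter grid (cells
#' are independent; the result does not depend on evaluation order).
#'
#' @param network an `rr_network`.
#' @param param_x,param_y parameter names (abundances, `"u"`, or kinetic
#'   constants).
#' @param grid_x,grid_y monotone numeric grids.
#' @param n_starts,seed forwarded to [dynamics_class()].
#' @return Object of class `rr_regionmap`: list with the grids and a
#'   character label matrix (`length(grid_x)` x `length(grid_y)`).
#' @export
region2d <- function(network, param_x, param_y, grid_x, grid_y,
                     n_starts = 8, seed = 1) {
  if (is.unsorted(grid_x, strictly = TRUE) ||
      is.unsorted(grid_y, strictly = TRUE)) {
    stop("grids must be strictly increasing")
  }
  labels <- matrix(NA_character_, length(grid_x), length(grid_y))
  for (i in seq_along(grid_x)) {
    nwx <- set_param(network, param_x, grid_x[i])
    for (j in seq_along(grid_y)) {
      nw <- set_param(nwx, param_y, grid_y[j])
      labels[i, j] <- dynamics_class(nw, n_starts = n_starts, seed = seed)
    }
  }
  structure(list(param_x = param_x, param_y = param_y,
                 grid_x = grid_x, grid_y = grid_y, labels = labels),
            class = "rr_regionmap")
}

#' @export
print.rr_regionmap <- function(x, ...) {
  cat("2D region map:", x$param_x, "x", x$param_y, "\n")
  print(table(factor(x$labels, c("monostable", "bistable", "other"))))
  invisible(x)
}

#' Tidy table of a region map
#'
#' @param x an `rr_regionmap`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Data frame with one row per grid cell.
#' @export
as.data.frame.rr_regionmap <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  out <- expand.grid(x = x$grid_x, y = x$grid_y, KEEP.OUT.ATTRS = FALSE)
  names(out) <- c(x$param_x, x$param_y)
  out$label <- as.vector(x$labels)
  out
}

#' Calibrate kinetic constants to the bistable regime
#'
#' Random search over a box of admissible kinetic ranges until a parameter
#' set whose inhibitor dose response is bistable (hysteresis with distinct
#' up- and down-switch thresholds) is found. The geometric midpoint of the
#' box is tried first, then log-uniform samples; the first qualifying set
#' is returned, so the result is deterministic under a fixed seed.
#'
#' @param kinetics_box list with numeric vectors `lo` and `hi` (named over
#'   [kinetics_names()]) bounding each constant; `lo` must be > 0 except
#'   where `hi` is also 0.
#' @param abundances abundance vector at which bistability is required.
#' @param u_grid inhibitor grid (>= 20 points) for the hysteresis check.
#' @param seed RNG seed.
#' @param max_iter maximum number of candidates (including the midpoint).
#' @return The first qualifying `rr_kinetics`, with the qualifying
#'   hysteresis result attached as attribute `"hysteresis"`.
#' @export
calibrate_bistable_defaults <- function(kinetics_box, abundances, u_grid,
                                        seed = 1, max_iter = 50) {
  lo <- kinetics_box$lo[kinetics_names()]
  hi <- kinetics_box$hi[kinetics_names()]
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo < 0) ||
      any(hi < lo)) {
    stop("kinetics_box must provide finite 0 <= lo <= hi for every constant")
  }
  set.seed(seed)
  try_candidate <- function(k) {
    kin <- try(kinetics(setNames(k, kinetics_names())), silent = TRUE)
    if (inherits(kin, "try-error")) return(NULL)
    nw <- build_network(abundances, kin, u = 0)
    h <- try(hysteresis(nw, "u", u_grid), silent = TRUE)
    if (inherits(h, "try-error") || !isTRUE(h$bistable)) return(NULL)
    attr(kin, "hysteresis") <- h
    kin
  }
  # geometric midpoint first (arithmetic where a bound is zero)
  mid <- ifelse(lo > 0, sqrt(lo * hi), (lo + hi) / 2)
  res <- try_candidate(mid)
  if (!is.null(res)) return(res)
  for (it in seq_len(max_iter - 1)) {
    r <- runif(length(lo))
    k <- ifelse(lo > 0, lo * (hi / lo)^r, lo + r * (hi - lo))
    res <- try_candidate(k)
    if (!is.null(res)) return(res)
  }
  stop("no bistable kinetics found in ", max_iter,
       " candidates; widen the kinetics box")
}
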