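# Stochastic phase portraits: fixed points of the convective field alpha with
# classification, nullclines, convective trajectories, limit cycles, and
# boundary maxima.

# Accept either a field_model (uses alpha) or a plain callable x -> vector.
as_field_fun <- function(field, N = NULL) {
  if (inherits(field, "field_model")) {
    NN <- if (is.null(N)) field$network$system_size else N
    return(function(x) convective_field(field, x, NN))
  }
  stopifnot(is.function(field))
  field
}

field_jac_fun <- function(field, N = NULL) {
  if (inherits(field, "field_model") && field$derivative_policy == "symbolic") {
    J_exprs <- field_jacobian_exprs(field, "alpha")
    NN <- if (is.null(N)) field$network$system_size else N
    k <- length(field$network$species)
    return(function(x) {
      env <- field_env(field, x, NN)
      J <- matrix(0, k, k)
      for (i in seq_len(k)) for (l in seq_len(k)) J[i, l] <- eval(J_exprs[[i, l]], env)
      if (any(!is.finite(J))) stop("non-finite Jacobian entries at x = ",
                                   paste(signif(x, 6), collapse = ", "))
      J
    })
  }
  fn <- as_field_fun(field, N)
  function(x) jacobian_fd(fn, x)
}

jacobian_fd <- function(fn, x) {
  k <- length(x)
  J <- matrix(0, k, k)
  h <- (.Machine$double.eps)^(1/3) * (1 + abs(x))
  for (l in seq_len(k)) {
    xp <- x; xm <- x
    xp[l] <- x[l] + h[l]; xm[l] <- x[l] - h[l]
    J[, l] <- (fn(xp) - fn(xm)) / (xp[l] - xm[l])
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries at x = ",
                               paste(signif(x, 6), collapse = ", "))
  J
}

#' Jacobian of a field by the active derivative policy
#'
#' For a symbolic [field_model()], entries `dalpha_i/dx_k` are exact
#' derivatives of the convective-field expressions; otherwise central finite
#' differences are used. Applied to the drift instead (`which = "f"`), this is
#' the deterministic Jacobian.
#'
#' @param field a [field_model()] or a function `x -> vector`.
#' @param x point of evaluation.
#' @param N system size override (field models only).
#' @param which `"alpha"` (stochastic Jacobian, default) or `"f"`
#'   (deterministic Jacobian; field models only).
#' @return k x k Jacobian matrix.
#' @export
jacobian <- function(field, x, N = NULL, which = c("alpha", "f")) {
  which <- match.arg(which)
  if (which == "f") {
    stopifnot(inherits(field, "field_model"))
    if (field$derivative_policy == "symbolic") {
      J_exprs <- field_jacobian_exprs(field, "f")
      NN <- if (is.null(N)) field$network$system_size else N
      k <- length(field$network$species)
      env <- field_env(field, x, NN)
      J <- matrix(0, k, k)
      for (i in seq_len(k)) for (l in seq_len(k)) J[i, l] <- eval(J_exprs[[i, l]], env)
      return(J)
    }
    return(jacobian_fd(function(xx) drift(field, xx, if (is.null(N)) field$network$system_size else N), x))
  }
  field_jac_fun(field, N)(x)
}

#' Classify a fixed point from the eigenvalues of its Jacobian
#'
#' Stable fixed points of the convective field are favorable-state candidates
#' (density maxima), unstable ones unfavorable (minima); any eigenvalue with
#' `|Re| < zero_tol` yields the `"marginal/manifold"` class, which is what
#' conservation-law models produce along their fixed-point lines.
#'
#' @param eigenvalues complex vector.
#' @param zero_tol absolute tolerance on real parts; default
#'   `1e-8 * max(|lambda|)`.
#' @return One of `"stable-node"`, `"stable-spiral"`, `"unstable-node"`,
#'   `"unstable-spiral"`, `"saddle"`, `"marginal/manifold"`.
#' @export
classify_eigenvalues <- function(eigenvalues, zero_tol = NULL) {
  ev <- as.complex(eigenvalues)
  scale <- max(Mod(ev), 0)
  if (is.null(zero_tol)) zero_tol <- 1e-8 * max(scale, .Machine$double.eps)
  re <- Re(ev)
  if (any(abs(re) < zero_tol)) return("marginal/manifold")
  spiral <- any(abs(Im(ev)) > zero_tol)
  if (all(re < 0)) return(if (spiral) "stable-spiral" else "stable-node")
  if (all(re > 0)) return(if (spiral) "unstable-spiral" else "unstable-node")
  "saddle"
}

fixed_point_record <- function(field, x, N = NULL, root_tol = 1e-9,
                               zero_tol = NULL) {
  fn <- as_field_fun(field, N)
  a <- fn(x)
  J <- field_jac_fun(field, N)(x)
  ev <- eigen(J, only.values = TRUE)$values
  cls <- classify_eigenvalues(ev, zero_tol)
  tol_used <- if (is.null(zero_tol)) 1e-8 * max(Mod(ev), .Machine$double.eps) else zero_tol
  structure(
    list(location = x, residual = sqrt(sum(a^2)), jacobian = J,
         eigenvalues = ev, classification = cls,
         favorable_candidate = all(Re(ev) < -tol_used)),
    class = "fixed_point_record")
}

#' @export
print.fixed_point_record <- function(x, ...) {
  cat(sprintf("Fixed point at (%s): %s%s, residual %.2e\n",
              paste(signif(x$location, 6), collapse = ", "),
              x$classification,
              if (x$favorable_candidate) " [favorable candidate]" else "",
              x$residual))
  invisible(x)
}

project_to_box <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Find fixed points of a field in a box
#'
#' Damped (backtracking) Newton iteration from a deterministic multistart
#' (regular grid plus seeded jitter); singular Jacobians are handled with an
#' SVD pseudo-inverse so that fixed-point *lines* (conservation-law models)
#' still converge, and are then flagged `"marginal/manifold"` by the
#' classifier. Duplicates closer than `1e-6 *` the domain diagonal are merged.
#'
#' @param field a [field_model()] or function `x -> vector`.
#' @param domain list of per-coordinate ranges `list(c(lo, hi), ...)`.
#' @param n_starts number of multistart points (>= 1).
#' @param seed integer seed for the start-point jitter (results are
#'   deterministic given the seed, and the converged root set is insensitive
#'   to it).
#' @param root_tol residual tolerance `||alpha|| < root_tol` for acceptance.
#' @param N system size override (field models only).
#' @param zero_tol marginal-eigenvalue tolerance passed to the classifier.
#' @return List of fixed-point records (possibly empty, with a warning if no
#'   start converged).
#' @export
find_fixed_points <- function(field, domain, n_starts = 64, seed = 1,
                              root_tol = 1e-9, N = NULL, zero_tol = NULL) {
  stopifnot(n_starts >= 1)
  fn <- as_field_fun(field, N)
  jac <- field_jac_fun(field, N)
  k <- length(domain)
  lo <- vapply(domain, `[`, 0, 1)
  hi <- vapply(domain, `[`, 0, 2)
  diag_len <- sqrt(sum((hi - lo)^2))
  per_axis <- max(2L, ceiling(n_starts^(1 / k)))
  axes <- lapply(seq_len(k), function(i)
    seq(lo[i], hi[i], length.out = per_axis + 2)[-c(1, per_axis + 2)])
  starts <- as.matrix(expand.grid(axes))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  jit <- matrix(stats::runif(length(starts), -0.5, 0.5), nrow(starts), k) *
    rep((hi - lo) / (per_axis + 1), each = nrow(starts))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  starts <- sweep(starts + jit, 2, lo, pmax)
  starts <- sweep(starts, 2, hi, pmin)
  roots <- list()
  for (s in seq_len(nrow(starts))) {
    x <- unname(starts[s, ])
    ok <- FALSE
    for (it in 1:60) {
      a <- fn(x)
      na <- sqrt(sum(a^2))
      if (!is.finite(na)) break
      if (na < root_tol) { ok <- TRUE; break }
      J <- jac(x)
      step <- tryCatch(-solve(J, a), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        sv <- svd(J)
        d <- sv$d
        inv <- ifelse(d > 1e-12 * max(d, 1), 1 / d, 0)
        step <- -drop(sv$v %*% (inv * (t(sv$u) %*% a)))
      }
      lam <- 1
      improved <- FALSE
      for (bt in 1:30) {
        xn <- project_to_box(x + lam * step, lo, hi)
        an <- fn(xn)
        if (all(is.finite(an)) && sqrt(sum(an^2)) < na) {
          x <- xn; improved <- TRUE; break
        }
        lam <- lam / 2
      }
      if (!improved) break
    }
    if (!ok) {
      a <- fn(x)
      if (sqrt(sum(a^2)) < root_tol) ok <- TRUE
    }
    if (ok) {
      dup <- FALSE
      for (r in roots)
        if (sqrt(sum((r - x)^2)) < 1e-6 * diag_len) { dup <- TRUE; break }
      if (!dup) roots[[length(roots) + 1L]] <- x
    }
  }
  if (length(roots) == 0L) {
    warning("no fixed point converged from any of the ", nrow(starts), " starts")
    return(list())
  }
  lapply(roots, function(x)
    fixed_point_record(field, x, N = N, root_tol = root_tol, zero_tol = zero_tol))
}

#' Nullclines of a 2D field
#'
#' Zero-level contours of each field component, extracted by marching squares
#' on a regular sample grid.
#'
#' @inheritParams find_fixed_points
#' @param resolution grid points per axis (>= 16).
#' @return List with one element per component; each a list of polyline
#'   data.frames (columns `x`, `y`). A component that never changes sign
#'   yields an empty list.
#' @export
nullclines <- function(field, domain, resolution = 256, N = NULL) {
  stopifnot(length(domain) == 2, resolution >= 16)
  fn <- as_field_fun(field, N)
  gx <- seq(domain[[1]][1], domain[[1]][2], length.out = resolution)
  gy <- seq(domain[[2]][1], domain[[2]][2], length.out = resolution)
  pts <- as.matrix(expand.grid(gx, gy))
  vals <- if (inherits(field, "field_model")) {
    convective_field(field, pts, if (is.null(N)) field$network$system_size else N)
  } else {
    t(apply(pts, 1, fn))
  }
  out <- vector("list", 2)
  for (comp in 1:2) {
    z <- matrix(vals[, comp], nrow = resolution) # rows follow gx (first grid factor)
    # contourLines misplaces segments when the level coincides exactly with
    # grid values; a relative level shift of 1e-9 avoids the degeneracy while
    # moving the polyline by O(1e-9 / |grad|)
    if (max(z) == min(z)) { out[[comp]] <- list(); next }
    eps <- 1e-9 * max(abs(z), 1)
    cl <- grDevices::contourLines(gx, gy, z, levels = eps)
    out[[comp]] <- lapply(cl, function(li) data.frame(x = li$x, y = li$y))
  }
  names(out) <- c("component1", "component2")
  out
}

#' Integrate a trajectory of dx/dt = alpha(x)
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 5(4)) integration of the
#' convective dynamical system, clipped to the non-negative orthant: on a
#' boundary face with outward-pointing field the flow is projected onto the
#' face, which reproduces the sliding of probability flow along an axis
#' toward a boundary maximum.
#'
#' @inheritParams find_fixed_points
#' @param x0 starting point (non-negative).
#' @param t_max integration horizon.
#' @param record_dt minimum spacing of recorded points (0 = every accepted
#'   step; when positive it also caps the step size, so the recorded path is
#'   dense enough for recurrence analysis).
#' @param rtol,atol step-control tolerances.
#' @param clip clip the flow to the non-negative orthant (default TRUE; turn
#'   off for toy fields not living on concentration space).
#' @return An object of class `"spp_trajectory"`: `t`, `x` (matrix), flag
#'   `truncated` (step-size collapse or step budget), and the field for later
#'   use by [detect_limit_cycle()].
#' @export
integrate_trajectory <- function(field, x0, t_max, N = NULL, record_dt = 0,
                                 rtol = 1e-7, atol = 1e-9, clip = TRUE) {
  fn <- as_field_fun(field, N)
  rhs <- if (clip) function(x) {
    x <- pmax(x, 0)
    v <- fn(x)
    at0 <- x <= 0 & v < 0
    v[at0] <- 0
    v
  } else fn
  sol <- rk45(rhs, if (clip) pmax(x0, 0) else x0, t_max, rtol = rtol,
              atol = atol, record_dt = record_dt,
              max_step = if (record_dt > 0) record_dt else Inf)
  if (clip) sol$x <- pmax(sol$x, 0)
  structure(list(t = sol$t, x = sol$x, truncated = sol$truncated,
                 field = field, N = N),
            class = "spp_trajectory")
}

#' Detect a limit cycle in an integrated trajectory
#'
#' Poincare-style nearest-return analysis of the second half of the path
#' (the first half is discarded as transient). If the path returns to within
#' `cycle_tol` of its end point after a nontrivial excursion, one period is
#' extracted along with the speed profile `||alpha||`: speed minima mark
#' slow-transient-state candidates (local maxima of the stationary density on
#' the probability ridge), speed maxima mark saddle-like throughput points.
#'
#' @param traj an [integrate_trajectory()] result.
#' @param cycle_tol recurrence distance; default `1e-3 *` the diameter of the
#'   analysed path segment.
#' @return `NULL` if no cycle is found; otherwise a list with `points` (closed
#'   polyline), `t`, `period`, and `speed`.
#' @export
detect_limit_cycle <- function(traj, cycle_tol = NULL) {
  stopifnot(inherits(traj, "spp_trajectory"))
  n <- nrow(traj$x)
  if (n < 32) return(NULL)
  i0 <- floor(n / 2)
  Z <- traj$x[i0:n, , drop = FALSE]
  tt <- traj$t[i0:n]
  m <- nrow(Z)
  ranges <- apply(Z, 2, range)
  diam <- sqrt(sum((ranges[2, ] - ranges[1, ])^2))
  if (is.null(cycle_tol)) cycle_tol <- 1e-3 * max(diam, .Machine$double.eps)
  if (diam < 10 * cycle_tol) return(NULL) # converged/stationary path
  ref <- Z[m, ]
  # nearest return: distance from the end point to every earlier path
  # *segment* (point spacing can exceed cycle_tol), excluding the tail
  # adjacent to the reference point itself
  span <- tt[m] - tt[1]
  last_seg <- max(which(tt < tt[m] - 0.01 * span))
  if (!is.finite(last_seg) || last_seg < 2) return(NULL)
  A <- Z[1:(last_seg - 1), , drop = FALSE]
  B <- Z[2:last_seg, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  tpar <- rowSums(sweep(A, 2, ref, function(a, r) (r - a)) * AB) /
    pmax(len2, .Machine$double.xmin)
  tpar <- pmin(pmax(tpar, 0), 1)
  P <- A + AB * tpar
  d <- sqrt(rowSums(sweep(P, 2, ref)^2))
  cand <- which(d < cycle_tol)
  if (length(cand) == 0L) return(NULL)
  istart <- cand[length(cand)] + 1L # most recent return => one period
  cyc <- Z[istart:m, , drop = FALSE]
  cranges <- apply(cyc, 2, range)
  if (sqrt(sum((cranges[2, ] - cranges[1, ])^2)) < 10 * cycle_tol) return(NULL)
  fn <- as_field_fun(traj$field, traj$N)
  speed <- apply(cyc, 1, function(x) sqrt(sum(fn(x)^2)))
  list(points = cyc, t = tt[istart:m], period = tt[m] - tt[istart],
       speed = speed)
}

#' Boundary maxima candidates of a 2D field
#'
#' For each axis of the non-negative quadrant, finds the roots of the field
#' component *parallel* to that axis restricted to the axis (the intersection
#' points of a nullcline with its own axis). Each root is flagged
#' `inflow = TRUE` when the perpendicular component points *into* the
#' boundary there, which is the condition for a boundary maximum of the
#' stationary density to form.
#'
#' @inheritParams find_fixed_points
#' @param scan_n number of scan points per axis used to bracket roots.
#' @return data.frame with columns `axis` (1 = x-axis, 2 = y-axis),
#'   `location_x`, `location_y`, `inflow`, `perp_component`.
#' @export
boundary_maxima <- function(field, domain, N = NULL, scan_n = 512) {
  stopifnot(length(domain) == 2)
  fn <- as_field_fun(field, N)
  res <- list()
  for (axis in 1:2) {
    perp <- 3L - axis
    rng <- domain[[axis]]
    par_comp <- function(s) {
      x <- numeric(2); x[axis] <- s
      fn(x)[axis]
    }
    ss <- seq(max(rng[1], 0), rng[2], length.out = scan_n)
    vals <- vapply(ss, par_comp, 0)
    sgn <- sign(vals)
    idx <- which(sgn[-1] * sgn[-scan_n] < 0)
    for (i in idx) {
      root <- stats::uniroot(par_comp, lower = ss[i], upper = ss[i + 1],
                             tol = 1e-12)$root
      x <- numeric(2); x[axis] <- root
      perp_val <- fn(x)[perp]
      res[[length(res) + 1L]] <- data.frame(
        axis = axis, location_x = x[1], location_y = x[2],
        inflow = perp_val < 0, perp_component = perp_val)
    }
  }
  if (length(res) == 0L)
    return(data.frame(axis = integer(0), location_x = numeric(0),
                      location_y = numeric(0), inflow = logical(0),
                      perp_component = numeric(0)))
  do.call(rbind, res)
}

#' Assemble a stochastic phase portrait
#'
#' Convenience umbrella: samples the convective field on a grid, extracts
#' nullclines, locates and classifies fixed points, finds boundary maxima
#' candidates, and optionally integrates trajectories from given starts.
#'
#' @inheritParams find_fixed_points
#' @param grid_resolution resolution of the exported vector grid.
#' @param nullcline_resolution marching-squares resolution.
#' @param trajectories optional list of start points.
#' @param t_max horizon for trajectories.
#' @return An object of class `"spp_portrait"`.
#' @export
phase_portrait <- function(field, domain, N = NULL, n_starts = 64, seed = 1,
                           grid_resolution = 25, nullcline_resolution = 256,
                           trajectories = list(), t_max = 200) {
  stopifnot(length(domain) == 2)
  grid <- if (inherits(field, "field_model"))
    field_grid(field, domain, grid_resolution,
               if (is.null(N)) field$network$system_size else N) else NULL
  structure(
    list(grid = grid,
         nullclines = nullclines(field, domain, nullcline_resolution, N),
         fixed_points = suppressWarnings(
           find_fixed_points(field, domain, n_starts = n_starts, seed = seed, N = N)),
         boundary_maxima = boundary_maxima(field, domain, N),
         trajectories = lapply(trajectories, function(x0)
           integrate_trajectory(field, x0, t_max, N = N)),
         domain = domain),
    class = "spp_portrait")
}

#' @export
print.spp_portrait <- function(x, ...) {
  cat("Stochastic phase portrait\n")
  cat(" ", length(x$fixed_points), "fixed point(s):\n")
  for (fp in x$fixed_points) { cat("   "); print(fp) }
  bm <- x$boundary_maxima
  if (nrow(bm)) {
    for (i in seq_len(nrow(bm)))
      cat(sprintf("  boundary point (%.4g, %.4g) on axis %d: inflow = %s\n",
                  bm$location_x[i], bm$location_y[i], bm$axis[i], bm$inflow[i]))
  } else cat("  no boundary nullcline roots\n")
  invisible(x)
}
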