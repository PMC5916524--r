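# Stochastic bifurcation detection under parameter / system-size variation:
# eigenvalue crossings of the stochastic Jacobian, the nullcline-gap
# bifurcation (reversal of the convective flow through the gap between
# nullclines at a boundary), and nullcline detachment (loss of the interior
# fixed point).

# Largest real part among eigenvalues of J_s at a point, excluding
# structurally zero modes (|Re| below zero_tol), as used for stability
# tracking of a fixed point under a parameter sweep.
leading_eigenvalue <- function(field, x, N = NULL, zero_tol = NULL) {
  J <- jacobian(field, x, N = N)
  ev <- eigen(J, only.values = TRUE)$values
  scale <- max(Mod(ev), .Machine$double.eps)
  if (is.null(zero_tol)) zero_tol <- 1e-8 * scale
  re <- Re(ev)
  keep <- abs(re) >= zero_tol
  if (!any(keep)) return(0)
  max(re[keep])
}

#' Locate an eigenvalue crossing of a tracked fixed point
#'
#' Bisects on the leading nonzero real part of the stochastic Jacobian at a
#' fixed point tracked across a parameter interval. The tracked point is
#' re-converged (Newton from the previous location) at every parameter value.
#'
#' @param builder function `value -> field_model` (or `value -> function`).
#' @param interval numeric length-2 parameter interval.
#' @param x0 location of the tracked fixed point at `interval[1]` (it is
#'   re-polished at every evaluation).
#' @param rel_tol relative bisection tolerance on the parameter (default 1e-6).
#' @param root_tol residual tolerance for re-polishing the fixed point.
#' @param zero_tol structural-zero eigenvalue tolerance.
#' @return Critical parameter value, with attributes `bracket` and
#'   `leading_eigenvalue` at both ends; `NULL` if the leading eigenvalue does
#'   not change sign over the interval.
#' @export
eigenvalue_crossing <- function(builder, interval, x0, rel_tol = 1e-6,
                                root_tol = 1e-10, zero_tol = NULL) {
  track <- local({
    xcur <- x0
    function(value) {
      field <- builder(value)
      fn <- as_field_fun(field)
      jac <- field_jac_fun(field)
      x <- xcur
      for (it in 1:50) {
        a <- fn(x)
        if (sqrt(sum(a^2)) < root_tol) break
        J <- jac(x)
        step <- tryCatch(-solve(J, a), error = function(e) NULL)
        if (is.null(step)) {
          sv <- svd(J)
          inv <- ifelse(sv$d > 1e-12 * max(sv$d, 1), 1 / sv$d, 0)
          step <- -drop(sv$v %*% (inv * (t(sv$u) %*% a)))
        }
        x <- x + step
      }
      if (sqrt(sum(fn(x)^2)) > 1e-6)
        stop("tracked fixed point lost at parameter value ", value)
      xcur <<- x
      leading_eigenvalue(field, x, zero_tol = zero_tol)
    }
  })
  g_lo <- track(interval[1])
  g_hi <- track(interval[2])
  if (sign(g_lo) == sign(g_hi)) return(NULL)
  lo <- interval[1]; hi <- interval[2]
  while (abs(hi - lo) > rel_tol * max(abs(lo), abs(hi), 1)) {
    mid <- (lo + hi) / 2
    g_mid <- track(mid)
    if (sign(g_mid) == sign(g_lo)) { lo <- mid; g_lo <- g_mid } else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "bracket") <- c(lo, hi)
  attr(out, "leading_eigenvalue") <- c(g_lo, g_hi)
  out
}

# Largest root of the axis-parallel alpha component on the given axis; the
# tracked boundary-maximum location x*(N).
largest_axis_root <- function(field, domain, axis = 1, N = NULL) {
  bm <- boundary_maxima(field, domain, N = N)
  bm <- bm[bm$axis == axis, , drop = FALSE]
  if (nrow(bm) == 0L) return(NULL)
  loc <- if (axis == 1) bm$location_x else bm$location_y
  i <- which.max(loc)
  list(s = loc[i], point = c(bm$location_x[i], bm$location_y[i]),
       perp = bm$perp_component[i])
}

#' Critical system size of the nullcline-gap bifurcation
#'
#' The nullcline-gap bifurcation reverses the direction of the convective
#' flow through the gap between the nullclines near a boundary: when the
#' perpendicular field component at the boundary-maximum location points into
#' the boundary, probability escapes through the gap and a boundary maximum
#' forms; when it points inward, probability is caught in the interior. This
#' operation bisects on the event function
#' `g(N) = alpha_perp(x*(N), boundary)`, where `x*(N)` is the largest root of
#' the axis-parallel component on the boundary axis (`g < 0`: boundary
#' maximum exists; `g > 0`: escape-proof interior).
#'
#' @param builder function `N -> field_model`.
#' @param interval numeric length-2 system-size interval.
#' @param domain 2D domain box for the axis-root scan.
#' @param axis boundary axis (1 = x-axis, default).
#' @param tol absolute tolerance on `g(N*)` / bisection depth control.
#' @param max_depth maximum bisection depth (default 40).
#' @return Critical N with attributes `bracket` (final bracket) and `trace`
#'   (data.frame of every evaluated N, x*(N) and g(N), for audit); `NULL` if
#'   `g` has equal signs at both ends or the axis root disappears.
#' @export
nullcline_gap_critical_size <- function(builder, interval, domain, axis = 1,
                                        tol = 1e-8, max_depth = 40) {
  evals <- list()
  g <- function(N) {
    root <- largest_axis_root(builder(N), domain, axis = axis)
    if (is.null(root)) return(NA_real_)
    evals[[length(evals) + 1L]] <<- data.frame(N = N, x_star = root$s,
                                               g = root$perp)
    root$perp
  }
  g_lo <- g(interval[1]); g_hi <- g(interval[2])
  if (is.na(g_lo) || is.na(g_hi) || sign(g_lo) == sign(g_hi)) return(NULL)
  lo <- interval[1]; hi <- interval[2]
  for (d in seq_len(max_depth)) {
    mid <- (lo + hi) / 2
    g_mid <- g(mid)
    if (is.na(g_mid)) break
    if (abs(g_mid) < tol) { lo <- mid; hi <- mid; break }
    if (sign(g_mid) == sign(g_lo)) { lo <- mid; g_lo <- g_mid } else {
      hi <- mid; g_hi <- g_mid
    }
  }
  out <- (lo + hi) / 2
  attr(out, "bracket") <- c(lo, hi)
  attr(out, "trace") <- do.call(rbind, evals)
  out
}

#' Critical system size of nullcline detachment
#'
#' Bisects on the existence of an interior fixed point of the convective
#' field (interior root count 1 -> 0), the event at which the two nullcline
#' families cease to intersect and the interior density maximum disappears.
#'
#' @param builder function `N -> field_model`.
#' @param interval numeric length-2 system-size interval.
#' @param domain 2D domain box.
#' @param interior_margin roots closer than this to the domain boundary do not
#'   count as interior.
#' @param n_starts,seed multistart controls for the root search.
#' @param rel_tol relative bisection tolerance on N.
#' @return Critical N with attribute `bracket`; `NULL` if the interior fixed
#'   point exists (or is absent) at both ends.
#' @export
nullcline_detachment <- function(builder, interval, domain,
                                 interior_margin = 1e-3, n_starts = 36,
                                 seed = 1, rel_tol = 1e-4) {
  lo_box <- vapply(domain, `[`, 0, 1)
  hi_box <- vapply(domain, `[`, 0, 2)
  has_interior <- function(N) {
    fps <- suppressWarnings(
      find_fixed_points(builder(N), domain, n_starts = n_starts, seed = seed,
                        root_tol = 1e-9))
    margin <- interior_margin * (hi_box - lo_box)
    for (fp in fps) {
      x <- fp$location
      if (all(x > lo_box + margin) && all(x < hi_box - margin)) return(TRUE)
    }
    FALSE
  }
  e_lo <- has_interior(interval[1])
  e_hi <- has_interior(interval[2])
  if (e_lo == e_hi) return(NULL)
  lo <- interval[1]; hi <- interval[2]
  while (abs(hi - lo) > rel_tol * max(abs(lo), abs(hi), 1)) {
    mid <- (lo + hi) / 2
    if (has_interior(mid) == e_lo) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "bracket") <- c(lo, hi)
  out
}

#' Sweep a parameter and collect portrait summaries
#'
#' Evaluates fixed points and boundary-maxima flags over an ordered list of
#' parameter values and reports detected events (eigenvalue crossings of the
#' leading interior fixed point and boundary-inflow sign changes between
#' consecutive values).
#'
#' @param builder function `value -> field_model`.
#' @param values ordered numeric vector of parameter values.
#' @param domain 2D domain box.
#' @param parameter name of the swept parameter (metadata).
#' @param n_starts,seed multistart controls.
#' @return An object of class `"spp_sweep"`: per-value records plus an
#'   `events` data.frame of brackets.
#' @export
sweep_parameter <- function(builder, values, domain, parameter = "N",
                            n_starts = 36, seed = 1) {
  recs <- lapply(values, function(v) {
    field <- builder(v)
    fps <- suppressWarnings(
      find_fixed_points(field, domain, n_starts = n_starts, seed = seed))
    bm <- boundary_maxima(field, domain)
    lead <- if (length(fps))
      max(vapply(fps, function(fp) max(Re(fp$eigenvalues)), 0)) else NA_real_
    list(value = v, fixed_points = fps, boundary_maxima = bm,
         leading_re = lead,
         any_inflow = nrow(bm) > 0 && any(bm$inflow))
  })
  events <- list()
  for (i in seq_along(values)[-1]) {
    a <- recs[[i - 1]]; b <- recs[[i]]
    if (!is.na(a$leading_re) && !is.na(b$leading_re) &&
        sign(a$leading_re) != sign(b$leading_re))
      events[[length(events) + 1L]] <- data.frame(
        type = "eigenvalue-crossing", lower = a$value, upper = b$value)
    if (a$any_inflow != b$any_inflow)
      events[[length(events) + 1L]] <- data.frame(
        type = "nullcline-gap", lower = a$value, upper = b$value)
    if ((length(a$fixed_points) > 0) != (length(b$fixed_points) > 0))
      events[[length(events) + 1L]] <- data.frame(
        type = "nullcline-detachment", lower = a$value, upper = b$value)
  }
  structure(list(parameter = parameter, values = values, records = recs,
                 events = if (length(events)) do.call(rbind, events) else
                   data.frame(type = character(0), lower = numeric(0),
                              upper = numeric(0))),
            class = "spp_sweep")
}
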