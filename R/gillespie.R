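# Exact stochastic simulation (direct-method SSA) of the master equation, for
# validation of the phase-portrait predictions. Pure R: the per-event cost is
# ~10 microseconds, which is sufficient at desk scale; histogram run lengths
# in the test-suite are chosen accordingly.

# Compile the count-space event-rate function a_j(n) = N * nu_j(n): the rate
# expression (written in concentrations) is substituted with n/N, and the
# combinatorial factor becomes a falling factorial in counts over N^sigma.
# Parameters and N are baked into the closure environment.
ssa_rate_function <- function(net) {
  sp <- net$species
  cnt_syms <- lapply(paste0(".n_", sp), as.symbol)
  names(cnt_syms) <- sp
  N_sym <- quote(.N)
  conc_subs <- lapply(cnt_syms, function(s) call("/", s, N_sym))
  exprs <- lapply(net$reactions, function(rx) {
    e <- if (is.numeric(rx$rate)) rx$rate else
      subst_expr(rx$rate, c(conc_subs, list(N = N_sym)))
    out <- call("*", N_sym, e)
    for (spn in names(rx$reactants)) {
      s <- rx$reactants[[spn]]
      for (l in seq_len(s) - 1L) {
        fac <- if (l == 0L) cnt_syms[[spn]] else call("-", cnt_syms[[spn]], l)
        out <- call("*", out, fac)
      }
      out <- call("/", out, if (s == 1L) N_sym else call("^", N_sym, s))
    }
    out
  })
  body <- as.call(c(quote(c), exprs))
  env <- list2env(as.list(net$parameters), parent = baseenv())
  env$.N <- net$system_size
  f <- function() NULL
  formals(f) <- stats::setNames(rep(list(quote(expr = )), length(sp)),
                                paste0(".n_", sp))
  body(f) <- body
  environment(f) <- env
  f
}

#' Simulate an exact SSA trajectory
#'
#' Direct-method stochastic simulation: waiting times are exponential with
#' total rate `N * sum_j nu_j(n)`, the next reaction is chosen proportional
#' to its rate, and the state is updated by the reaction's stoichiometric
#' column. Bitwise reproducible for a fixed seed.
#'
#' @param net a [reaction_network()].
#' @param n0 non-negative integer initial state, in species order.
#' @param t_max simulated time horizon.
#' @param seed integer RNG seed.
#' @param max_events safety cap on the number of events.
#' @return An object of class `"ssa_trajectory"`: `t` (event times, starting
#'   at 0), `states` (event-indexed count matrix, first row = `n0`),
#'   `t_end`, flags `frozen` (all propensities vanished; absorbing state) and
#'   `truncated` (event cap reached).
#' @export
ssa_simulate <- function(net, n0, t_max, seed = 1, max_events = 5e6) {
  stopifnot(inherits(net, "reaction_network"))
  k <- length(net$species)
  if (length(n0) != k || any(n0 < 0) || any(n0 != round(n0)))
    stop("n0 must be a non-negative integer state of length ", k)
  S <- stoichiometric_matrix(net)
  m <- ncol(S)
  ratefun <- ssa_rate_function(net)
  set.seed(seed)
  cap <- 4096L
  ts <- numeric(cap)
  states <- matrix(0, cap, k)
  n <- as.numeric(n0)
  t <- 0
  nev <- 1L
  ts[1] <- 0; states[1, ] <- n
  frozen <- FALSE; truncated <- FALSE
  Scols <- lapply(seq_len(m), function(j) as.numeric(S[, j]))
  args <- as.list(n)
  while (t < t_max) {
    for (i in seq_len(k)) args[[i]] <- n[i]
    a <- do.call(ratefun, args)
    A <- sum(a)
    if (!is.finite(A)) stop("non-finite total event rate at state ",
                            paste(n, collapse = ","))
    if (A <= 0) { frozen <- TRUE; break }
    t <- t + stats::rexp(1L, A)
    if (t >= t_max) break
    j <- 1L + sum(stats::runif(1L, 0, A) > cumsum(a))
    if (j > m) j <- m
    n <- n + Scols[[j]]
    nev <- nev + 1L
    if (nev > cap) {
      cap <- cap * 2L
      length(ts) <- cap
      states <- rbind(states, matrix(0, cap - nrow(states), k))
    }
    ts[nev] <- t
    states[nev, ] <- n
    if (nev >= max_events) { truncated <- TRUE; break }
  }
  structure(
    list(t = ts[seq_len(nev)],
         states = states[seq_len(nev), , drop = FALSE],
         t_end = min(t, t_max), t_max = t_max, network = net, seed = seed,
         frozen = frozen, truncated = truncated),
    class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory:", length(x$t), "events over t in [0,",
      format(x$t_end, digits = 6), "]",
      if (x$frozen) "(frozen/absorbing)" else "",
      if (x$truncated) "(event cap reached)" else "", "\n")
  invisible(x)
}

#' Time-weighted stationary histogram of an SSA trajectory
#'
#' Occupancy histogram over concentration space x = n / N, weighting every
#' state by its holding time (not by event counts), after discarding a
#' burn-in period. Bins are half-open with edges aligned to multiples of
#' 1 / N, so every integer state falls into exactly one bin.
#'
#' @param traj an [ssa_simulate()] result.
#' @param burn_in time to discard (must be < the trajectory end time).
#' @param bins target number of bins per dimension (the realised widths are
#'   rounded up to multiples of 1/N), or a list of per-dimension edge vectors.
#' @return An object of class `"spp_histogram"`: `edges` (per-dimension),
#'   `mass` (array summing to 1), `mids`.
#' @export
stationary_histogram <- function(traj, burn_in = 0, bins = 40) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  if (burn_in >= traj$t_end)
    stop("burn_in (", burn_in, ") must be smaller than the trajectory end time (",
         traj$t_end, ")")
  N <- traj$network$system_size
  k <- ncol(traj$states)
  x <- traj$states / N
  tt <- c(traj$t, traj$t_end)
  w <- diff(tt)
  # partial weight for the interval straddling burn_in
  keep <- tt[-length(tt)] + w > burn_in
  x <- x[keep, , drop = FALSE]
  w <- pmin(w[keep], tt[-1][keep] - burn_in)
  if (is.list(bins)) {
    edges <- bins
  } else {
    edges <- lapply(seq_len(k), function(i) {
      r <- range(x[, i])
      width <- max(1, ceiling((r[2] - r[1]) / bins * N)) / N
      lo <- floor(r[1] * N) / N
      seq(lo, r[2] + width, by = width)
    })
  }
  nb <- vapply(edges, function(e) length(e) - 1L, 0L)
  idx <- matrix(0L, nrow(x), k)
  for (i in seq_len(k)) {
    idx[, i] <- findInterval(x[, i], edges[[i]], left.open = FALSE,
                             rightmost.closed = TRUE)
    idx[, i] <- pmin(pmax(idx[, i], 1L), nb[i])
  }
  flat <- idx[, 1]
  if (k > 1) for (i in 2:k) flat <- flat + (idx[, i] - 1L) * prod(nb[1:(i - 1)])
  mass_vec <- numeric(prod(nb))
  agg <- rowsum(w, flat)
  mass_vec[as.integer(rownames(agg))] <- agg
  mass <- array(mass_vec, dim = nb)
  mass <- mass / sum(mass)
  structure(
    list(edges = edges, mass = mass,
         mids = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
         N = N, species = traj$network$species),
    class = "spp_histogram")
}

# Separable Gaussian smoothing of a histogram array, width in bins.
smooth_array <- function(a, width) {
  if (width <= 0) return(a)
  r <- max(1L, ceiling(3 * width))
  kern <- stats::dnorm(seq(-r, r), sd = width)
  kern <- kern / sum(kern)
  sm1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(vp, kern, sides = 2)[(r + 1):(r + n)]
  }
  if (is.null(dim(a)) || length(dim(a)) == 1L) return(as.numeric(sm1(a)))
  out <- apply(a, 2, sm1)
  t(apply(out, 1, sm1))
}

#' Local modes of a stationary histogram
#'
#' Local maxima of the (optionally kernel-smoothed) histogram mass exceeding
#' a prominence threshold, sorted by decreasing mass. A bin is a mode when it
#' strictly dominates all of its neighbours (8-neighbourhood in 2D), so a
#' flat histogram has no modes.
#'
#' @param hist an [stationary_histogram()] result.
#' @param smoothing Gaussian kernel width in bins (0 = no smoothing).
#' @param prominence threshold as a fraction of the global maximum
#'   (default 0.05).
#' @return data.frame with one row per mode: bin-centre coordinates and mass.
#' @export
histogram_modes <- function(hist, smoothing = 0, prominence = 0.05) {
  stopifnot(inherits(hist, "spp_histogram"))
  a <- smooth_array(hist$mass, smoothing)
  dims <- dim(hist$mass)
  if (is.null(dims)) dims <- length(hist$mass)
  a <- array(a, dim = dims)
  thr <- prominence * max(a)
  k <- length(dims)
  modes <- list()
  if (k == 1L) {
    v <- as.numeric(a); n <- length(v)
    for (i in seq_len(n)) {
      left <- if (i > 1) v[i - 1] else -Inf
      right <- if (i < n) v[i + 1] else -Inf
      if (v[i] > thr && v[i] > left && v[i] > right)
        modes[[length(modes) + 1L]] <- data.frame(x = hist$mids[[1]][i],
                                                  mass = hist$mass[i])
    }
  } else if (k == 2L) {
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      v <- a[i, j]
      if (v <= thr) next
      ok <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= dims[1] && jj >= 1 && jj <= dims[2] &&
            a[ii, jj] >= v) ok <- FALSE
      }
      if (ok)
        modes[[length(modes) + 1L]] <- data.frame(
          x = hist$mids[[1]][i], y = hist$mids[[2]][j], mass = hist$mass[i, j])
    }
  } else stop("histogram_modes supports 1D and 2D histograms")
  if (length(modes) == 0L)
    return(if (k == 1L) data.frame(x = numeric(0), mass = numeric(0)) else
      data.frame(x = numeric(0), y = numeric(0), mass = numeric(0)))
  out <- do.call(rbind, modes)
  out[order(-out$mass), , drop = FALSE]
}
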