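# Adaptive Dormand-Prince 5(4) integrator. deSolve is not assumed to be
# available; trajectories of the convective dynamical system dx/dt = alpha(x)
# only need a standard non-stiff embedded RK pair with step control.

dopri_A <- matrix(c(
  0, 0, 0, 0, 0, 0,
  1/5, 0, 0, 0, 0, 0,
  3/40, 9/40, 0, 0, 0, 0,
  44/45, -56/15, 32/9, 0, 0, 0,
  19372/6561, -25360/2187, 64448/6561, -212/729, 0, 0,
  9017/3168, -355/33, 46732/5247, 49/176, -5103/18656, 0),
  nrow = 6, byrow = TRUE)
dopri_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
dopri_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
dopri_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1)

rk45 <- function(fn, x0, t_max, rtol = 1e-7, atol = 1e-9, h0 = NULL,
                 h_min = 1e-12, max_steps = 2e5, record_dt = 0,
                 max_step = Inf) {
  k <- length(x0)
  x <- x0
  t <- 0
  h <- if (is.null(h0)) min(0.01, t_max / 10) else h0
  ts <- numeric(512); xs <- matrix(0, 512, k)
  np <- 1L; ts[1] <- 0; xs[1, ] <- x0
  last_rec <- 0
  truncated <- FALSE
  f1 <- fn(x)
  steps <- 0L
  while (t < t_max && steps < max_steps) {
    steps <- steps + 1L
    h <- min(h, t_max - t, max_step)
    K <- matrix(0, 7, k)
    K[1, ] <- f1
    for (s in 2:6) {
      xi <- x + h * drop(dopri_A[s, 1:(s - 1)] %*% K[1:(s - 1), , drop = FALSE])
      K[s, ] <- fn(xi)
    }
    x5 <- x + h * drop(dopri_b5 %*% K[1:6, , drop = FALSE])
    K[7, ] <- fn(x5)
    x4 <- x + h * drop(dopri_b4 %*% K)
    sc <- atol + rtol * pmax(abs(x), abs(x5))
    err <- sqrt(mean(((x5 - x4) / sc)^2))
    if (is.finite(err) && err <= 1) {
      t <- t + h
      x <- x5
      f1 <- K[7, ] # FSAL
      if (record_dt <= 0 || t - last_rec >= record_dt || t >= t_max) {
        np <- np + 1L
        if (np > length(ts)) {
          ts <- c(ts, numeric(length(ts)))
          xs <- rbind(xs, matrix(0, nrow(xs), k))
        }
        ts[np] <- t; xs[np, ] <- x
        last_rec <- t
      }
    }
    fac <- if (is.finite(err) && err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    if (h < h_min) { truncated <- TRUE; break }
  }
  if (steps >= max_steps) truncated <- TRUE
  list(t = ts[seq_len(np)], x = xs[seq_len(np), , drop = FALSE],
       truncated = truncated)
}
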