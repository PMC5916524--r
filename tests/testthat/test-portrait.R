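test_that("Jacobians of the ant model match the closed forms", {
  cases <- list(c(eps = 0.01, r = 5, N = 1000),
                c(eps = 0.02, r = 30, N = 1000),
                c(eps = 0.1, r = 1, N = 50))
  for (p in cases) {
    fix <- ant_fixture(r = p[["r"]], eps = p[["eps"]], N = p[["N"]])
    Js <- jacobian(fix$model, c(0.5, 0.5))
    pref <- p[["eps"]] - p[["r"]] / p[["N"]]
    expect_equal(Js, pref * matrix(c(-1, 1, 1, -1), 2), tolerance = 1e-12)
    ev <- sort(Re(eigen(Js, only.values = TRUE)$values))
    expect_equal(ev, sort(c(0, -2 * pref)), tolerance = 1e-12)
    Jd <- jacobian(fix$model, c(0.5, 0.5), which = "f")
    evd <- sort(Re(eigen(Jd, only.values = TRUE)$values))
    expect_equal(evd, sort(c(0, -2 * p[["eps"]])), tolerance = 1e-12)
  }
  # linear toy through the callable interface
  expect_equal(jacobian(function(x) -x, c(0.3, 0.7)), -diag(2),
               tolerance = 1e-8)
})

test_that("classification follows the eigenvalue sign pattern", {
  expect_equal(classify_eigenvalues(c(-1, -2)), "stable-node")
  expect_equal(classify_eigenvalues(complex(real = c(-1, -1),
                                            imaginary = c(2, -2))),
               "stable-spiral")
  expect_equal(classify_eigenvalues(c(1, 2)), "unstable-node")
  expect_equal(classify_eigenvalues(c(-1, 1)), "saddle")
  expect_equal(classify_eigenvalues(c(0, -2)), "marginal/manifold")
  # ant model: stability flips at r/N = eps
  stable <- ant_fixture(r = 5, eps = 0.01, N = 1000)   # r/N = 0.005 < eps
  unstable <- ant_fixture(r = 15, eps = 0.01, N = 1000) # r/N = 0.015 > eps
  law <- conservation_laws(stable$network)[[1]]
  cls_1d <- function(fix) {
    m1 <- reduce_by_conservation(fix$model, law, 1)
    ev <- eval(stats::D(m1$alpha_expr, "X1"),
               c(as.list(fix$network$parameters),
                 list(X1 = 0.5, N = fix$network$system_size)))
    classify_eigenvalues(ev)
  }
  expect_equal(cls_1d(stable), "stable-node")
  expect_equal(cls_1d(unstable), "unstable-node")
})

test_that("fixed points of the constrained and unconstrained ant model", {
  fix <- ant_fixture(r = 5, eps = 0.01, N = 1000)
  law <- conservation_laws(fix$network)[[1]]
  m1 <- reduce_by_conservation(fix$model, law, 1)
  # constrained root: unique at x1 = 1/2
  st <- stationary_density_1d(m1, c(0, 1))
  inter <- st$extrema[!st$extrema$edge, ]
  expect_equal(nrow(inter), 1)
  expect_equal(inter$location, 0.5, tolerance = 1e-9)
  # unconstrained 2D: the root set is the line x1 = x2, reported as
  # marginal/manifold representatives
  fps <- suppressWarnings(
    find_fixed_points(fix$model, list(c(0, 1), c(0, 1)), n_starts = 25,
                      seed = 3))
  expect_gt(length(fps), 0)
  for (fp in fps) {
    expect_lt(abs(fp$location[1] - fp$location[2]), 1e-7)
    expect_equal(fp$classification, "marginal/manifold")
    expect_lt(fp$residual, 1e-9)
  }
})

test_that("interior fixed point of the predator-prey model at N = 80", {
  fps <- find_fixed_points(rm_fixture(N = 80)$model, rm_domain,
                           n_starts = 64, seed = 1)
  stable <- Filter(function(fp) fp$favorable_candidate, fps)
  expect_equal(length(stable), 1)
  expect_equal(stable[[1]]$location[1], 3, tolerance = 0.05)
  expect_lt(stable[[1]]$residual, 1e-9)
})

test_that("find_fixed_points is invariant under n_starts and seed changes", {
  locs <- function(n_starts, seed) {
    fps <- find_fixed_points(rm_fixture(N = 80)$model, rm_domain,
                             n_starts = n_starts, seed = seed)
    sort(vapply(fps, function(fp) fp$location[1], 0))
  }
  base <- locs(36, 1)
  expect_equal(locs(72, 99), base, tolerance = 1e-6)
})

test_that("every reported fixed point re-evaluates below root_tol", {
  for (model in list(rm_fixture(N = 80)$model, rm_fixture(N = 200)$model)) {
    fps <- suppressWarnings(
      find_fixed_points(model, rm_domain, n_starts = 36, seed = 1))
    for (fp in fps)
      expect_lt(sqrt(sum(convective_field(model, fp$location)^2)), 1e-9)
  }
})

test_that("nullclines: toy lines and predator-prey intersection structure", {
  nc <- nullclines(function(x) c(x[1] - 1, x[2] - 2),
                   list(c(0, 3), c(0, 3)), resolution = 64)
  expect_length(nc[[1]], 1)
  expect_equal(unique(round(nc[[1]][[1]]$x, 6)), 1, tolerance = 1e-4)
  expect_equal(unique(round(nc[[2]][[1]]$y, 6)), 2, tolerance = 1e-4)
  # component that never changes sign -> empty
  nc0 <- nullclines(function(x) c(1, x[2] - 1), list(c(0, 2), c(0, 2)), 32)
  expect_length(nc0[[1]], 0)

  # large N: the two nullcline families intersect once in the interior
  # (stable spiral of the deterministic portrait); at N = 10 they no longer do
  crossing_count <- function(N) {
    nc <- nullclines(rm_fixture(N = N)$model, rm_domain, resolution = 192)
    fps <- suppressWarnings(
      find_fixed_points(rm_fixture(N = N)$model, rm_domain, n_starts = 36,
                        seed = 1))
    interior <- Filter(function(fp)
      all(fp$location > 0.05) && fp$location[1] < 11.9 && fp$location[2] < 2.9,
      fps)
    length(interior)
  }
  expect_equal(crossing_count(1000), 1)
  expect_equal(crossing_count(10), 0)
})

test_that("trajectories: stationarity, boundary sliding, step control", {
  model <- rm_fixture(N = 80)$model
  fp <- find_fixed_points(model, rm_domain, n_starts = 36, seed = 1)[[1]]
  tr <- integrate_trajectory(model, fp$location, t_max = 50, record_dt = 0.5)
  expect_lt(max(apply(tr$x, 2, function(v) diff(range(v)))), 1e-6)
  expect_false(tr$truncated)
  # N = 10: no interior fixed point; the flow reaches the x-axis and slides
  # to the boundary maximum near x = 4
  m10 <- rm_fixture(N = 10)$model
  tr10 <- integrate_trajectory(m10, c(2, 1), t_max = 400, record_dt = 0.5)
  endp <- tr10$x[nrow(tr10$x), ]
  expect_equal(endp[2], 0, tolerance = 1e-6)
  expect_equal(endp[1], 4, tolerance = 0.05)
})

test_that("limit-cycle detection: toy circle, spiral, predator-prey", {
  toy <- function(x) {
    r2 <- sum(x^2)
    c(-x[2], x[1]) + (1 - r2) * x
  }
  tr <- integrate_trajectory(toy, c(0.2, 0), t_max = 100, record_dt = 0.01,
                             clip = FALSE)
  cyc <- detect_limit_cycle(tr)
  expect_false(is.null(cyc))
  radii <- sqrt(rowSums(cyc$points^2))
  expect_lt(max(abs(radii - 1)), 1e-3)
  expect_equal(cyc$period, 2 * pi, tolerance = 1e-2)
  expect_lt(stats::sd(cyc$speed) / mean(cyc$speed), 1e-6) # rotational symmetry

  spiral <- function(x) c(-0.2 * x[1] - x[2], x[1] - 0.2 * x[2])
  trs <- integrate_trajectory(spiral, c(1, 0), t_max = 120, record_dt = 0.02,
                              clip = FALSE)
  expect_null(detect_limit_cycle(trs))

  # limit-cycle parameter set at large N: closed orbit, non-constant speed
  mlc <- rm_limit_cycle_fixture(N = 10000)$model
  trl <- integrate_trajectory(mlc, c(2, 1), t_max = 300, record_dt = 0.05)
  cl <- detect_limit_cycle(trl)
  expect_false(is.null(cl))
  expect_gt(stats::sd(cl$speed) / mean(cl$speed), 0.1)
})

test_that("boundary maxima carry correct locations and inflow flags", {
  # stable parameters, N = 10: root near x = 4 with inflow
  bm10 <- boundary_maxima(rm_fixture(N = 10)$model, rm_domain)
  big <- bm10[bm10$axis == 1 & bm10$location_x > 1, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$location_x, 4, tolerance = 0.05)
  expect_true(big$inflow)
  # limit-cycle parameters, N = 50: root near x = 9 with inflow
  bmlc <- boundary_maxima(rm_limit_cycle_fixture(N = 50)$model,
                          list(c(0, 15), c(0, 3)))
  biglc <- bmlc[bmlc$axis == 1 & bmlc$location_x > 1, ]
  expect_equal(biglc$location_x, 9, tolerance = 0.05)
  expect_true(biglc$inflow)
  # stable parameters, N = 1000: the root survives but the flow points away
  # from the boundary -> no boundary maximum
  bmL <- boundary_maxima(rm_fixture(N = 1000)$model, rm_domain)
  bigL <- bmL[bmL$axis == 1 & bmL$location_x > 1, ]
  expect_equal(nrow(bigL), 1)
  expect_false(bigL$inflow)
})

test_that("phase_portrait assembles all layers", {
  pp <- phase_portrait(rm_fixture(N = 80)$model, rm_domain,
                       grid_resolution = 10, nullcline_resolution = 96,
                       n_starts = 25, trajectories = list(c(2, 1)),
                       t_max = 100)
  expect_s3_class(pp, "spp_portrait")
  expect_equal(nrow(pp$grid), 100)
  expect_gt(length(pp$fixed_points), 0)
  expect_gt(nrow(pp$boundary_maxima), 0)
  expect_length(pp$trajectories, 1)
  expect_output(print(pp), "fixed point")
})
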