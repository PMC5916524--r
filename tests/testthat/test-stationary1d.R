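test_that("conservation reduction reproduces the closed-form 1D ant model", {
  fix <- ant_fixture(r = 7.5, eps = 0.01, N = 1000)
  law <- conservation_laws(fix$network)[[1]]
  m1 <- reduce_by_conservation(fix$model, law, total = 1)
  vars <- c("X1", "r", "eps", "N")
  expect_true(expr_equivalent(m1$f_expr, "eps * (1 - 2 * X1)", vars,
                              range = c(0.05, 0.95)))
  expect_true(expr_equivalent(m1$D_expr, "2 * r * X1 * (1 - X1) + eps", vars,
                              range = c(0.05, 0.95)))
  expect_true(expr_equivalent(m1$alpha_expr, "(eps - r/N) * (1 - 2 * X1)",
                              vars, range = c(0.05, 0.95)))
  # invalid laws are rejected
  expect_error(reduce_by_conservation(fix$model, c(0, 0)), "nonzero")
  expect_error(reduce_by_conservation(fix$model, c(1, 2)), "null space")
  # an already-1D model passes through unchanged
  src <- field_model(reaction_network(
    "X", list(parse_reaction("0 -> X @ 1"), parse_reaction("X -> 0 @ 1")),
    system_size = 10))
  m_id <- reduce_by_conservation(src, 1, total = 1)
  expect_s3_class(m_id, "field_model_1d")
  expect_true(expr_equivalent(m_id$f_expr, "1 - X", "X"))
})

test_that("OU drift yields the Gaussian with variance s2/(2 N k)", {
  ou <- field_model_1d("-k * x", "s2", N = 50, parameters = c(k = 2, s2 = 1))
  st <- stationary_density_1d(ou, c(-1.5, 1.5), n = 4001)
  dx <- st$x[2] - st$x[1]
  expect_equal(sum(st$density) * dx, 1, tolerance = 1e-8)
  expect_equal(sum(st$x * st$density) * dx, 0, tolerance = 1e-6)
  expect_equal(sum(st$x^2 * st$density) * dx, 1 / (2 * 50 * 2),
               tolerance = 1e-4)
  expect_equal(st$extrema$location, 0, tolerance = 1e-9)
  expect_equal(st$extrema$type, "max")
})

test_that("reduced ant model is monostable or bistable according to N_C/N", {
  law <- c(1, 1)
  mono <- reduce_by_conservation(
    ant_fixture(r = 7.5, eps = 0.01, N = 1000)$model, law, 1) # N_C/N = 0.75
  st <- stationary_density_1d(mono, c(0, 1))
  expect_equal(st$extrema$location, 0.5, tolerance = 1e-9)
  expect_equal(st$extrema$type, "max")

  bist <- reduce_by_conservation(
    ant_fixture(r = 15, eps = 0.01, N = 1000)$model, law, 1) # N_C/N = 1.5
  st2 <- stationary_density_1d(bist, c(0, 1))
  inter <- st2$extrema[!st2$extrema$edge, ]
  expect_equal(inter$location, 0.5, tolerance = 1e-9)
  expect_equal(inter$type, "min")
  edges <- st2$extrema[st2$extrema$edge, ]
  expect_equal(sort(edges$location), c(0, 1))
  expect_true(all(edges$type == "max"))
})

test_that("alpha roots coincide with density extrema (cubic drift oracle)", {
  cub <- field_model_1d("x - x^3", 1, N = 10)
  ec <- extrema_consistency(cub, c(-2.5, 2.5))
  expect_equal(ec$alpha_roots$location, c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(ec$alpha_roots$type, c("max", "min", "max"))
  expect_lt(ec$max_discrepancy, ec$grid_spacing)

  for (p in list(c(r = 5, eps = 0.01, N = 1000), c(r = 15, eps = 0.01, N = 1000),
                 c(r = 2, eps = 0.1, N = 50))) {
    m1 <- reduce_by_conservation(
      ant_fixture(r = p[["r"]], eps = p[["eps"]], N = p[["N"]])$model,
      c(1, 1), 1)
    ec <- extrema_consistency(m1, c(0, 1), N = p[["N"]])
    expect_lt(ec$max_discrepancy, ec$grid_spacing)
  }
})

test_that("detailed balance: sign(dp/dx) equals sign(alpha) pointwise", {
  models <- list(
    list(m = reduce_by_conservation(ant_fixture(r = 15, eps = 0.01)$model,
                                    c(1, 1), 1), dom = c(0, 1)),
    list(m = field_model_1d("x - x^3", 1, N = 10), dom = c(-2.5, 2.5)),
    list(m = field_model_1d("-k * x", "1 + 0.5 * x^2", N = 20,
                            parameters = c(k = 1)), dom = c(-2, 2)))
  for (case in models) {
    st <- stationary_density_1d(case$m, case$dom, n = 2001)
    dp <- diff(st$density)
    xm <- (st$x[-1] + st$x[-length(st$x)]) / 2
    a <- eval_expr_1d(case$m, case$m$alpha_expr, xm, case$m$network$system_size)
    sig <- abs(a) > 1e-8 & abs(dp) > 1e-12
    expect_true(all(sign(dp[sig]) == sign(a[sig])))
  }
})

test_that("1D stability verdict matches the density extremum type", {
  # Hessian relation specialization: J_s sign at each alpha root determines
  # max (stable) vs min (unstable) for every tested (r, eps, N)
  for (p in list(c(r = 5, eps = 0.01, N = 1000),
                 c(r = 15, eps = 0.01, N = 1000),
                 c(r = 30, eps = 0.05, N = 400))) {
    m1 <- reduce_by_conservation(
      ant_fixture(r = p[["r"]], eps = p[["eps"]], N = p[["N"]])$model,
      c(1, 1), 1)
    st <- stationary_density_1d(m1, c(0, 1), N = p[["N"]])
    inter <- st$extrema[!st$extrema$edge, ]
    for (i in seq_len(nrow(inter))) {
      slope <- eval_expr_1d(m1, stats::D(m1$alpha_expr, "X1"), inter$location[i],
                       p[["N"]])
      expect_equal(inter$type[i], if (slope < 0) "max" else "min")
    }
  }
})

test_that("vanishing interior diffusion is rejected", {
  bad <- field_model_1d("-x", "x^2", N = 10)
  expect_error(stationary_density_1d(bad, c(-1, 1)), "positive")
})
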