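test_that("reaction grammar parses the documented forms", {
  rx <- parse_reaction("X1 + X2 -> 2 X1 @ r")
  expect_equal(rx$reactants, c(X1 = 1L, X2 = 1L))
  expect_equal(rx$products, c(X1 = 2L))
  expect_identical(rx$rate, quote(r))

  rx2 <- parse_reaction("Y -> 0 @ c")
  expect_equal(rx2$reactants, c(Y = 1L))
  expect_length(rx2$products, 0)

  rx3 <- parse_reaction("0 -> X @ 0.25")
  expect_length(rx3$reactants, 0)
  expect_equal(rx3$rate, 0.25)

  rx4 <- parse_reaction("x + y -> 2 y @ d / (1 + A * x)")
  expect_identical(rx4$rate, quote(d / (1 + A * x)))
})

test_that("parse_network validates and reports failures", {
  expect_error(parse_network("species: [X]\nreactions:\n  - X + Q -> X @ 1\n"),
               "undeclared species")
  expect_error(parse_network("species: [X]\nreactions:\n  - X -> 0 @ -2\n"),
               "positive")
  expect_error(parse_network("species: [X]\nreactions:\n  - X 0 @ 1\n"),
               "line 1")
  expect_error(reaction(c(X = 1), c(), rate = 0), "positive")
  expect_error(reaction(c(), c(), rate = 1), "at least one")
})

test_that("networks round-trip through the serializer losslessly", {
  for (fix in list(ant_fixture(), rm_fixture())) {
    net <- fix$network
    text <- write_network(net)
    net2 <- parse_network(text)
    expect_identical(net2$species, net$species)
    expect_identical(stoichiometric_matrix(net2), stoichiometric_matrix(net))
    expect_equal(net2$parameters, net$parameters)
    expect_equal(net2$system_size, net$system_size)
    expect_identical(write_network(net2), text)
  }
  f <- tempfile(fileext = ".yml")
  write_network(ant_fixture()$network, f)
  expect_identical(stoichiometric_matrix(parse_network(file = f)),
                   stoichiometric_matrix(ant_fixture()$network))
  unlink(f)
})

test_that("stoichiometric matrix matches products minus reactants", {
  S <- stoichiometric_matrix(ant_fixture()$network)
  expect_identical(unname(S),
                   matrix(c(1L, -1L, -1L, 1L, -1L, 1L, 1L, -1L), 2, 4))

  one <- reaction_network("X", list(parse_reaction("0 -> X @ 1")))
  expect_identical(unname(stoichiometric_matrix(one)), matrix(1L, 1, 1))

  comp <- reaction_network("X", list(parse_reaction("X + X -> X @ 1")))
  expect_identical(unname(stoichiometric_matrix(comp)), matrix(-1L, 1, 1))

  empty <- reaction_network(c("A", "B"))
  expect_identical(dim(stoichiometric_matrix(empty)), c(2L, 0L))
})

test_that("S = rho - sigma on randomly generated networks", {
  for (seed in 1:25) {
    net <- random_network(seed)
    S <- stoichiometric_matrix(net)
    expect_identical(unname(S), unname(rho_matrix(net) - sigma_matrix(net)),
                     info = paste("seed", seed))
  }
})

test_that("propensities use falling factorials on the concentration scale", {
  unary <- reaction_network("X", list(parse_reaction("X -> 0 @ c")),
                            system_size = 7, parameters = c(c = 2))
  expect_equal(propensities(unary, 5), 2 * 5 / 7)

  binary <- reaction_network("X", list(parse_reaction("X + X -> X @ 0.5")),
                             system_size = 10)
  expect_equal(propensities(binary, 4), 0.5 * 4 * 3 / 100)
  # insufficient molecules -> exactly zero
  expect_equal(propensities(binary, 1), 0)
  tern <- reaction_network("X", list(parse_reaction("3 X -> 0 @ 1")),
                           system_size = 2)
  expect_equal(propensities(tern, 2), 0)
  expect_equal(propensities(tern, 5), 5 * 4 * 3 / 8)
  expect_error(propensities(unary, -1), "negative")
})

test_that("propensity of order-<=1 reactions is the mass-action rate", {
  # nu_j(n) * N equals mu_j * prod n_z / N^(order-1) when all sigma in {0,1}
  net <- ant_fixture(r = 3, eps = 0.2, N = 50)$network
  counts <- c(12, 38)
  nu <- propensities(net, counts)
  expect_equal(nu[1] * 50, 3 * 12 * 38 / 50)
  expect_equal(nu[3] * 50, 0.2 * 12)
})

test_that("conservation laws are exact integer left-null vectors", {
  laws <- conservation_laws(ant_fixture()$network)
  expect_length(laws, 1)
  expect_equal(abs(laws[[1]]), c(1L, 1L))

  expect_length(conservation_laws(rm_fixture()$network), 0)

  iso <- reaction_network(c("X1", "X2"),
                          list(parse_reaction("X1 -> X2 @ 1"),
                               parse_reaction("X2 -> X1 @ 2")))
  laws_iso <- conservation_laws(iso)
  expect_length(laws_iso, 1)
  expect_equal(abs(laws_iso[[1]]), c(1L, 1L))

  for (seed in 26:45) {
    net <- random_network(seed)
    S <- stoichiometric_matrix(net)
    for (law in conservation_laws(S)) {
      expect_true(all(law == round(law)))
      expect_true(any(law != 0))
      expect_identical(as.integer(t(law) %*% S), rep(0L, ncol(S)),
                       info = paste("seed", seed))
    }
    # basis completeness: number of laws equals the corank
    expect_equal(length(conservation_laws(S)),
                 nrow(S) - qr(matrix(as.numeric(S), nrow(S)))$rank,
                 info = paste("seed", seed))
  }
})
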