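# Shared fixtures and generators for the test-suite. Everything is built in
# code; no stored data.

ant_fixture <- function(r = 7.5, eps = 0.01, N = 1000) {
  fixture("foraging_colony", list(r = r, eps = eps, N = N))
}

rm_fixture <- function(N = 1000, ...) {
  fixture("rosenzweig_macarthur", c(list(N = N), list(...)))
}

rm_limit_cycle_fixture <- function(N = 1000) {
  fixture("rosenzweig_macarthur", list(delta = 0.1, beta = 0.9, N = N))
}

rm_domain <- list(c(0, 12), c(0, 3))

immigration_death_net <- function(q = 1, cc = 1, N = 100) {
  parse_network(sprintf("
species: [X]
parameters: {q: %g, c: %g}
reactions:
  - 0 -> X @ q
  - X -> 0 @ c
system_size: %g
", q, cc, N))
}

# Random small mass-action network for property tests.
random_network <- function(seed, max_species = 3, max_reactions = 5) {
  set.seed(seed)
  k <- sample(1:max_species, 1)
  sp <- paste0("S", seq_len(k))
  m <- sample(0:max_reactions, 1)
  reactions <- lapply(seq_len(m), function(j) {
    repeat {
      sig <- sample(0:2, k, replace = TRUE, prob = c(0.5, 0.35, 0.15))
      rho <- sample(0:2, k, replace = TRUE, prob = c(0.5, 0.35, 0.15))
      if (any(sig > 0) || any(rho > 0)) break
    }
    reaction(setNames(sig, sp), setNames(rho, sp),
             rate = round(runif(1, 0.1, 3), 3))
  })
  reaction_network(sp, reactions, system_size = sample(c(10, 100, 1000), 1))
}

sigma_matrix <- function(net) {
  k <- length(net$species); m <- length(net$reactions)
  out <- matrix(0L, k, m, dimnames = list(net$species, NULL))
  for (j in seq_len(m)) {
    rx <- net$reactions[[j]]
    out[names(rx$reactants), j] <- rx$reactants
  }
  out
}

rho_matrix <- function(net) {
  k <- length(net$species); m <- length(net$reactions)
  out <- matrix(0L, k, m, dimnames = list(net$species, NULL))
  for (j in seq_len(m)) {
    rx <- net$reactions[[j]]
    out[names(rx$products), j] <- rx$products
  }
  out
}

# Evaluate a 1D-model expression at given coordinate values.
eval_expr_1d <- function(model, expr, x, N = model$network$system_size) {
  e <- as.list(model$network$parameters)
  e$N <- N
  e[[model$species]] <- x
  eval(expr, e)
}
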