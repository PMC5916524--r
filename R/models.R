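# Built-in model fixtures, written in the package's own model dialect so the
# parser is on the main path.

foraging_colony_text <- function(r, eps, N) {
  sprintf(
"species: [X1, X2]
parameters: {r: %.17g, eps: %.17g}
reactions:
  - X1 + X2 -> 2 X1 @ r
  - X1 + X2 -> 2 X2 @ r
  - X1 -> X2 @ eps
  - X2 -> X1 @ eps
system_size: %s
", r, eps, fmt_num(N))
}

rosenzweig_macarthur_text <- function(p, N) {
  sprintf(
"species: [x, y]
parameters: {A: %.17g, b: %.17g, c: %.17g, d: %.17g, q: %.17g, delta: %.17g, beta: %.17g}
reactions:
  - x -> 2 x @ beta
  - x + x -> x @ delta
  - x + y -> 2 y @ d / (1 + A * x)
  - x + y -> y @ (b - d) / (1 + A * x)
  - y -> 0 @ c
  - 0 -> x @ q
  - 0 -> y @ q
system_size: %s
", p[["A"]], p[["b"]], p[["c"]], p[["d"]], p[["q"]], p[["delta"]], p[["beta"]], fmt_num(N))
}

#' Built-in model fixtures
#'
#' Two fixtures are provided.
#'
#' `"foraging_colony"`: two ant "species" feeding on two food sources;
#' recruitment (`X1 + X2 -> 2 X1` and mirror, rate `r`) and spontaneous
#' switching (`X1 -> X2` and mirror, rate `eps`). The total concentration
#' `x1 + x2` is conserved, and the behaviour is governed by `N_C = r / eps`
#' relative to the system size N (monostable for `N_C < N`, bistable with
#' boundary maxima for `N_C > N`). Defaults: `eps = 0.01`, `r = 7.5`,
#' `N = 1000` (i.e. the monostable `N_C / N = 0.75` case).
#'
#' `"rosenzweig_macarthur"`: predator-prey dynamics with logistic prey
#' growth, a Holling type-II functional response, and small immigration
#' terms (`q`) kept in the network to prevent spontaneous extinctions.
#' Defaults are the stable-fixed-point parameter set `A = 2/3, d = 0.65,
#' c = 0.65, b = 1, q = 0.01, delta = 0.2, beta = 0.8`, `N = 1000`; the
#' limit-cycle regime is reached by overriding `delta = 0.1, beta = 0.9`.
#'
#' @param name fixture name.
#' @param overrides named list of parameter overrides; the entry `N`
#'   overrides the system size.
#' @param derivative_policy passed to [field_model()].
#' @return List with `network` (a [reaction_network()]), `model` (a
#'   [field_model()]), `name`, and `derived` (named derived quantities:
#'   `N_C` for the foraging colony; `kappa` and `eps_eff` for the
#'   predator-prey fixture).
#' @export
fixture <- function(name, overrides = list(),
                    derivative_policy = c("symbolic", "fd")) {
  known <- c("foraging_colony", "rosenzweig_macarthur")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  if (name == "foraging_colony") {
    p <- list(r = 7.5, eps = 0.01, N = 1000)
    p[names(overrides)] <- overrides
    net <- parse_network(foraging_colony_text(p$r, p$eps, p$N))
    derived <- c(N_C = p$r / p$eps)
  } else {
    p <- list(A = 2 / 3, b = 1, c = 0.65, d = 0.65, q = 0.01,
              delta = 0.2, beta = 0.8, N = 1000)
    p[names(overrides)] <- overrides
    net <- parse_network(rosenzweig_macarthur_text(p, p$N))
    derived <- c(kappa = p$A * p$c / p$d,
                 eps_eff = p$delta * p$c / (p$beta * p$d))
  }
  list(name = name, network = net,
       model = field_model(net, match.arg(derivative_policy)),
       derived = derived)
}

#' Effective parameters of the predator-prey fixture
#'
#' The deterministic regime (stable coexistence, limit cycle, predator
#' extinction) of the Holling type-II predator-prey model is governed by the
#' dimensionless combinations `kappa = A * c / d` and
#' `eps_eff = delta * c / (beta * d)`.
#'
#' @param fix a [fixture()] result.
#' @return named numeric vector `c(kappa =, eps_eff =)`.
#' @export
effective_parameters <- function(fix) {
  if (!identical(fix$name, "rosenzweig_macarthur"))
    stop("effective parameters kappa/eps_eff are defined for the ",
         "'rosenzweig_macarthur' fixture only")
  fix$derived
}
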