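#' Randomized symbolic-identity check for field expressions
#'
#' R ships no computer-algebra system, but the field quantities built by
#' [field_model()] are polynomial or rational in the species concentrations
#' and parameters. Equality of two such expressions is therefore verified by
#' randomized polynomial identity testing (Schwartz-Zippel): the expressions
#' are evaluated at `n` random points for the variables, and declared
#' equivalent when they agree to relative tolerance `tol` at all of them,
#' which for rational functions is a sound identity test up to vanishing
#' probability.
#'
#' @param e1,e2 expressions (language objects or strings).
#' @param vars character vector of free variable names; values are drawn
#'   uniformly from `range`.
#' @param n number of random evaluation points.
#' @param seed RNG seed.
#' @param tol relative tolerance.
#' @param range length-2 sampling range for the variables.
#' @return TRUE/FALSE, with attribute `max_rel_err`.
#' @export
expr_equivalent <- function(e1, e2, vars, n = 200, seed = 1, tol = 1e-9,
                            range = c(0.1, 2)) {
  if (is.character(e1)) e1 <- str2lang(e1)
  if (is.character(e2)) e2 <- str2lang(e2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  vals <- matrix(stats::runif(n * length(vars), range[1], range[2]), n,
                 length(vars), dimnames = list(NULL, vars))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  worst <- 0
  for (i in seq_len(n)) {
    env <- as.list(vals[i, ])
    v1 <- eval(e1, env)
    v2 <- eval(e2, env)
    rel <- abs(v1 - v2) / max(abs(v1), abs(v2), 1e-12)
    if (!is.finite(rel)) rel <- Inf
    worst <- max(worst, rel)
  }
  structure(worst <= tol, max_rel_err = worst)
}

#' Convective-field expressions of a symbolic model
#'
#' Returns the exact expressions for the components of the convective field
#' `alpha` (with species, parameter and `N` symbols unresolved), e.g. for
#' regression tests against hand-derived closed forms.
#'
#' @param model a [field_model()] with the symbolic policy.
#' @return named list of language objects, one per species.
#' @export
alpha_expressions <- function(model) {
  stopifnot(inherits(model, "field_model"))
  if (is.null(model$alpha_exprs))
    stop("alpha expressions require derivative_policy = 'symbolic'")
  stats::setNames(model$alpha_exprs, model$network$species)
}

#' Drift expressions of a symbolic model
#'
#' @param model a [field_model()].
#' @return named list of language objects, one per species.
#' @export
drift_expressions <- function(model) {
  stopifnot(inherits(model, "field_model"))
  stats::setNames(model$f_exprs, model$network$species)
}
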