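# Symbolic expression helpers ------------------------------------------------
# Propensities of mass-action networks are polynomials (or, with state-
# dependent rate factors, rational functions) of the concentrations, so exact
# derivatives are available through stats::D. All field quantities are built
# once as R expressions over the species symbols, the parameter symbols and N,
# and evaluated vectorised.

expr_zero <- quote(0)

expr_add <- function(a, b) {
  if (identical(a, expr_zero)) return(b)
  if (identical(b, expr_zero)) return(a)
  call("+", a, b)
}

expr_mul <- function(a, b) {
  if (identical(a, expr_zero) || identical(b, expr_zero)) return(expr_zero)
  if (identical(a, quote(1)) || identical(a, 1)) return(b)
  if (identical(b, quote(1)) || identical(b, 1)) return(a)
  call("*", a, b)
}

expr_scale <- function(coef, e) {
  if (coef == 0) return(expr_zero)
  if (coef == 1) return(e)
  if (coef == -1) return(call("-", e))
  expr_mul(coef, e)
}

# Recursive symbol substitution: replace symbols named in `subs` by the
# corresponding language objects.
subst_expr <- function(e, subs) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(subs)) return(subs[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- subst_expr(e[[i]], subs)
    return(e)
  }
  e
}

# Propensity of one reaction in concentration space: rate(x) times the
# falling-factorial combinatorics written in concentrations,
# prod_z prod_{l=0}^{sigma-1} (x_z - l/N).
propensity_expr <- function(rx) {
  e <- if (is.numeric(rx$rate)) rx$rate else rx$rate
  out <- if (is.numeric(e) && e == 1) quote(1) else e
  for (sp in names(rx$reactants)) {
    s_sym <- as.symbol(sp)
    for (l in seq_len(rx$reactants[[sp]]) - 1L) {
      fac <- if (l == 0L) s_sym else call("-", s_sym, call("/", l, quote(N)))
      out <- expr_mul(out, fac)
    }
  }
  out
}

#' Build drift, diffusion, and convective field from a network
#'
#' Constructs the Fokker-Planck field quantities on concentration space
#' x = n / N: the deterministic drift `f(x) = S %*% nu(x)`, the diffusion
#' matrix `D(x) = S %*% diag(nu) %*% t(S)`, and the convective field
#' `alpha_i(x) = f_i(x) - 1/(2N) * sum_k dD_ik/dx_k`. Stable fixed points of
#' alpha are the candidate maxima (favorable states) of the stationary
#' probability density.
#'
#' Propensities retain the finite-size factors of the falling factorials
#' (e.g. `x * (x - 1/N)` for a binary self-interaction), so the fields agree
#' with the master equation at any N rather than only in the thermodynamic
#' limit.
#'
#' @param net a [reaction_network()].
#' @param derivative_policy `"symbolic"` (exact derivatives of the
#'   polynomial/rational propensities; default) or `"fd"` (central finite
#'   differences with step `h = eps^(1/3) * (1 + |x|)`, for black-box use).
#' @return An object of class `"field_model"` with callable components; see
#'   [drift()], [diffusion_matrix()], [convective_field()].
#' @export
field_model <- function(net, derivative_policy = c("symbolic", "fd")) {
  stopifnot(inherits(net, "reaction_network"))
  derivative_policy <- match.arg(derivative_policy)
  S <- stoichiometric_matrix(net)
  k <- length(net$species)
  m <- length(net$reactions)
  nu <- lapply(net$reactions, propensity_expr)
  f <- vector("list", k)
  D <- matrix(list(), k, k)
  for (i in seq_len(k)) {
    fi <- expr_zero
    for (j in seq_len(m)) fi <- expr_add(fi, expr_scale(S[i, j], nu[[j]]))
    f[[i]] <- fi
    for (l in seq_len(k)) {
      e <- expr_zero
      for (j in seq_len(m)) e <- expr_add(e, expr_scale(S[i, j] * S[l, j], nu[[j]]))
      D[[i, l]] <- e
    }
  }
  alpha <- NULL
  if (derivative_policy == "symbolic") {
    alpha <- vector("list", k)
    for (i in seq_len(k)) {
      div <- expr_zero
      for (l in seq_len(k))
        div <- expr_add(div, stats::D(D[[i, l]], net$species[[l]]))
      alpha[[i]] <- if (identical(div, expr_zero)) f[[i]] else
        call("-", f[[i]], call("*", call("/", 1, call("*", 2, quote(N))), div))
    }
  }
  structure(
    list(network = net, S = S, nu_exprs = nu, f_exprs = f, D_exprs = D,
         alpha_exprs = alpha, derivative_policy = derivative_policy,
         cache = new.env(parent = emptyenv())),
    class = "field_model")
}

#' @export
print.field_model <- function(x, ...) {
  cat("Field model (", x$derivative_policy, " derivatives) over species ",
      paste(x$network$species, collapse = ", "), "\n", sep = "")
  for (i in seq_along(x$f_exprs))
    cat("  f_", x$network$species[[i]], " = ", deparse1(x$f_exprs[[i]]), "\n", sep = "")
  invisible(x)
}

field_env <- function(model, x, N) {
  sp <- model$network$species
  k <- length(sp)
  e <- as.list(model$network$parameters)
  e$N <- N
  if (is.matrix(x)) {
    if (ncol(x) != k) stop("x must have ", k, " columns")
    for (i in seq_len(k)) e[[sp[i]]] <- x[, i]
  } else {
    if (length(x) != k) stop("x must have length ", k, " (one per species)")
    for (i in seq_len(k)) e[[sp[i]]] <- x[[i]]
  }
  e
}

eval_exprs <- function(exprs, env, nrow_out) {
  out <- matrix(0, nrow_out, length(exprs))
  for (i in seq_along(exprs)) {
    v <- eval(exprs[[i]], env)
    out[, i] <- v
  }
  out
}

#' Deterministic drift f(x)
#'
#' @param model a [field_model()].
#' @param x concentration vector (length k), or an n x k matrix of points.
#' @param N system size (defaults to the network's); enters only through the
#'   finite-size falling-factorial factors.
#' @return Drift vector (or n x k matrix of drift vectors).
#' @export
drift <- function(model, x, N = model$network$system_size) {
  stopifnot(inherits(model, "field_model"))
  env <- field_env(model, x, N)
  n <- if (is.matrix(x)) nrow(x) else 1L
  out <- eval_exprs(model$f_exprs, env, n)
  if (is.matrix(x)) out else drop(out)
}

#' Diffusion matrix D(x)
#'
#' `D(x) = S %*% diag(nu(x)) %*% t(S)`; symmetric by construction, positive
#' semidefinite on the non-negative orthant (positive definite wherever the
#' propensities span the species space).
#'
#' @inheritParams drift
#' @return k x k symmetric matrix (single point only).
#' @export
diffusion_matrix <- function(model, x, N = model$network$system_size) {
  stopifnot(inherits(model, "field_model"), !is.matrix(x))
  env <- field_env(model, x, N)
  k <- length(model$network$species)
  D <- matrix(0, k, k, dimnames = list(model$network$species, model$network$species))
  for (i in seq_len(k)) for (l in seq_len(k))
    D[i, l] <- eval(model$D_exprs[[i, l]], env)
  D
}

divergence_D_fd <- function(model, x, N) {
  k <- length(model$network$species)
  h <- (.Machine$double.eps)^(1/3) * (1 + abs(x))
  div <- numeric(k)
  for (l in seq_len(k)) {
    xp <- x; xm <- x
    xp[l] <- x[l] + h[l]; xm[l] <- x[l] - h[l]
    Dp <- diffusion_matrix(model, xp, N)
    Dm <- diffusion_matrix(model, xm, N)
    div <- div + unname(Dp[, l] - Dm[, l]) / (xp[l] - xm[l])
  }
  div
}

#' Convective field alpha(x)
#'
#' `alpha_i(x) = f_i(x) - 1/(2N) * sum_k dD_ik/dx_k`. The convective field
#' transports probability toward the favorable states; it converges to the
#' drift pointwise as N grows, with O(1/N) error.
#'
#' @inheritParams drift
#' @return Convective field vector (or n x k matrix).
#' @export
convective_field <- function(model, x, N = model$network$system_size) {
  stopifnot(inherits(model, "field_model"))
  if (model$derivative_policy == "symbolic") {
    env <- field_env(model, x, N)
    n <- if (is.matrix(x)) nrow(x) else 1L
    out <- eval_exprs(model$alpha_exprs, env, n)
    if (any(!is.finite(out))) {
      bad <- which(apply(!is.finite(out), 2, any))
      stop("non-finite convective-field component(s): ",
           paste(model$network$species[bad], collapse = ", "))
    }
    return(if (is.matrix(x)) out else drop(out))
  }
  one <- function(xx) {
    val <- drift(model, xx, N) - divergence_D_fd(model, xx, N) / (2 * N)
    if (any(!is.finite(val)))
      stop("non-finite convective-field component(s): ",
           paste(model$network$species[!is.finite(val)], collapse = ", "))
    val
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Probability current j(x)
#'
#' `j = alpha * p - 1/(2N) * D %*% grad_p`: the convective current `alpha*p`
#' plus the diffusive current `-(1/2N) D grad p`. Vanishes identically at a
#' density extremum that is also a root of alpha.
#'
#' @inheritParams drift
#' @param p density value at x (non-negative scalar).
#' @param grad_p density gradient at x (length-k vector).
#' @return Current vector of length k.
#' @export
probability_current <- function(model, x, p, grad_p,
                                N = model$network$system_size) {
  stopifnot(inherits(model, "field_model"), p >= 0, length(grad_p) == length(x))
  a <- convective_field(model, x, N)
  D <- diffusion_matrix(model, x, N)
  unname(drop(a * p - (D %*% grad_p) / (2 * N)))
}

# Jacobian of alpha (or f) by the active derivative policy; used by the root
# finder and the classifier.
field_jacobian_exprs <- function(model, which = c("alpha", "f")) {
  which <- match.arg(which)
  key <- paste0("jac_", which)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  sp <- model$network$species
  k <- length(sp)
  src <- if (which == "alpha") model$alpha_exprs else model$f_exprs
  if (is.null(src)) return(NULL)
  J <- matrix(list(), k, k)
  for (i in seq_len(k)) for (l in seq_len(k))
    J[[i, l]] <- stats::D(src[[i]], sp[[l]])
  model$cache[[key]] <- J
  J
}

#' Export a sampled vector-field grid
#'
#' Evaluates the convective field on a regular grid over a 2D box and returns
#' a data frame (columns: coordinates and field components) ready for CSV or
#' JSON export.
#'
#' @param model a [field_model()].
#' @param domain list of per-species ranges `list(c(lo, hi), c(lo, hi))`.
#' @param resolution points per axis.
#' @inheritParams drift
#' @return data.frame with 2k columns.
#' @export
field_grid <- function(model, domain, resolution = 25,
                       N = model$network$system_size) {
  sp <- model$network$species
  stopifnot(length(domain) == length(sp))
  axes <- lapply(domain, function(r) seq(r[1], r[2], length.out = resolution))
  pts <- as.matrix(expand.grid(axes))
  colnames(pts) <- sp
  a <- convective_field(model, pts, N)
  colnames(a) <- paste0("alpha_", sp)
  cbind(as.data.frame(pts), as.data.frame(a))
}
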