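#' Create a single reaction
#'
#' A reaction is a pair of stoichiometric maps (reactants `sigma`, products
#' `rho`) together with a rate. The rate may be a positive number, the name of
#' a parameter, or an arithmetic expression over parameters and species
#' concentrations (e.g. `"d / (1 + A * x)"` for a Holling type-II
#' interaction). Symbolic rates are resolved against the network's parameter
#' table when fields are built.
#'
#' @param reactants named integer vector, species -> stoichiometric
#'   coefficient (may be empty for a pure source reaction).
#' @param products named integer vector, species -> stoichiometric
#'   coefficient (may be empty for a pure sink reaction).
#' @param rate positive number, parameter name, or expression (string or
#'   language object).
#' @param label optional text label.
#' @return An object of class `"spp_reaction"`.
#' @export
reaction <- function(reactants, products, rate, label = "") {
  reactants <- validate_stoich(reactants, "reactants")
  products <- validate_stoich(products, "products")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction must have at least one reactant or product")
  rate <- as_rate(rate)
  if (is.numeric(rate) && rate <= 0)
    stop("reaction rate must be positive, got ", rate)
  structure(
    list(reactants = reactants, products = products, rate = rate,
         label = as.character(label)),
    class = "spp_reaction")
}

validate_stoich <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named vector (species -> coefficient)")
  if (any(x != round(x)) || any(x < 0))
    stop(what, " coefficients must be non-negative integers")
  x <- x[x > 0]
  storage.mode(x) <- "integer"
  x
}

as_rate <- function(rate) {
  if (is.numeric(rate)) {
    stopifnot(length(rate) == 1L, is.finite(rate))
    return(rate)
  }
  if (is.character(rate)) {
    expr <- tryCatch(str2lang(rate), error = function(e)
      stop("cannot parse rate expression '", rate, "': ", conditionMessage(e)))
    # constant expressions (including negative literals) fold to numbers
    v <- tryCatch(eval(expr, baseenv()), error = function(e) NULL)
    if (is.numeric(v) && length(v) == 1L) return(as.numeric(v))
    return(expr)
  }
  if (is.language(rate) || is.symbol(rate)) return(rate)
  stop("rate must be numeric, a string, or a language object")
}

#' Create a reaction network
#'
#' The network is the single source of truth for all downstream analyses:
#' species ordering fixes row order of the stoichiometric matrix, the
#' parameter table resolves symbolic rates, and the system size `N` scales
#' the intrinsic noise (concentrations are x = n / N).
#'
#' @param species character vector of unique species names.
#' @param reactions list of [reaction()] objects.
#' @param system_size positive real N.
#' @param parameters named numeric vector resolving symbolic rate parameters.
#' @return An object of class `"reaction_network"`.
#' @export
reaction_network <- function(species, reactions = list(), system_size = 1,
                             parameters = numeric(0)) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species names must be unique")
  if (length(system_size) != 1L || !is.finite(system_size) || system_size <= 0)
    stop("system_size must be a positive real")
  if (inherits(reactions, "spp_reaction")) reactions <- list(reactions)
  for (rx in reactions) {
    if (!inherits(rx, "spp_reaction")) stop("reactions must be spp_reaction objects")
    used <- union(names(rx$reactants), names(rx$products))
    bad <- setdiff(used, species)
    if (length(bad))
      stop("reaction '", deparse_reaction(rx), "' references undeclared species: ",
           paste(bad, collapse = ", "))
  }
  if (length(parameters)) {
    if (is.null(names(parameters)) || any(!nzchar(names(parameters))))
      stop("parameters must be a named numeric vector")
    parameters <- unlist(parameters)
    storage.mode(parameters) <- "double"
  }
  structure(
    list(species = species, reactions = reactions,
         system_size = as.numeric(system_size),
         parameters = parameters),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions, N =", x$system_size, "\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (rx in x$reactions) cat("  ", deparse_reaction(rx), "\n")
  if (length(x$parameters))
    cat("  parameters:",
        paste(names(x$parameters), signif(x$parameters, 6), sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}

# Format a number so the YAML dialect round-trips it as a number: integers
# beyond the 32-bit range must carry a decimal point to resolve as floats.
fmt_num <- function(v) {
  if (v == round(v) && abs(v) < 2^31) return(sprintf("%d", as.integer(v)))
  s <- sprintf("%.17g", v)
  if (!grepl(".", s, fixed = TRUE)) s <- sub("(e|$)", ".0\\1", s)
  s
}

side_to_string <- function(stoich) {
  if (length(stoich) == 0L) return("0")
  paste(ifelse(stoich > 1L, paste(stoich, names(stoich)), names(stoich)),
        collapse = " + ")
}

deparse_rate <- function(rate) {
  if (is.numeric(rate)) format(rate, digits = 15) else deparse1(rate)
}

deparse_reaction <- function(rx) {
  paste(side_to_string(rx$reactants), "->", side_to_string(rx$products),
        "@", deparse_rate(rx$rate))
}

# --- reaction grammar ---------------------------------------------------------
# "reactants -> products @ rate", e.g. "X1 + X2 -> 2 X1 @ r", "Y -> 0 @ c",
# "0 -> X @ q". "0" (or the empty-set sign) denotes the empty side. Integer
# stoichiometric prefixes; rate is a number, parameter, or expression.

parse_side <- function(text, line) {
  text <- trimws(text)
  if (text == "0" || text == "∅" || text == "")
    return(stats::setNames(integer(0), character(0)))
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  out <- integer(0)
  for (term in terms) {
    term <- trimws(term)
    if (!nzchar(term))
      stop("line ", line, ": empty term in '", text, "'")
    m <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z_.][A-Za-z0-9_.]*)$", term))[[1]]
    if (length(m) == 0L)
      stop("line ", line, ": cannot parse species term '", term, "'")
    coef <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    sp <- m[3]
    out[sp] <- if (sp %in% names(out)) out[[sp]] + coef else coef
  }
  out
}

#' Parse a single reaction grammar string
#'
#' Grammar: `"reactants -> products @ rate"` with integer stoichiometric
#' prefixes and `0` for the empty side, e.g. `"X1 + X2 -> 2 X1 @ r"` or
#' `"Y -> 0 @ c"`.
#'
#' @param text grammar string.
#' @param line optional line number used in error messages.
#' @return A [reaction()].
#' @export
parse_reaction <- function(text, line = NA) {
  parts <- strsplit(text, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("line ", line, ": reaction must contain exactly one '@': '", text, "'")
  sides <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("line ", line, ": reaction must contain exactly one '->': '", text, "'")
  reaction(parse_side(sides[1], line), parse_side(sides[2], line),
           trimws(parts[2]))
}

#' Parse a model description into a reaction network
#'
#' The model dialect is a YAML document with keys `species` (list of names),
#' `parameters` (map name -> value), `reactions` (list of grammar strings
#' `"reactants -> products @ rate"`) and `system_size`. [write_network()]
#' emits the identical dialect, and the pair round-trips losslessly.
#'
#' @param text model description as a single string, or a character vector of
#'   lines.
#' @param file alternatively, path to a model file.
#' @return A [reaction_network()].
#' @examples
#' net <- parse_network("
#' species: [X]
#' parameters: {q: 1.0, c: 0.5}
#' reactions:
#'   - 0 -> X @ q
#'   - X -> 0 @ c
#' system_size: 100
#' ")
#' @export
parse_network <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply text or file")
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  # keep YAML 1.1 boolean-like scalars (y, n, yes, no, ...) as plain strings:
  # they are common species names
  keep <- function(x) x
  doc <- tryCatch(
    yaml::yaml.load(text, handlers = list("bool#yes" = keep, "bool#no" = keep)),
    error = function(e) stop("model syntax error: ", conditionMessage(e)))
  if (!is.list(doc)) stop("model document must be a mapping")
  species <- as.character(unlist(doc$species))
  if (length(species) == 0L) stop("model must declare at least one species")
  params <- unlist(doc$parameters)
  if (!is.null(params) && !is.numeric(params))
    stop("parameters must map names to numbers")
  rx_strings <- as.character(unlist(doc$reactions))
  reactions <- lapply(seq_along(rx_strings), function(i)
    parse_reaction(rx_strings[i], line = i))
  N <- doc$system_size
  if (is.null(N)) N <- 1
  net <- reaction_network(species, reactions, system_size = N,
                          parameters = if (is.null(params)) numeric(0) else params)
  net
}

#' Serialize a reaction network to the model dialect
#'
#' @param net a [reaction_network()].
#' @param file optional path; if omitted the document is returned as a string.
#' @return The document text, invisibly when written to a file.
#' @export
write_network <- function(net, file = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  lines <- c(
    paste0("species: [", paste(net$species, collapse = ", "), "]"),
    if (length(net$parameters))
      paste0("parameters: {",
             paste(names(net$parameters),
                   vapply(net$parameters, fmt_num, ""),
                   sep = ": ", collapse = ", "), "}"),
    "reactions:",
    vapply(net$reactions, function(rx) paste0("  - ", deparse_reaction(rx)), ""),
    paste0("system_size: ", fmt_num(net$system_size)))
  text <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

#' Stoichiometric matrix of a network
#'
#' Entry (i, j) is the net change of species i in reaction j:
#' `S[i, j] = rho[i, j] - sigma[i, j]` (products minus reactants).
#'
#' @param net a [reaction_network()].
#' @return Integer k x m matrix with species as rownames.
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  k <- length(net$species)
  m <- length(net$reactions)
  S <- matrix(0L, nrow = k, ncol = m,
              dimnames = list(net$species,
                              if (m) paste0("r", seq_len(m)) else NULL))
  for (j in seq_len(m)) {
    rx <- net$reactions[[j]]
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
  }
  S
}

# Evaluation environment for symbolic rates: parameters, N, and species
# concentrations.
rate_env <- function(net, x = NULL) {
  e <- as.list(net$parameters)
  e$N <- net$system_size
  if (!is.null(x)) e[net$species] <- as.list(x)
  e
}

eval_rate <- function(rate, env) {
  if (is.numeric(rate)) return(rate)
  v <- eval(rate, env)
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("rate expression '", deparse1(rate), "' did not evaluate to a finite number")
  v
}

#' Propensity vector at an integer state
#'
#' For reaction j with reactant coefficients sigma, the propensity is the
#' rate constant times the combinatorial factor for the reactant molecules to
#' meet, on the concentration scale:
#' `nu_j = mu_j * prod_z N^(-sigma_zj) * n_z! / (n_z - sigma_zj)!`.
#' Falling factorials are used directly (never full factorials), so large
#' counts do not overflow. The propensity is zero whenever any `n_z <
#' sigma_zj`. The total stochastic event rate of reaction j is `N * nu_j`.
#'
#' @param net a [reaction_network()].
#' @param counts non-negative integer vector of molecule numbers, in species
#'   order.
#' @return Numeric vector of propensities, one per reaction.
#' @export
propensities <- function(net, counts) {
  stopifnot(inherits(net, "reaction_network"))
  k <- length(net$species)
  if (length(counts) != k) stop("counts must have one entry per species")
  if (any(counts < 0)) stop("negative molecule counts")
  if (any(counts != round(counts))) stop("molecule counts must be integers")
  N <- net$system_size
  x <- counts / N
  env <- rate_env(net, x)
  vapply(net$reactions, function(rx) {
    nu <- eval_rate(rx$rate, env)
    for (sp in names(rx$reactants)) {
      s <- rx$reactants[[sp]]
      n <- counts[[match(sp, net$species)]]
      if (n < s) return(0)
      # falling factorial n (n-1) ... (n-s+1), scaled by N^-s
      for (l in seq_len(s) - 1L) nu <- nu * (n - l) / N
    }
    nu
  }, numeric(1))
}

# --- conservation laws --------------------------------------------------------

# Exact rational null space of the transpose (left null space of S), returned
# with integer entries scaled to smallest terms. Implemented as fraction-free
# Gauss-Jordan elimination over the rationals on small matrices; tolerance-free.
#' Conservation laws of a stoichiometric matrix
#'
#' Returns an integer basis of the left null space \{c : t(c) %*% S = 0\}.
#' Each law corresponds to a conserved linear combination of species
#' concentrations along every trajectory (e.g. a constant total population).
#'
#' @param S integer stoichiometric matrix (from [stoichiometric_matrix()]), or
#'   a [reaction_network()].
#' @return List of integer vectors (possibly empty) satisfying
#'   `t(c) %*% S == 0` exactly.
#' @export
conservation_laws <- function(S) {
  if (inherits(S, "reaction_network")) S <- stoichiometric_matrix(S)
  k <- nrow(S)
  if (k == 0L) return(list())
  if (ncol(S) == 0L) {
    basis <- lapply(seq_len(k), function(i) as.integer(seq_len(k) == i))
    names(basis) <- NULL
    return(basis)
  }
  A <- t(S) # null space of A gives left null space of S
  A <- matrix(as.numeric(A), nrow(A), ncol(A))
  m <- nrow(A)
  # Gauss-Jordan with exact arithmetic: entries stay rational; since inputs are
  # integers and pivots are divided out, represent rows as numerators over a
  # common denominator to stay exact.
  num <- A
  den <- matrix(1, m, k)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(k)) {
    if (row > m) break
    sel <- which(abs(num[row:m, col]) > 0)
    if (length(sel) == 0L) next
    piv <- row + sel[1] - 1L
    if (piv != row) {
      num[c(row, piv), ] <- num[c(piv, row), ]
      den[c(row, piv), ] <- den[c(piv, row), ]
    }
    # normalize pivot row to leading 1 (rational)
    pn <- num[row, col]; pd <- den[row, col]
    for (cc in seq_len(k)) {
      num[row, cc] <- num[row, cc] * pd
      den[row, cc] <- den[row, cc] * pn
      g <- rational_gcd(num[row, cc], den[row, cc])
      if (g > 1) { num[row, cc] <- num[row, cc] / g; den[row, cc] <- den[row, cc] / g }
      if (den[row, cc] < 0) { num[row, cc] <- -num[row, cc]; den[row, cc] <- -den[row, cc] }
    }
    for (r in seq_len(m)) {
      if (r == row || num[r, col] == 0) next
      fn <- num[r, col]; fd <- den[r, col]
      for (cc in seq_len(k)) {
        # row_r <- row_r - (fn/fd) * row_row
        a_n <- num[r, cc] * fd * den[row, cc] - fn * num[row, cc] * den[r, cc]
        a_d <- den[r, cc] * fd * den[row, cc]
        g <- rational_gcd(a_n, a_d)
        if (g > 1) { a_n <- a_n / g; a_d <- a_d / g }
        if (a_d < 0) { a_n <- -a_n; a_d <- -a_d }
        num[r, cc] <- a_n; den[r, cc] <- a_d
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(k), pivots)
  basis <- lapply(free, function(fc) {
    v_n <- numeric(k); v_d <- rep(1, k)
    v_n[fc] <- 1
    for (i in seq_along(pivots)) {
      v_n[pivots[i]] <- -num[i, fc]
      v_d[pivots[i]] <- den[i, fc]
    }
    # integer scaling: multiply by lcm of denominators
    L <- 1
    for (d in v_d) L <- L * d / rational_gcd(L, d)
    v <- v_n * (L / v_d)
    g <- 0
    for (e in v) g <- rational_gcd(g, e)
    if (g > 1) v <- v / g
    as.integer(round(v))
  })
  names(basis) <- NULL
  basis
}

rational_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}
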