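# Time-reversible substitution models: LG (amino acid), GTR and JC
# (nucleotide), with discrete-gamma rate variation (+G), invariant sites
# (+I) and empirical frequencies (+F).

#' Specify a substitution model
#'
#' Models are specified by a string such as `"LG+G4+I+F"`, `"GTR+G4"` or
#' `"JC"`: a base matrix (`LG` or `POISSON` for amino acids, `GTR` or `JC`
#' for nucleotides), optionally `+G<k>` for k
#' discrete-gamma categories (default k = 4 when the count is omitted), `+I`
#' for a proportion of invariant sites and `+F` for empirical (counted)
#' equilibrium frequencies. Parameter values (`alpha`, `p_inv`, GTR
#' exchangeabilities) may be fixed here; if left `NA` they must be estimated
#' with [fit_model_parameters()] before likelihoods can be computed.
#'
#' The LG exchangeabilities and frequencies are taken from phangorn's shipped
#' model tables. A user-supplied PAML-layout `.dat` file can be used instead
#' via `exchangeabilities = parse_paml_dat(file)`.
#'
#' @param spec Model string, e.g. `"LG+G4+I+F"`.
#' @param alpha Gamma shape (> 0), or `NA` to estimate.
#' @param p_inv Proportion of invariant sites in `[0, 1)`, or `NA` to
#'   estimate.
#' @param gtr_rates Six GTR exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT (last fixed to 1 during estimation), or `NA` to estimate.
#' @param frequencies Explicit equilibrium frequencies (overrides both model
#'   defaults and `+F`).
#' @param exchangeabilities Optional list with elements `S` (symmetric
#'   matrix, zero diagonal) and `freqs`, as returned by [parse_paml_dat()].
#' @return An object of class `"subst_model"`.
#' @examples
#' subst_model("JC")
#' subst_model("LG+G4+F", alpha = 0.8)
#' @export
subst_model <- function(spec, alpha = NA_real_, p_inv = NA_real_,
                        gtr_rates = NULL, frequencies = NULL,
                        exchangeabilities = NULL) {
  parts <- strsplit(toupper(spec), "+", fixed = TRUE)[[1]]
  base <- parts[1]
  flags <- parts[-1]
  if (!base %in% c("LG", "POISSON", "GTR", "JC"))
    stop("unknown base model '", base, "' (expected LG, POISSON, GTR or JC)")
  gamma <- grepl("^G[0-9]*$", flags)
  if (sum(gamma) > 1 || sum(flags == "I") > 1 || sum(flags == "F") > 1)
    stop("duplicated model flag in '", spec, "'")
  bad <- flags[!(gamma | flags %in% c("I", "F"))]
  if (length(bad)) stop("unknown model flag(s): ", paste(bad, collapse = ", "))
  k <- 1L
  if (any(gamma)) {
    kstr <- sub("^G", "", flags[gamma][1])
    k <- if (nzchar(kstr)) as.integer(kstr) else 4L
    if (is.na(k) || k < 1) stop("invalid gamma category count in '", spec, "'")
  }
  has_g <- any(gamma)
  has_i <- "I" %in% flags
  has_f <- "F" %in% flags
  alphabet <- if (base %in% c("LG", "POISSON")) "aa" else "nt"
  ns <- length(alphabet_states(alphabet))

  if (base == "LG") {
    lg <- if (is.null(exchangeabilities)) lg_model_data() else exchangeabilities
    S <- lg$S
    def_freqs <- lg$freqs
  } else if (base == "POISSON") {
    S <- matrix(1, ns, ns); diag(S) <- 0
    def_freqs <- rep(1 / ns, ns)
  } else if (base == "JC") {
    S <- matrix(1, ns, ns); diag(S) <- 0
    def_freqs <- rep(1 / ns, ns)
    if (has_f) stop("JC has fixed equal frequencies; +F is not available")
  } else { # GTR
    S <- matrix(0, ns, ns)
    if (is.null(gtr_rates)) gtr_rates <- rep(NA_real_, 6)
    if (length(gtr_rates) != 6) stop("gtr_rates must have length 6")
    rates_use <- if (anyNA(gtr_rates)) rep(1, 6) else gtr_rates
    S[lower.tri(S)] <- rates_use[c(1, 2, 3, 4, 5, 6)]
    S <- S + t(S)
    def_freqs <- rep(1 / ns, ns)
  }
  dimnames(S) <- list(alphabet_states(alphabet), alphabet_states(alphabet))

  if (!is.null(frequencies)) {
    if (length(frequencies) != ns || abs(sum(frequencies) - 1) > 1e-8)
      stop("frequencies must be a length-", ns, " simplex vector")
    freqs <- frequencies / sum(frequencies)
    freqs_mode <- "given"
  } else if (has_f) {
    freqs <- NULL
    freqs_mode <- "empirical"
  } else {
    freqs <- def_freqs
    freqs_mode <- "model"
  }
  if (!is.na(alpha) && alpha <= 0) stop("alpha must be > 0")
  if (!is.na(p_inv) && (p_inv < 0 || p_inv >= 1)) stop("p_inv must be in [0, 1)")
  structure(list(
    name = spec, base = base, alphabet = alphabet,
    S = S, freqs = freqs, freqs_mode = freqs_mode,
    has_gamma = has_g, k = if (has_g) k else 1L, alpha = alpha,
    has_inv = has_i, p_inv = if (has_i) p_inv else 0,
    gtr_rates = if (base == "GTR") gtr_rates else NULL
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model>", x$name, sprintf("(%s)\n", x$alphabet))
  if (x$has_gamma)
    cat("  gamma: k =", x$k, "alpha =",
        if (is.na(x$alpha)) "(to estimate)" else format(x$alpha), "\n")
  if (x$has_inv)
    cat("  p_inv:", if (is.na(x$p_inv)) "(to estimate)" else format(x$p_inv), "\n")
  cat("  frequencies:", x$freqs_mode, "\n")
  invisible(x)
}

# LG exchangeabilities + frequencies, sourced from phangorn's shipped model
# tables (PAML state order ARNDCQEGHILKMFPSTWYV).
lg_model_data <- function() {
  lg <- get(".LG", envir = environment(phangorn::pml))
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- lg$Q
  S <- S + t(S)
  dimnames(S) <- list(AA_STATES, AA_STATES)
  freqs <- as.numeric(lg$bf)
  freqs <- freqs / sum(freqs)
  list(S = S, freqs = freqs)
}

#' Parse a PAML-layout amino-acid model file
#'
#' Reads the standard `.dat` layout used by PAML/CodeML for empirical
#' amino-acid models: 190 lower-triangle exchangeabilities (rows 2..20)
#' followed by 20 equilibrium frequencies.
#'
#' @param file Path to a `.dat` file.
#' @return A list with elements `S` (20 x 20 symmetric exchangeability
#'   matrix) and `freqs`.
#' @export
parse_paml_dat <- function(file) {
  vals <- scan(file, what = numeric(), comment.char = "#", quiet = TRUE)
  if (length(vals) < 210)
    stop("expected at least 210 numbers (190 exchangeabilities + 20 frequencies)")
  S <- matrix(0, 20, 20)
  idx <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {     # row-wise lower triangle
    S[i, j] <- vals[idx]; idx <- idx + 1L
  }
  S <- S + t(S)
  dimnames(S) <- list(AA_STATES, AA_STATES)
  freqs <- vals[idx:(idx + 19)]
  list(S = S, freqs = freqs / sum(freqs))
}

#' Build a scaled rate matrix
#'
#' Constructs Q with off-diagonal entries \eqn{Q_{ij} = S_{ij} \pi_j},
#' diagonal set to minus the row sum, rescaled so the expected substitution
#' rate at equilibrium is 1 per site (before any gamma/invariant-site
#' adjustment). The symmetric eigendecomposition (via the
#' \eqn{\sqrt{\pi}}-similarity transform) is cached for fast transition
#' probabilities.
#'
#' @param model A [subst_model()]; its frequencies must be resolved (pass
#'   `freqs` for `+F` models).
#' @param freqs Optional frequency vector overriding the model's.
#' @return An object of class `"rate_matrix"` with elements `Q`, `pi`,
#'   `states`, and eigendecomposition components `V`, `W`, `lambda` such that
#'   \eqn{P(t) = V e^{\Lambda t} W}.
#' @export
build_rate_matrix <- function(model, freqs = NULL) {
  stopifnot(inherits(model, "subst_model"))
  pi <- if (!is.null(freqs)) freqs else model$freqs
  if (is.null(pi))
    stop("model uses empirical frequencies (+F); supply freqs= or resolve ",
         "the model against an alignment first")
  S <- model$S
  if (max(abs(S - t(S))) > 1e-12) stop("exchangeability matrix is not symmetric")
  if (any(pi <= 0) && any(S[pi <= 0, ] > 0))
    stop("zero equilibrium frequency with nonzero exchangeability")
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = nrow(S))      # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))              # expected rate at equilibrium
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))            # diag(sq) Q diag(1/sq), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  V <- e$vectors / sq                   # diag(1/sq) %*% U
  W <- t(e$vectors * sq)                # t(U) %*% diag(sq) ... note below
  # careful: t(diag(sq) %*% U) = t(U) %*% diag(sq); e$vectors * sq scales rows
  structure(list(Q = Q, pi = pi, states = rownames(S),
                 V = V, W = W, lambda = e$values),
            class = "rate_matrix")
}

#' Transition probability matrix
#'
#' \eqn{P = \exp(Q t r)} computed from the cached symmetric
#' eigendecomposition. Rows sum to 1 within 1e-12; tiny negative entries from
#' round-off are clipped to 0.
#'
#' @param rm A `"rate_matrix"` from [build_rate_matrix()].
#' @param t Branch length (expected substitutions/site), `>= 0`.
#' @param rate Rate-category multiplier.
#' @return A stochastic matrix.
#' @export
transition_probabilities <- function(rm, t, rate = 1) {
  stopifnot(inherits(rm, "rate_matrix"))
  if (t < 0) stop("branch length must be >= 0")
  P <- rm$V %*% (exp(rm$lambda * t * rate) * rm$W)
  P[P < 0] <- 0
  dimnames(P) <- list(rm$states, rm$states)
  P
}

#' Discrete-gamma rate categories
#'
#' k equal-probability categories whose rates are the conditional means of a
#' Gamma(shape = alpha, rate = alpha) density over its equiprobable quantile
#' bins (mean-of-bin discretization, overall mean exactly 1). With
#' `p_inv > 0` an invariant category of rate 0 and weight `p_inv` is
#' prepended and the gamma rates are rescaled by `1/(1 - p_inv)` so the
#' weighted mean rate stays 1.
#'
#' @param alpha Gamma shape, > 0.
#' @param k Number of gamma categories, >= 1.
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return A list of class `"rate_categories"`: `rates`, `weights`.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k, p_inv = 0) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.numeric(k) || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  k <- as.integer(k)
  if (k == 1L) {
    rates <- 1
  } else {
    b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
    # E[X | bin] * k  using the incomplete-gamma identity
    # E[X 1{X <= q}] = pgamma(q, alpha + 1, rate = alpha) for Gamma(alpha, alpha)
    rates <- k * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  }
  rates <- rates / sum(rates / k)   # pin mean at exactly 1 against round-off
  if (p_inv > 0) {
    structure(list(rates = c(0, rates / (1 - p_inv)),
                   weights = c(p_inv, rep((1 - p_inv) / k, k))),
              class = "rate_categories")
  } else {
    structure(list(rates = rates, weights = rep(1 / k, k)),
              class = "rate_categories")
  }
}

#' Empirical equilibrium frequencies (+F)
#'
#' Observed state proportions over all non-gap, non-missing residues.
#' Zero-count states are floored at 1e-6 and the vector renormalized, which
#' keeps the rate matrix irreducible on short alignments.
#'
#' @param aln An [alignment()].
#' @param floor Minimum frequency for unobserved states.
#' @return A named frequency vector summing to 1.
#' @export
empirical_frequencies <- function(aln, floor = 1e-6) {
  stopifnot(inherits(aln, "lca_alignment"))
  codes <- alignment_codes(aln)
  st <- alphabet_states(aln$alphabet)
  counts <- tabulate(codes[codes > 0], nbins = length(st))
  if (sum(counts) == 0) stop("alignment contains only gap/missing characters")
  f <- counts / sum(counts)
  f[f < floor] <- floor
  setNames(f / sum(f), st)
}

# --- internal: concrete (fully numeric) model ready for the engine ---------

# Resolve a subst_model against an alignment: fill +F frequencies, require
# numeric alpha/p_inv, build Q + eigendecomposition and rate categories.
resolve_model <- function(model, aln = NULL) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.null(aln) && model$alphabet != aln$alphabet)
    stop("model alphabet (", model$alphabet, ") does not match alignment (",
         aln$alphabet, ")")
  freqs <- model$freqs
  if (model$freqs_mode == "empirical") {
    if (is.null(aln))
      stop("+F model needs an alignment to compute empirical frequencies")
    freqs <- empirical_frequencies(aln)
  }
  if (model$has_gamma && is.na(model$alpha))
    stop("gamma shape alpha is unset; fix it in subst_model() or estimate ",
         "it with fit_model_parameters()")
  p_inv <- model$p_inv
  if (model$has_inv && is.na(p_inv))
    stop("p_inv is unset; fix it in subst_model() or estimate it with ",
         "fit_model_parameters()")
  if (model$base == "GTR" && anyNA(model$gtr_rates)) {
    # unestimated GTR exchangeabilities default to 1 (F81-like); they are
    # free parameters for fit_model_parameters()
    model$S[] <- 1; diag(model$S) <- 0
  }
  rm <- build_rate_matrix(model, freqs = freqs)
  alpha <- if (model$has_gamma) model$alpha else NA_real_
  gr <- if (model$has_gamma) discrete_gamma_rates(alpha, model$k)$rates else 1
  # gamma rates rescaled for the invariant fraction; weights sum to 1 - p_inv
  rates <- gr / (1 - p_inv)
  weights <- rep((1 - p_inv) / length(gr), length(gr))
  list(model = model, rm = rm, pi = rm$pi, alpha = alpha, p_inv = p_inv,
       rates = rates, weights = weights)
}

# Number of free model parameters for AIC (branch lengths counted separately).
n_model_params <- function(model) {
  ns <- length(alphabet_states(model$alphabet))
  k <- 0L
  if (model$has_gamma) k <- k + 1L
  if (model$has_inv) k <- k + 1L
  if (model$freqs_mode == "empirical") k <- k + ns - 1L
  if (model$base == "GTR") k <- k + 5L
  k
}
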