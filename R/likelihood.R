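# Likelihood computation and optimization on trees, built on the C++
# pruning engine. Alignments are compressed to unique site patterns first.

# --- pattern compression ----------------------------------------------------

compress_patterns <- function(aln, tip_order) {
  codes <- alignment_codes(aln)[tip_order, , drop = FALSE]
  if (ncol(codes) == 0L) stop("alignment has zero columns")
  keys <- apply(codes, 2, paste, collapse = ",")
  ord <- match(keys, unique(keys))
  upat <- !duplicated(keys)
  pat <- codes[, upat, drop = FALSE]
  w <- as.numeric(tabulate(ord, nbins = max(ord)))
  cs <- apply(pat, 2, function(col) {
    nz <- unique(col[col > 0])
    if (length(nz) == 0L) -1L else if (length(nz) == 1L) nz else 0L
  })
  list(pat = pat, w = w, site_of = ord, cs = as.integer(cs))
}

# --- engine glue ------------------------------------------------------------

# Package a phylo tree + alignment + concrete model for the C++ engine.
# `cp` may carry a compression precomputed in the *alignment's* taxon order
# (one search evaluates many topologies over the same data).
engine_data <- function(tree, aln, cm, cp = NULL) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!setequal(tree$tip.label, taxa(aln)))
    stop("tree tip labels and alignment taxa differ: {",
         paste(setdiff(tree$tip.label, taxa(aln)), collapse = ","), "} vs {",
         paste(setdiff(taxa(aln), tree$tip.label), collapse = ","), "}")
  tre <- ape::reorder.phylo(tree, "postorder")
  if (is.null(cp)) cp <- compress_patterns(aln, taxa(aln))
  cp$pat <- cp$pat[match(tre$tip.label, taxa(aln)), , drop = FALSE]
  list(tree = tre, cp = cp,
       args = list(edge = tre$edge, lens = tre$edge.length,
                   nnode = length(tre$tip.label) + tre$Nnode,
                   ntip = length(tre$tip.label),
                   tip = cp$pat, w = cp$w,
                   V = cm$rm$V, W = cm$rm$W, lam = cm$rm$lambda,
                   pi = cm$pi, rates = cm$rates, rw = cm$weights,
                   pinv = cm$p_inv, cs = cp$cs))
}

default_optim_control <- function(...) {
  ctrl <- list(min_len = 1e-8, max_len = 20, tol = 1e-6, max_passes = 50,
               brent_tol = 1e-5, brent_maxit = 50)
  override <- list(...)
  ctrl[names(override)] <- override
  ctrl
}

make_fit <- function(tree, aln, model, cm, loglik, site_pat, site_of,
                     converged = TRUE, passes = NA_integer_) {
  df_model <- n_model_params(model)
  structure(list(
    logLik = loglik,
    site_loglik = site_pat[site_of],
    tree = tree, model = model,
    alpha = cm$alpha, p_inv = cm$p_inv, freqs = cm$pi,
    df = df_model + nrow(tree$edge),
    df_model = df_model,
    converged = converged, passes = passes
  ), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<ml fit> model %s  lnL = %.4f  (df = %d)\n",
              x$model$name, x$logLik, x$df))
  if (x$model$has_gamma) cat("  alpha =", format(x$alpha, digits = 4), "\n")
  if (x$model$has_inv) cat("  p_inv =", format(x$p_inv, digits = 4), "\n")
  invisible(x)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a tree under a concrete
#' substitution model, summing over discrete-gamma rate categories and an
#' optional invariant-sites category (a site can contribute invariant-class
#' likelihood only if its observed states are compatible with a single
#' state). Gap/missing characters are treated as missing data (partial
#' likelihood of one at the tip). Per-node log-scaling prevents underflow on
#' long concatenates.
#'
#' The tree may be rooted, unrooted (basal multifurcation) or a star tree;
#' under a time-reversible model the likelihood does not depend on where the
#' virtual root sits (the pulley principle).
#'
#' @param tree A `phylo` tree with branch lengths; tip labels must match the
#'   alignment's taxa.
#' @param aln An [alignment()].
#' @param model A [subst_model()] with all parameters fixed (`+F`
#'   frequencies are resolved against `aln`).
#' @return An object of class `"lca_fit"`: `logLik`, per-site `site_loglik`,
#'   the `tree`, parameter values and the free-parameter count `df`.
#' @export
log_likelihood <- function(tree, aln, model) {
  cm <- resolve_model(model, aln)
  ed <- engine_data(tree, aln, cm)
  res <- do.call(eng_loglik, ed$args)
  if (!is.finite(res$loglik))
    warning("log-likelihood is -Inf (data impossible under this tree/model)")
  make_fit(tree, aln, model, cm, res$loglik, res$site, ed$cp$site_of)
}

#' Optimize branch lengths by coordinate-wise line search
#'
#' Each edge in turn is optimized by bounded Brent search (default bounds
#' `[1e-8, 20]` expected substitutions/site) with all other edges fixed,
#' cycling until the log-likelihood gain in a full pass drops below `tol` or
#' `max_passes` is reached. Accepted steps never decrease the
#' log-likelihood; the traversal order (postorder by node id) makes the
#' result deterministic.
#'
#' @inheritParams log_likelihood
#' @param ... Control overrides: `min_len`, `max_len`, `tol` (default 1e-6),
#'   `max_passes` (default 50), `brent_tol`, `brent_maxit`.
#' @return A list: `tree` (with optimized lengths) and `fit` (an
#'   `"lca_fit"`; `fit$converged` is `FALSE` if the pass cap was hit).
#' @export
optimize_branch_lengths <- function(tree, aln, model, ...) {
  ctrl <- default_optim_control(...)
  cm <- resolve_model(model, aln)
  ed <- engine_data(tree, aln, cm)
  res <- do.call(eng_optim_bl, c(ed$args, ctrl))
  tre <- ed$tree
  tre$edge.length <- res$lens
  fit <- make_fit(tre, aln, model, cm, res$loglik, res$site, ed$cp$site_of,
                  converged = res$converged, passes = res$passes)
  if (!res$converged)
    warning("branch-length optimization hit the pass cap (maxiter); ",
            "returning best-so-far")
  list(tree = tre, fit = fit)
}

# internal: lnL with fixed branch lengths under modified model parameters
loglik_given <- function(ed, cm) {
  args <- ed$args
  args$V <- cm$rm$V; args$W <- cm$rm$W; args$lam <- cm$rm$lambda
  args$pi <- cm$pi; args$rates <- cm$rates; args$rw <- cm$weights
  args$pinv <- cm$p_inv
  do.call(eng_loglik, args)$loglik
}

# rebuild the concrete-model pieces after changing alpha/p_inv/GTR rates
update_cm <- function(cm, alpha = NULL, p_inv = NULL, gtr = NULL) {
  model <- cm$model
  if (!is.null(alpha)) { model$alpha <- alpha; cm$alpha <- alpha }
  if (!is.null(p_inv)) { model$p_inv <- p_inv; cm$p_inv <- p_inv }
  if (!is.null(gtr)) {
    model$gtr_rates <- gtr
    S <- matrix(0, 4, 4); S[lower.tri(S)] <- gtr; S <- S + t(S)
    dimnames(S) <- dimnames(model$S)
    model$S <- S
    cm$rm <- build_rate_matrix(model, freqs = cm$pi)
  }
  gr <- if (model$has_gamma) discrete_gamma_rates(cm$alpha, model$k)$rates else 1
  cm$rates <- gr / (1 - cm$p_inv)
  cm$weights <- rep((1 - cm$p_inv) / length(gr), length(gr))
  cm$model <- model
  cm
}

#' Fit free model parameters (and branch lengths)
#'
#' Interleaves branch-length optimization with one-dimensional fits of the
#' gamma shape (bounded to `[0.02, 100]`, searched on the log scale) and the
#' invariant-sites proportion (`[0, 0.99]`), and, for GTR, a multivariate
#' quasi-Newton fit of the five free exchangeabilities (log scale, GT fixed
#' at 1). Rounds repeat until the round-to-round log-likelihood gain falls
#' below `tol` or `max_rounds` is reached.
#'
#' @inheritParams log_likelihood
#' @param free Character vector naming the parameters to estimate, a subset
#'   of `c("alpha", "p_inv", "gtr")`. Defaults to every parameter the model
#'   declares but does not fix (`NA` values in [subst_model()]).
#' @param optimize_edges Also optimize branch lengths (default `TRUE`).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_rounds Maximum outer rounds.
#' @param ... Branch-length control overrides, see
#'   [optimize_branch_lengths()].
#' @return A list: `tree`, `fit` (an `"lca_fit"` with fitted `alpha`,
#'   `p_inv`, GTR rates recorded in `fit$model`).
#' @export
fit_model_parameters <- function(tree, aln, model, free = NULL,
                                 optimize_edges = TRUE, tol = 1e-4,
                                 max_rounds = 5, ...) {
  if (is.null(free)) {
    free <- character(0)
    if (model$has_gamma && is.na(model$alpha)) free <- c(free, "alpha")
    if (model$has_inv && is.na(model$p_inv)) free <- c(free, "p_inv")
    if (model$base == "GTR" && anyNA(model$gtr_rates)) free <- c(free, "gtr")
  }
  bad <- setdiff(free, c("alpha", "p_inv", "gtr"))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  if ("alpha" %in% free && !model$has_gamma)
    stop("alpha is only free for +G models")
  if ("p_inv" %in% free && !model$has_inv)
    stop("p_inv is only free for +I models")
  if ("gtr" %in% free && model$base != "GTR")
    stop("gtr exchangeabilities are only free for GTR models")

  # starting values
  if (model$has_gamma && is.na(model$alpha)) model$alpha <- 1
  if (model$has_inv && is.na(model$p_inv)) model$p_inv <- 0.1
  if (model$base == "GTR" && anyNA(model$gtr_rates)) model$gtr_rates <- rep(1, 6)
  cm <- resolve_model(model, aln)
  ctrl <- default_optim_control(...)
  ed <- engine_data(tree, aln, cm)
  cur <- loglik_given(ed, cm)

  for (round in seq_len(max_rounds)) {
    before <- cur
    if (optimize_edges) {
      args <- ed$args
      args$V <- cm$rm$V; args$W <- cm$rm$W; args$lam <- cm$rm$lambda
      args$pi <- cm$pi; args$rates <- cm$rates; args$rw <- cm$weights
      args$pinv <- cm$p_inv
      res <- do.call(eng_optim_bl, c(args, ctrl))
      ed$args$lens <- res$lens
      cur <- res$loglik
    }
    if ("alpha" %in% free) {
      op <- optimize(function(la) {
        loglik_given(ed, update_cm(cm, alpha = exp(la)))
      }, lower = log(0.02), upper = log(100), maximum = TRUE, tol = 1e-4)
      cm <- update_cm(cm, alpha = exp(op$maximum))
      cur <- op$objective
    }
    if ("p_inv" %in% free) {
      op <- optimize(function(p) {
        loglik_given(ed, update_cm(cm, p_inv = p))
      }, lower = 0, upper = 0.99, maximum = TRUE, tol = 1e-5)
      if (op$objective > cur) {
        cm <- update_cm(cm, p_inv = op$maximum)
        cur <- op$objective
      }
    }
    if ("gtr" %in% free) {
      start <- log(pmax(cm$model$gtr_rates[1:5], 1e-4))
      op <- optim(start, function(lr) {
        -loglik_given(ed, update_cm(cm, gtr = c(exp(lr), 1)))
      }, method = "L-BFGS-B", lower = rep(-7, 5), upper = rep(7, 5),
      control = list(maxit = 50))
      if (-op$value > cur) {
        cm <- update_cm(cm, gtr = c(exp(op$par), 1))
        cur <- -op$value
      }
    }
    if (cur - before < tol && round > 1) break
  }
  tre <- ed$tree
  tre$edge.length <- ed$args$lens
  args <- ed$args
  args$V <- cm$rm$V; args$W <- cm$rm$W; args$lam <- cm$rm$lambda
  args$pi <- cm$pi; args$rates <- cm$rates; args$rw <- cm$weights
  args$pinv <- cm$p_inv
  res <- do.call(eng_loglik, args)
  fit <- make_fit(tre, aln, cm$model, cm, res$loglik, res$site, ed$cp$site_of)
  list(tree = tre, fit = fit, cm = cm)
}

#' Rank substitution models by AIC
#'
#' Fits each candidate model on the same tree (branch lengths and free
#' parameters optimized per candidate) and ranks by
#' \eqn{AIC = 2k - 2\,lnL}, where k counts free model parameters plus free
#' branch lengths. Ties are broken in favour of fewer parameters.
#'
#' @param aln An [alignment()].
#' @param tree A `phylo` tree with starting branch lengths.
#' @param models A list of [subst_model()] objects or model strings.
#' @param ... Passed to [fit_model_parameters()].
#' @return A data frame ranked by AIC: `model`, `logLik`, `k`, `AIC`,
#'   `delta_AIC`.
#' @export
aic_select <- function(aln, tree, models, ...) {
  if (length(models) < 2) stop("need at least 2 candidate models")
  models <- lapply(models, function(m) {
    if (inherits(m, "subst_model")) m else subst_model(m)
  })
  rows <- lapply(models, function(m) {
    ft <- fit_model_parameters(tree, aln, m, ...)
    k <- ft$fit$df
    data.frame(model = m$name, logLik = ft$fit$logLik, k = k,
               AIC = 2 * k - 2 * ft$fit$logLik, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, tab$k), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}

#' Write per-site log-likelihoods as TSV
#'
#' @param fit An `"lca_fit"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_site_loglik <- function(fit, file) {
  write.table(data.frame(site = seq_along(fit$site_loglik),
                         loglik = fit$site_loglik),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
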