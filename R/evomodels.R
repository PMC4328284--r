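# Maximum-likelihood Brownian-motion and multi-optima Ornstein-Uhlenbeck
# (Hansen) model fits on a time tree, and AIC comparison of painted regime
# hypotheses.
#
# Traits (PC scores) are fitted independently, with log-likelihoods and
# parameter counts summed across traits: scores from a PCA are orthogonal by
# construction and the per-trait profile keeps the optimization
# one-dimensional in alpha.

# Match a species x m score matrix against tree tips (exact set match).
check_scores_tree <- function(scores, tree) {
  sp <- rownames(scores)
  if (!setequal(sp, tree$tip.label)) {
    missing_tree <- setdiff(sp, tree$tip.label)
    missing_scores <- setdiff(tree$tip.label, sp)
    abort(paste0(
      "species mismatch between scores and tree",
      if (length(missing_tree)) paste0("; not in tree: ",
                                       paste(missing_tree, collapse = ", ")),
      if (length(missing_scores)) paste0("; not in scores: ",
                                         paste(missing_scores, collapse = ", "))))
  }
  scores[tree$tip.label, , drop = FALSE]
}

new_model_fit <- function(hypothesis, params, logLik, n_params, converged,
                          details = list()) {
  structure(
    list(hypothesis = hypothesis, params = params, logLik = logLik,
         n_params = n_params, AIC = 2 * n_params - 2 * logLik,
         converged = converged, details = details),
    class = "evo_model_fit")
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat(sprintf("<evo_model_fit> %s: logLik = %.3f, K = %d, AIC = %.3f%s\n",
              x$hypothesis, x$logLik, x$n_params, x$AIC,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
tidy.evo_model_fit <- function(x, ...) x$params

#' @export
glance.evo_model_fit <- function(x, ...) {
  tibble(hypothesis = x$hypothesis, logLik = x$logLik, n_params = x$n_params,
         AIC = x$AIC, converged = x$converged)
}

#' Fit Brownian motion by maximum likelihood
#'
#' Per trait, the root state is the generalized-least-squares mean under the
#' BM covariance ([bm_vcv()]) and `sigma2` has the closed-form ML solution
#' (quadratic form divided by n). Works on non-ultrametric trees.
#'
#' @param tree A `phylo` object.
#' @param scores Species x m trait/score matrix (rownames = tip labels) or a
#'   data frame with a `species_id` column.
#' @return An `evo_model_fit` (hypothesis `"BM"`, `K = 2m`).
#' @export
fit_bm <- function(tree, scores) {
  y_all <- check_scores_tree(as_trait_matrix(scores), tree)
  C <- bm_vcv(tree)
  ch <- tryCatch(chol(C), error = function(e) {
    abort("singular BM covariance (duplicate or zero-length tips?)")
  })
  n <- nrow(y_all)
  logdetC <- 2 * sum(log(diag(ch)))
  one <- rep(1, n)
  Cinv_one <- backsolve(ch, forwardsolve(t(ch), one))
  denom <- sum(one * Cinv_one)
  params <- purrr::map(seq_len(ncol(y_all)), function(j) {
    y <- y_all[, j]
    root <- sum(y * Cinv_one) / denom
    r <- y - root
    Cinv_r <- backsolve(ch, forwardsolve(t(ch), r))
    q <- sum(r * Cinv_r)
    sigma2 <- q / n
    ll <- if (sigma2 <= 0) {
      # Degenerate data (all tips equal): report the boundary.
      Inf
    } else {
      -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdetC / 2 - n / 2
    }
    tibble(trait = colnames(y_all)[j] %||% paste0("trait", j),
           regime = NA_character_, sigma2 = sigma2, alpha = NA_real_,
           theta = NA_real_, root_state = root, logLik = ll)
  })
  params <- list_rbind(params)
  boundary <- !is.finite(params$logLik)
  if (any(boundary)) {
    warn(paste0("sigma2 at zero boundary for trait(s): ",
                paste(params$trait[boundary], collapse = ", ")))
  }
  new_model_fit("BM", params, sum(params$logLik[!boundary]),
                2L * ncol(y_all), converged = TRUE,
                details = list(boundary_traits = params$trait[boundary]))
}

# Root-to-tip path decomposition: per tip, the branches on its path with
# parent/child depths and regimes.
tip_paths <- function(tree, painting) {
  depths <- node_depths(tree)
  n_tip <- length(tree$tip.label)
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  regime_of <- character(n_tip + tree$Nnode)
  regime_of[painting$child] <- painting$regime
  root <- n_tip + 1L
  lapply(seq_len(n_tip), function(tip) {
    node <- tip
    segs <- list()
    while (node != root) {
      segs[[length(segs) + 1]] <- c(start = unname(depths[parent_of[node]]),
                                    end = unname(depths[node]))
      names(segs)[length(segs)] <- regime_of[node]
      node <- parent_of[node]
    }
    segs
  })
}

# Hansen weight matrix: expected tip value = W(alpha) %*% theta, with the
# root state conditioned at the root regime's optimum.
hansen_weights <- function(alpha, paths, tip_depths, regimes, root_reg) {
  n <- length(paths)
  W <- matrix(0, n, length(regimes), dimnames = list(NULL, regimes))
  for (i in seq_len(n)) {
    Ti <- tip_depths[i]
    W[i, root_reg] <- exp(-alpha * Ti)
    for (k in seq_along(paths[[i]])) {
      seg <- paths[[i]][[k]]
      reg <- names(paths[[i]])[k]
      W[i, reg] <- W[i, reg] +
        exp(-alpha * (Ti - seg["end"])) - exp(-alpha * (Ti - seg["start"]))
    }
  }
  W
}

# OU tip correlation structure (sigma2 factored out), valid for
# non-ultrametric trees: (1/(2 alpha)) e^{-alpha(d_i + d_j - 2 d_a)}
# (1 - e^{-2 alpha d_a}) with d_a the MRCA depth.
ou_vcv0 <- function(alpha, mrca_depths, tip_depths) {
  dsum <- outer(tip_depths, tip_depths, "+")
  exp(-alpha * (dsum - 2 * mrca_depths)) *
    (-expm1(-2 * alpha * mrca_depths)) / (2 * alpha)
}

# Profile log-likelihood of one trait at a given alpha; returns the profiled
# theta vector, sigma2 and logLik.
ou_profile <- function(alpha, y, W_fun, V0_fun) {
  n <- length(y)
  V0 <- V0_fun(alpha)
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(list(logLik = -Inf))
  W <- W_fun(alpha)
  solve_v <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  WtVi <- crossprod(W, solve_v(W))
  theta <- tryCatch(
    solve(WtVi, crossprod(W, solve_v(y))),
    error = function(e) qr.solve(WtVi, crossprod(W, solve_v(y)), tol = 1e-12))
  r <- y - as.numeric(W %*% theta)
  q <- sum(r * solve_v(r))
  sigma2 <- q / n
  if (sigma2 <= 0) return(list(logLik = -Inf))
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(sigma2) -
    sum(log(diag(ch))) - n / 2
  list(logLik = ll, theta = as.numeric(theta), sigma2 = sigma2)
}

#' Fit a fixed-painting multi-optima OU (Hansen) model
#'
#' Per trait: the expected tip value is a weighted sum of regime optima with
#' Hansen exponential weights accumulated along the root-to-tip path (the
#' root state is the root regime's optimum); tip covariances use the
#' non-ultrametric OU form. `alpha` is optimized per trait on a log-spaced
#' grid over `[1e-8, 50/tree height]` with local refinement (ties broken
#' toward smaller `alpha`); optima and `sigma2` are profiled in closed form
#' given `alpha`. In the `alpha -> 0` limit the fit coincides with BM plus a
#' free optimum.
#'
#' @param tree A `phylo` object.
#' @param scores Species x m trait/score matrix.
#' @param painting A [paint_regimes()] painting covering every branch.
#' @param alpha_grid_size Number of grid points for the alpha search.
#' @return An `evo_model_fit` with `K = m (2 + #regimes)`.
#' @export
fit_ou <- function(tree, scores, painting, alpha_grid_size = 30) {
  y_all <- check_scores_tree(as_trait_matrix(scores), tree)
  n <- nrow(y_all)
  regimes <- attr(painting, "regimes") %||% unique(painting$regime)
  root_reg <- root_regime(tree, painting)
  depths <- node_depths(tree)
  tip_depths <- depths[seq_len(n)]
  mrca_depths <- bm_vcv(tree)
  paths <- tip_paths(tree, painting)
  H <- max(tip_depths)
  W_fun <- function(a) hansen_weights(a, paths, tip_depths, regimes, root_reg)
  V0_fun <- function(a) ou_vcv0(a, mrca_depths, tip_depths)
  lo <- log(1e-8); hi <- log(50 / H)
  grid <- exp(seq(lo, hi, length.out = alpha_grid_size))

  fits <- purrr::map(seq_len(ncol(y_all)), function(j) {
    y <- y_all[, j]
    ll_grid <- vapply(grid, function(a) {
      ou_profile(a, y, W_fun, V0_fun)$logLik
    }, numeric(1))
    best <- which.max(ll_grid)  # first maximum: ties go to smaller alpha
    lo_b <- grid[max(1, best - 1)]
    hi_b <- grid[min(length(grid), best + 1)]
    opt <- stats::optimize(function(la) {
      ou_profile(exp(la), y, W_fun, V0_fun)$logLik
    }, interval = log(c(lo_b, hi_b)), maximum = TRUE, tol = 1e-8)
    alpha <- exp(opt$maximum)
    prof <- ou_profile(alpha, y, W_fun, V0_fun)
    if (ll_grid[best] > prof$logLik) {  # refinement must not lose the grid optimum
      alpha <- grid[best]
      prof <- ou_profile(alpha, y, W_fun, V0_fun)
    }
    at_bound <- best == length(grid)
    tibble(trait = colnames(y_all)[j] %||% paste0("trait", j),
           regime = regimes, sigma2 = prof$sigma2, alpha = alpha,
           theta = prof$theta, root_state = prof$theta[match(root_reg, regimes)],
           logLik = prof$logLik, alpha_at_bound = at_bound)
  })
  params <- list_rbind(fits)
  per_trait <- params[!duplicated(params$trait), ]
  if (any(per_trait$alpha_at_bound)) {
    warn(paste0("alpha driven to the upper search bound for trait(s): ",
                paste(per_trait$trait[per_trait$alpha_at_bound], collapse = ", ")))
  }
  converged <- all(is.finite(per_trait$logLik))
  hyp <- attr(painting, "hypothesis") %||% "OU"
  new_model_fit(hyp, params, sum(per_trait$logLik),
                as.integer(ncol(y_all) * (2 + length(regimes))),
                converged = converged,
                details = list(alpha_at_bound = any(per_trait$alpha_at_bound)))
}

#' Compare evolutionary hypotheses by AIC
#'
#' Fits BM and painted OU hypotheses on one or more topology variants and
#' tabulates AIC. Scores from a [tangent_pca()] are truncated to the leading
#' axes jointly reaching `pc_threshold` percent of variance (or to `n_pcs`
#' axes if given).
#'
#' @param scores A `shape_pca`, or a species x m matrix / tibble.
#' @param trees A named list of `phylo` topology variants (or a single tree).
#' @param clade_tips Tip labels of the focal clade (for shift hypotheses).
#' @param otter_tip Convergent terminal tip label (for
#'   `terrestrial_aquatic`).
#' @param hypotheses Hypotheses to fit.
#' @param pc_threshold Percent-variance threshold for PC truncation.
#' @param n_pcs Explicit number of leading PCs (overrides `pc_threshold`).
#' @return A tibble of class `model_comparison`: one row per topology x
#'   hypothesis with `logLik`, `n_params`, `AIC`, `delta_AIC` (within
#'   topology), `best`, `converged`. Fits that fail to converge are flagged,
#'   not dropped.
#' @export
compare_models <- function(scores, trees, clade_tips = NULL, otter_tip = NULL,
                           hypotheses = c("BM", "one_regime",
                                          "terrestrial_aquatic",
                                          "pinniped_radiation"),
                           pc_threshold = 95, n_pcs = NULL) {
  if (inherits(trees, "phylo")) trees <- list(tree = trees)
  if (is.null(names(trees))) names(trees) <- paste0("topology", seq_along(trees))
  if (inherits(scores, "shape_pca")) {
    keep <- n_pcs %||% n_axes_for_variance(scores, pc_threshold)
    mat <- scores$scores[, seq_len(min(keep, ncol(scores$scores))), drop = FALSE]
  } else {
    mat <- as_trait_matrix(scores)
    if (!is.null(n_pcs)) mat <- mat[, seq_len(min(n_pcs, ncol(mat))), drop = FALSE]
  }
  if (length(hypotheses) < 2) abort("compare_models() needs >= 2 hypotheses")
  rows <- purrr::imap(trees, function(tree, topo) {
    fits <- purrr::map(hypotheses, function(h) {
      fit <- if (h == "BM") {
        fit_bm(tree, mat)
      } else {
        fit_ou(tree, mat,
               paint_regimes(tree, h, clade_tips = clade_tips,
                             otter_tip = otter_tip))
      }
      g <- glance(fit)
      g$topology <- topo
      g
    })
    out <- list_rbind(fits)
    out$delta_AIC <- out$AIC - min(out$AIC[out$converged])
    out$best <- out$AIC == min(out$AIC[out$converged]) & out$converged
    out
  })
  out <- list_rbind(rows)
  out <- out[, c("topology", "hypothesis", "logLik", "n_params", "AIC",
                 "delta_AIC", "best", "converged")]
  class(out) <- c("model_comparison", class(tibble()))
  out
}

#' Plot a model comparison
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot object showing delta-AIC per hypothesis and topology.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$hypothesis, y = .data$delta_AIC,
                               fill = .data$best)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~topology) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = expression(Delta * "AIC")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
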