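# Tangent-space principal component analysis of species-mean shapes.
#
# Procrustes-aligned configurations lie on (near) the unit hypersphere of
# pre-shapes; statistics are computed in the linear tangent space at the
# consensus, reached by orthogonal projection.

#' Tangent-space PCA of aligned shapes
#'
#' Projects aligned configurations orthogonally into the tangent space at the
#' consensus and performs PCA on the projected coordinates.
#'
#' @param means An `aligned_shapes` object, typically from [species_means()].
#' @param tol Eigenvalues below `tol` are treated as null axes and dropped.
#' @return An object of class `shape_pca` with `scores` (species x m),
#'   `eigenvalues`, `percent_variance`, `loadings` (m x 3K, orthonormal
#'   rows), `mean_shape` (K x 3, tangent-space mean), and `center` (the full
#'   3K-vector tangent-space mean used for reconstruction).
#' @export
tangent_pca <- function(means, tol = 1e-12) {
  n <- dim(means$coords)[1]
  if (n < 3) abort("tangent_pca() needs at least 3 species")
  K <- dim(means$coords)[2]
  flat <- t(vapply(seq_len(n), function(i) {
    as.numeric(means$coords[i, , , drop = TRUE])
  }, numeric(K * 3)))
  rownames(flat) <- means$specimens$species_id
  cons <- as.numeric(means$consensus)
  cons <- cons / sqrt(sum(cons^2))
  # Orthogonal projection into the tangent space at the consensus: remove the
  # component along the consensus direction.
  proj <- flat - outer(as.numeric(flat %*% cons), cons)
  ctr <- colMeans(proj)
  dev <- sweep(proj, 2, ctr)
  total_var <- sum(dev^2) / (n - 1)
  if (total_var < tol) abort("zero total shape variance: PCA undefined")
  sv <- svd(dev)
  eig <- sv$d^2 / (n - 1)
  keep <- which(eig > tol)
  keep <- keep[seq_len(min(length(keep), n - 1))]
  loadings <- t(sv$v[, keep, drop = FALSE])
  scores <- dev %*% t(loadings)
  # Deterministic axis orientation: largest-magnitude loading positive.
  for (a in seq_len(nrow(loadings))) {
    peak <- which.max(abs(loadings[a, ]))
    if (loadings[a, peak] < 0) {
      loadings[a, ] <- -loadings[a, ]
      scores[, a] <- -scores[, a]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(loadings) <- colnames(scores)
  eig <- eig[keep]
  structure(
    list(scores = scores,
         eigenvalues = eig,
         percent_variance = 100 * eig / sum(eig),
         loadings = loadings,
         center = ctr,
         mean_shape = matrix(colMeans(flat), K, 3,
                             dimnames = list(means$key$label, c("x", "y", "z"))),
         consensus = means$consensus,
         key = means$key,
         n_species = n,
         total_variance = sum(eig)),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d species, %d axes\n", x$n_species,
              length(x$eigenvalues)))
  pv <- utils::head(x$percent_variance, 4)
  cat("  leading percent variance:",
      paste(sprintf("%.2f", pv), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a shape PCA
#'
#' @param x A `shape_pca` object.
#' @param matrix One of `"scores"` (default; one row per species per axis),
#'   `"eigenvalues"` (one row per axis), or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.shape_pca <- function(x, matrix = c("scores", "eigenvalues", "loadings"),
                           ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    out <- as_tibble(x$scores)
    out$species_id <- rownames(x$scores)
    return(tidyr::pivot_longer(out, -"species_id", names_to = "axis",
                               values_to = "score"))
  }
  if (matrix == "eigenvalues") {
    return(tibble(axis = paste0("PC", seq_along(x$eigenvalues)),
                  eigenvalue = x$eigenvalues,
                  percent_variance = x$percent_variance,
                  cumulative_percent = cumsum(x$percent_variance)))
  }
  out <- as_tibble(t(x$loadings))
  out$coordinate <- rep(c("x", "y", "z"), each = nrow(x$key))
  out$landmark <- rep(x$key$label, times = 3)
  tidyr::pivot_longer(out, -c("coordinate", "landmark"),
                      names_to = "axis", values_to = "loading")
}

#' @export
glance.shape_pca <- function(x, ...) {
  tibble(n_species = x$n_species,
         n_axes = length(x$eigenvalues),
         total_variance = x$total_variance,
         pc1_percent = x$percent_variance[1])
}

#' Species scores as a wide tibble
#'
#' @param pca A `shape_pca` object.
#' @param n_axes Number of leading axes to keep (default all).
#' @return A tibble with `species_id` and one column per PC.
#' @export
pca_scores <- function(pca, n_axes = NULL) {
  m <- pca$scores
  if (!is.null(n_axes)) m <- m[, seq_len(min(n_axes, ncol(m))), drop = FALSE]
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(species_id = rownames(pca$scores)), out)
  out
}

# Number of leading axes reaching a cumulative percent-variance threshold.
n_axes_for_variance <- function(pca, threshold = 95) {
  cum <- cumsum(pca$percent_variance)
  max(1L, which(cum >= threshold - 1e-9)[1])
}

#' Scatterplot of a shape-PCA morphospace
#'
#' @param object A `shape_pca` object.
#' @param axes Integer vector of length 2: which PCs to plot.
#' @param groups Optional tibble (`species_id`, `group`) used to colour
#'   points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_pca <- function(object, axes = c(1, 2), groups = NULL, ...) {
  df <- pca_scores(object)
  ax <- paste0("PC", axes)
  pv <- object$percent_variance[axes]
  if (!is.null(groups)) df <- left_join(df, groups, by = "species_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]))
  p <- if (!is.null(groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], pv[1]),
      y = sprintf("%s (%.1f%%)", ax[2], pv[2])) +
    ggplot2::theme_minimal()
}
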