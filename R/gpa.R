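# Generalized Procrustes superimposition and related shape geometry.
#
# Full Procrustes variant: every configuration is centred, scaled to unit
# centroid size, and rotated (rotations only — reflections disallowed) to the
# evolving consensus until the consensus stabilises.

centroid_size <- function(x) {
  cen <- sweep(x, 2, colMeans(x))
  sqrt(sum(cen^2))
}

center_config <- function(x) sweep(x, 2, colMeans(x))

# Optimal rotation R (det +1) minimising ||x %*% R - target||^2 for centred
# configurations, via SVD of the cross-covariance.
optimal_rotation <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# Ordinary (two-configuration) Procrustes superimposition of y onto x:
# centre both, scale to unit centroid size, rotate y.
opa_align <- function(x, y) {
  xs <- center_config(x); xs <- xs / sqrt(sum(xs^2))
  ys <- center_config(y); ys <- ys / sqrt(sum(ys^2))
  r <- optimal_rotation(ys, xs)
  list(x = xs, y = ys %*% r, rotation = r)
}

#' Procrustes distance between two landmark configurations
#'
#' Square root of the summed squared coordinate differences after optimal
#' superimposition (translation, unit-centroid-size scaling, and rotation
#' without reflection) of `b` onto `a`.
#'
#' @param a,b Numeric K x 3 (or K x 2, padded internally) matrices with the
#'   same number of landmarks.
#' @return A non-negative scalar; zero iff the shapes are identical up to a
#'   similarity transform.
#' @export
procrustes_distance <- function(a, b) {
  a <- pad3(as.matrix(a)); b <- pad3(as.matrix(b))
  if (!all(dim(a) == dim(b))) abort("configurations must have the same K")
  al <- opa_align(a, b)
  sqrt(sum((al$x - al$y)^2))
}

pad3 <- function(x) {
  if (ncol(x) == 3) return(x)
  if (ncol(x) == 2) return(cbind(x, 0))
  abort("landmark configurations must be K x 2 or K x 3")
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes all specimen configurations: each is centred,
#' scaled to unit centroid size, and rotated to the current consensus; the
#' consensus is re-estimated until it changes by less than `tol` (root summed
#' squared difference) or `max_iter` iterations.
#'
#' @param lms A [landmark_set()] with no missing landmarks (run
#'   [mirror_fill()] first), or an n x K x 3 array.
#' @param tol Convergence tolerance on the consensus update.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `aligned_shapes`: list with `coords`
#'   (n x K x 3 Procrustes coordinates), `centroid_sizes` (original sizes,
#'   length units), `consensus` (K x 3), and the landmark/specimen
#'   bookkeeping needed downstream.
#' @export
gpa <- function(lms, tol = 1e-10, max_iter = 200) {
  if (inherits(lms, "landmark_set")) {
    arr <- landmark_array(lms)
    if (any(arr$missing)) {
      abort("missing landmarks present; run mirror_fill() before gpa()")
    }
    coords <- arr$coords
    meta <- arr[c("key", "pairs", "midline", "specimens")]
  } else if (is.array(lms) && length(dim(lms)) == 3) {
    coords <- lms
    n <- dim(coords)[1]
    meta <- list(
      key = tibble(landmark_id = sprintf("lm%02d", seq_len(dim(coords)[2])),
                   side = "M",
                   label = sprintf("lm%02d|M", seq_len(dim(coords)[2]))),
      pairs = tibble(landmark_id = character(), left = integer(), right = integer()),
      midline = seq_len(dim(coords)[2]),
      specimens = tibble(specimen_id = dimnames(coords)[[1]] %||%
                           sprintf("spec%03d", seq_len(n)),
                         species_id = dimnames(coords)[[1]] %||%
                           sprintf("spec%03d", seq_len(n)),
                         observer_id = NA_character_)
    )
  } else {
    abort("gpa() expects a landmark_set or an n x K x 3 array")
  }
  n <- dim(coords)[1]
  K <- dim(coords)[2]
  if (n < 2) abort("gpa() needs at least 2 specimens")

  sizes <- numeric(n)
  aligned <- array(NA_real_, dim = dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) {
    cfg <- coords[i, , , drop = TRUE]
    sizes[i] <- centroid_size(cfg)
    if (sizes[i] < 1e-12) {
      abort(paste0("degenerate (all-coincident) configuration: specimen `",
                   meta$specimens$specimen_id[i], "`"))
    }
    cen <- center_config(cfg)
    aligned[i, , ] <- cen / sqrt(sum(cen^2))
  }
  names(sizes) <- meta$specimens$specimen_id

  consensus <- aligned[1, , , drop = TRUE]
  delta <- Inf
  iter <- 0
  while (delta > tol && iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(n)) {
      cfg <- aligned[i, , , drop = TRUE]
      aligned[i, , ] <- cfg %*% optimal_rotation(cfg, consensus)
    }
    new_consensus <- apply(aligned, c(2, 3), mean)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  if (delta > tol) {
    abort(sprintf("gpa() did not converge in %d iterations (residual %.3e)",
                  max_iter, delta))
  }
  structure(
    list(coords = aligned, centroid_sizes = sizes, consensus = consensus,
         key = meta$key, pairs = meta$pairs, midline = meta$midline,
         specimens = meta$specimens, iterations = iter),
    class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("<aligned_shapes> %d configurations, K = %d landmarks (converged in %d iterations)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$iterations))
  invisible(x)
}

#' @export
as_tibble.aligned_shapes <- function(x, ...) {
  n <- dim(x$coords)[1]; K <- dim(x$coords)[2]
  grid <- expand.grid(j = seq_len(K), i = seq_len(n))
  xs <- x$coords[cbind(grid$i, grid$j, 1)]
  ys <- x$coords[cbind(grid$i, grid$j, 2)]
  zs <- x$coords[cbind(grid$i, grid$j, 3)]
  tibble(
    specimen_id = x$specimens$specimen_id[grid$i],
    species_id = x$specimens$species_id[grid$i],
    landmark_id = x$key$landmark_id[grid$j],
    side = x$key$side[grid$j],
    x = xs, y = ys, z = zs
  )
}

# Reflect a configuration across the yz-plane and swap left/right labels.
# For an object with bilateral symmetry this maps the configuration onto
# (approximately) itself.
reflect_relabel <- function(cfg, pairs) {
  out <- cfg
  out[, 1] <- -out[, 1]
  if (nrow(pairs) > 0) {
    tmp <- out[pairs$left, , drop = FALSE]
    out[pairs$left, ] <- out[pairs$right, , drop = FALSE]
    out[pairs$right, ] <- tmp
  }
  out
}

# Symmetric component of one centred, unit-size configuration: align the
# reflected-and-relabeled copy onto the original (rotation only) and average;
# iterate to the fixed point at which the configuration coincides with its
# own aligned reflection, so the output is exactly symmetric.
symmetric_component <- function(cfg, pairs, tol = 1e-12, max_iter = 100) {
  cur <- cfg
  for (k in seq_len(max_iter)) {
    refl <- reflect_relabel(cur, pairs)
    refl <- center_config(refl)
    refl <- refl / sqrt(sum(refl^2))
    refl <- refl %*% optimal_rotation(refl, cur)
    avg <- (cur + refl) / 2
    avg <- center_config(avg)
    avg <- avg / sqrt(sum(avg^2))
    if (sqrt(sum((avg - cur)^2)) < tol) return(avg)
    cur <- avg
  }
  cur
}

#' Extract the symmetric component of aligned shapes
#'
#' For each aligned configuration, forms its reflected copy with left/right
#' landmark labels swapped, superimposes the copy back onto the original, and
#' averages the two. The result retains only object-symmetric shape
#' variation. A final superimposition pass restores a common consensus.
#'
#' @param aligned An `aligned_shapes` object from [gpa()].
#' @return An `aligned_shapes` object of symmetric components. With an empty
#'   bilateral pair map the input is returned unchanged with a warning.
#' @export
symmetrize <- function(aligned) {
  if (nrow(aligned$pairs) == 0) {
    warn("no bilateral pairs annotated; symmetrize() is the identity")
    return(aligned)
  }
  out <- aligned
  n <- dim(aligned$coords)[1]
  for (i in seq_len(n)) {
    out$coords[i, , ] <- symmetric_component(
      aligned$coords[i, , , drop = TRUE], aligned$pairs)
  }
  # Re-align the symmetrized configurations to a common consensus.
  re <- gpa_realign(out)
  re
}

# One GPA pass over already unit-size centred configurations (keeps original
# centroid sizes and metadata).
gpa_realign <- function(aligned, tol = 1e-10, max_iter = 200) {
  consensus <- apply(aligned$coords, c(2, 3), mean)
  n <- dim(aligned$coords)[1]
  delta <- Inf; iter <- 0
  while (delta > tol && iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(n)) {
      cfg <- aligned$coords[i, , , drop = TRUE]
      aligned$coords[i, , ] <- cfg %*% optimal_rotation(cfg, consensus)
    }
    new_consensus <- apply(aligned$coords, c(2, 3), mean)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  aligned$consensus <- consensus
  aligned
}

#' Per-specimen asymmetry scores
#'
#' Procrustes distance between each aligned configuration and its symmetric
#' component. Large scores on fossil material may indicate taphonomic
#' distortion; thresholding is left to the user.
#'
#' @param aligned An `aligned_shapes` object from [gpa()].
#' @return A tibble with `specimen_id`, `species_id`, `asymmetry`.
#' @export
asymmetry_scores <- function(aligned) {
  n <- dim(aligned$coords)[1]
  score <- vapply(seq_len(n), function(i) {
    cfg <- aligned$coords[i, , , drop = TRUE]
    procrustes_distance(cfg, symmetric_component(cfg, aligned$pairs))
  }, numeric(1))
  tibble(specimen_id = aligned$specimens$specimen_id,
         species_id = aligned$specimens$species_id,
         asymmetry = score)
}

#' Species-mean shapes
#'
#' Arithmetic mean of aligned coordinates per species, so that each tip of a
#' phylogeny is represented by a single shape point. Species order follows
#' first appearance in the specimen table.
#'
#' @param aligned An `aligned_shapes` object.
#' @return An `aligned_shapes` object with one configuration per species.
#' @export
species_means <- function(aligned) {
  sp <- aligned$specimens$species_id
  species <- unique(sp)
  K <- dim(aligned$coords)[2]
  means <- array(NA_real_, dim = c(length(species), K, 3),
                 dimnames = list(species, dimnames(aligned$coords)[[2]],
                                 c("x", "y", "z")))
  for (s in seq_along(species)) {
    idx <- which(sp == species[s])
    sub <- aligned$coords[idx, , , drop = FALSE]
    means[s, , ] <- apply(sub, c(2, 3), mean)
  }
  sizes <- tapply(aligned$centroid_sizes, sp, mean)[species]
  structure(
    list(coords = means, centroid_sizes = sizes,
         consensus = apply(means, c(2, 3), mean),
         key = aligned$key, pairs = aligned$pairs, midline = aligned$midline,
         specimens = tibble(specimen_id = species, species_id = species,
                            observer_id = NA_character_),
         iterations = aligned$iterations),
    class = "aligned_shapes")
}
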