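# Independent oracles and small fixture builders used across test files.

# Brute-force full Procrustes distance for planar (z = 0) configurations:
# centre, scale to unit centroid size, then minimize over in-plane rotation
# angle by coarse grid + golden-section refinement. In-plane reflections are
# included because a proper 3-D rotation (180 degrees about an in-plane axis)
# realizes them for planar shapes.
oracle_procrustes_planar <- function(a, b) {
  norm_cfg <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm_cfg(a[, 1:2]); b <- norm_cfg(b[, 1:2])
  best_over_angles <- function(bb) {
    dist_at <- function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sqrt(sum((a - bb %*% R)^2))
    }
    grid <- seq(0, 2 * pi, length.out = 721)
    vals <- vapply(grid, dist_at, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    stats::optimize(dist_at, c(lo, hi), tol = 1e-12)$objective
  }
  b_refl <- b; b_refl[, 2] <- -b_refl[, 2]
  min(best_over_angles(b), best_over_angles(b_refl))
}

# Path-traversal MRCA-depth oracle for the BM covariance.
oracle_bm_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  anc_path <- function(tip) {
    node <- tip
    path <- node
    while (node != root) {
      node <- parent_of[node]
      path <- c(path, node)
    }
    path
  }
  paths <- lapply(seq_len(n), anc_path)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- max(depths[shared])
  }
  V
}

# Dense quadratic-programming oracle for gradual-mode ancestral states:
# numerically minimize sum((delta)^2 / length) over internal values.
oracle_gradual <- function(tree, tip_vals) {
  n <- length(tree$tip.label)
  obj <- function(internal) {
    vals <- c(tip_vals[tree$tip.label], internal)
    sum((vals[tree$edge[, 2]] - vals[tree$edge[, 1]])^2 / tree$edge.length)
  }
  init <- rep(mean(tip_vals), tree$Nnode)
  opt <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$par
}

# Hand-written bivariate normal log-density (no matrix package shortcuts).
oracle_dmvnorm2 <- function(y, mu, S) {
  det2 <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det2
  r <- y - mu
  -log(2 * pi) - 0.5 * log(det2) - 0.5 * as.numeric(t(r) %*% Sinv %*% r)
}

# Random bifurcating time tree with positive lengths.
random_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 0.1, death = 0)
    tr$tip.label <- sprintf("t%03d", seq_len(n_tips))
    tr
  })
}

# A small well-behaved landmark set: symmetric template, mild trait signal.
toy_landmarks <- function(n_species = 6, seed = 11, noise = 0.01,
                          missing_fraction = 0, n_specimens = 2) {
  spec <- simulation_spec(
    n_tips = max(n_species, 3), tree_height = 30, n_traits = 2, seed = seed,
    specimen_noise_sd = noise, n_specimens_per_species = n_specimens,
    missing_fraction = missing_fraction)
  d <- simulate_dataset(spec)
  d$spec <- spec
  d
}
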