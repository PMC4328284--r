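# Synthetic data with known ground truth: birth-process trees, exact-
# transition trait simulation under BM or painted multi-optima OU, and
# rendering of trait values as specimen-level 3D landmark configurations.

#' Specify a synthetic dataset
#'
#' Collects every knob of the generator in one validated object. The trait
#' model is parameterised per regime and per trait by `params`, a data frame
#' with columns `regime`, `trait` (1..p), `sigma2` (variance per My),
#' `alpha` (per-My adaptation rate; 0 means BM), and `theta` (optimum).
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth_rate Speciation rate per My of the pure-birth tree process.
#' @param tree_height Optional height (My) to rescale the tree to.
#' @param n_traits Number of traits p.
#' @param model `"BM"` or `"OU"`.
#' @param params Per-regime, per-trait parameter table (see above). For a
#'   single unnamed regime use regime = `"global"`.
#' @param root_state Numeric length-p root state for BM (OU roots start at
#'   the root regime's optimum).
#' @param fossils Optional tibble (`attach`, `divergence_frac`, `tip_age`,
#'   `label`): each fossil diverges from the branch subtending tip `attach`
#'   at a point `divergence_frac` (0, 1) along that branch (0 = child end)
#'   and ends at age `tip_age` My before present.
#' @param landmark_template Template tibble (`landmark_id`, `side`, `x`,
#'   `y`, `z`); defaults to [default_landmark_template()].
#' @param n_basis Number of orthonormal landmark-space directions that carry
#'   the traits (defaults to `n_traits`).
#' @param specimen_noise_sd Isotropic per-coordinate digitizing/individual
#'   noise, shape units.
#' @param n_specimens_per_species Specimens digitized per species.
#' @param missing_fraction Fraction of specimens with one whole side missing.
#' @param nuisance_transforms Apply an arbitrary rotation, translation and
#'   positive scale to every specimen (what Procrustes must undo).
#' @param seed Master seed; all stages use named substreams derived from it.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_tips = 20, birth_rate = 0.1, tree_height = NULL,
                            n_traits = 2, model = c("BM", "OU"),
                            params = NULL, root_state = NULL, fossils = NULL,
                            landmark_template = default_landmark_template(),
                            n_basis = n_traits, specimen_noise_sd = 0.02,
                            n_specimens_per_species = 3,
                            missing_fraction = 0, nuisance_transforms = TRUE,
                            seed = 1) {
  model <- match.arg(model)
  if (n_tips < 3) abort("n_tips must be >= 3")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  if (is.null(params)) {
    params <- tidyr::expand_grid(regime = "global", trait = seq_len(n_traits))
    params$sigma2 <- 1
    params$alpha <- if (model == "OU") 1 else 0
    params$theta <- 0
  }
  params <- as_tibble(params)
  if (any(params$sigma2 <= 0)) abort("sigma2 must be > 0")
  if (any(params$alpha < 0)) abort("alpha must be >= 0")
  if (missing_fraction < 0 || missing_fraction > 1) {
    abort("missing_fraction must be in [0, 1]")
  }
  if (is.null(root_state)) root_state <- rep(0, n_traits)
  structure(
    list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
         tree_height = tree_height, n_traits = as.integer(n_traits),
         model = model, params = params, root_state = root_state,
         fossils = fossils, landmark_template = as_tibble(landmark_template),
         n_basis = as.integer(n_basis),
         specimen_noise_sd = specimen_noise_sd,
         n_specimens_per_species = as.integer(n_specimens_per_species),
         missing_fraction = missing_fraction,
         nuisance_transforms = nuisance_transforms, seed = as.integer(seed)),
    class = "simulation_spec")
}

#' Default skull-like landmark template
#'
#' Eleven landmarks: three on the midline and four bilateral pairs, mirrored
#' exactly across the x = 0 plane, loosely arranged like a cranial landmark
#' scheme (rostral midline point, vault suture, occipital point, and paired
#' lateral points).
#'
#' @return A tibble with `landmark_id`, `side`, `x`, `y`, `z`.
#' @export
default_landmark_template <- function() {
  mid <- tibble(
    landmark_id = c("m1_rostrum", "m2_vault", "m3_occiput"),
    side = "M",
    x = 0, y = c(3, 1.2, -2.6), z = c(0, 1.1, 0.7))
  pr <- tibble(
    landmark_id = rep(c("p1_canine", "p2_jugal", "p3_squamosal", "p4_bulla"),
                      each = 2),
    side = rep(c("L", "R"), 4),
    x = rep(c(0.8, 1.25, 1.1, 0.6), each = 2) * rep(c(1, -1), 4),
    y = rep(c(2.1, 0.6, -1.0, -2.1), each = 2),
    z = rep(c(-0.6, -0.5, -0.2, 0.15), each = 2))
  bind_rows(mid, pr)
}

# Template as a K x 3 matrix ordered like landmark_info()'s key, plus pair
# and midline bookkeeping.
template_array <- function(template) {
  df <- as_tibble(template)
  df$label <- paste(df$landmark_id, df$side, sep = "|")
  ord <- order(df$landmark_id, df$side)
  df <- df[ord, ]
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$label
  pairs_ids <- unique(df$landmark_id[df$side %in% c("L", "R")])
  pairs <- tibble(landmark_id = pairs_ids,
                  left = match(paste(pairs_ids, "L", sep = "|"), df$label),
                  right = match(paste(pairs_ids, "R", sep = "|"), df$label))
  list(coords = m, key = df[, c("landmark_id", "side", "label")],
       pairs = pairs, midline = which(df$side == "M"))
}

#' Simulate a time-calibrated tree
#'
#' Pure-birth tree with `n_tips` extant tips, optionally rescaled to a fixed
#' height, with optional fossil tips grafted on afterwards.
#'
#' @param spec A [simulation_spec()].
#' @return A `phylo` object; reproducible for a fixed spec.
#' @export
simulate_tree <- function(spec) {
  tree <- with_seed(substream_seed(spec$seed, "tree"), {
    ape::rphylo(spec$n_tips, birth = spec$birth_rate, death = 0)
  })
  tree$tip.label <- sprintf("t%03d", seq_len(spec$n_tips))
  if (!is.null(spec$tree_height)) {
    h <- max(node_depths(tree))
    tree$edge.length <- tree$edge.length * spec$tree_height / h
  }
  if (!is.null(spec$fossils)) {
    for (i in seq_len(nrow(spec$fossils))) {
      f <- spec$fossils[i, ]
      ages <- node_ages(tree)
      node <- match(f$attach, tree$tip.label)
      if (is.na(node)) abort(paste0("fossil attach tip not found: ", f$attach))
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      div <- ages[node] + f$divergence_frac * (ages[parent] - ages[node])
      if (f$tip_age >= div) {
        abort(sprintf(
          "fossil `%s` is older (%.3g My) than its divergence point (%.3g My) on branch to `%s`",
          f$label, f$tip_age, div, f$attach))
      }
      tree <- graft_fossil(tree, f$attach, div, f$tip_age, f$label)
    }
  }
  tree
}

# Exact one-branch transition: child | parent under BM or OU.
transition_sample <- function(parent, t, sigma2, alpha, theta) {
  if (alpha <= 0) {
    return(stats::rnorm(1, mean = parent, sd = sqrt(sigma2 * t)))
  }
  w <- exp(-alpha * t)
  v <- sigma2 * -expm1(-2 * alpha * t) / (2 * alpha)
  stats::rnorm(1, mean = theta + (parent - theta) * w, sd = sqrt(v))
}

#' Simulate trait evolution on a tree by exact transition sampling
#'
#' Traits evolve independently along branches; each branch transition is
#' drawn from the exact conditional law (BM: `N(parent, sigma2 t)`; OU:
#' `N(theta + (parent - theta) e^{-alpha t}, sigma2 (1 - e^{-2 alpha t}) /
#' (2 alpha))`), so there is no discretization error. An OU regime with
#' `alpha = 0` falls back to the BM transition.
#'
#' @param tree A `phylo` object.
#' @param spec A [simulation_spec()].
#' @param painting Optional [paint_regimes()] painting; defaults to a single
#'   `"global"` regime on every branch. Regime labels must match
#'   `spec$params$regime`.
#' @return A list with `traits` (tips x p matrix, rownames = tip labels) and
#'   `truth` (class `synthetic_truth`: all node states, the painting,
#'   per-branch realized displacements, and the seed).
#' @export
simulate_traits <- function(tree, spec, painting = NULL) {
  p <- spec$n_traits
  if (is.null(painting)) {
    painting <- paint_regimes(tree, "one_regime")
    painting$regime <- "global"
    attr(painting, "regimes") <- "global"
  }
  if (!all(painting$regime %in% unique(spec$params$regime))) {
    abort("painting uses regimes absent from spec$params")
  }
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  states <- matrix(NA_real_, n_nodes, p)
  par_lookup <- function(regime, trait) {
    row <- spec$params[spec$params$regime == regime &
                         spec$params$trait == trait, ]
    if (nrow(row) != 1) {
      abort(paste0("no unique parameter row for regime `", regime,
                   "`, trait ", trait))
    }
    row
  }
  rr <- root_regime(tree, painting)
  with_seed(substream_seed(spec$seed, "traits"), {
    for (j in seq_len(p)) {
      states[root, j] <- if (spec$model == "OU") {
        par_lookup(rr, j)$theta
      } else spec$root_state[j]
    }
    # Preorder: ape's edge matrix from the root via reordering.
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      a <- ord$edge[e, 1]; b <- ord$edge[e, 2]
      t_len <- ord$edge.length[e]
      reg <- painting$regime[painting$child == b]
      for (j in seq_len(p)) {
        pr <- par_lookup(reg, j)
        alpha <- if (spec$model == "OU") pr$alpha else 0
        states[b, j] <- transition_sample(states[a, j], t_len, pr$sigma2,
                                          alpha, pr$theta)
      }
    }
  })
  rownames(states) <- c(tree$tip.label,
                        as.character(seq_len(tree$Nnode) + n_tip))
  colnames(states) <- paste0("trait", seq_len(p))
  disp <- tibble(parent = tree$edge[, 1], child = tree$edge[, 2])
  disp_mat <- states[disp$child, , drop = FALSE] -
    states[disp$parent, , drop = FALSE]
  truth <- structure(
    list(node_states = states, painting = painting,
         displacement = bind_cols(disp, as_tibble(disp_mat)),
         seed = spec$seed),
    class = "synthetic_truth")
  list(traits = states[seq_len(n_tip), , drop = FALSE], truth = truth)
}

# Orthonormal trait-carrying directions in landmark space: bilaterally
# symmetric and orthogonal to the similarity-transform directions at the
# template, so GPA cannot remove trait signal.
make_basis <- function(template, p, seed) {
  X0 <- center_config(template$coords)
  X0 <- X0 / sqrt(sum(X0^2))
  K <- nrow(X0)
  skew <- function(a) matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  nuisance <- cbind(
    as.numeric(matrix(rep(c(1, 0, 0), each = K), K, 3)),
    as.numeric(matrix(rep(c(0, 1, 0), each = K), K, 3)),
    as.numeric(matrix(rep(c(0, 0, 1), each = K), K, 3)),
    as.numeric(X0 %*% skew(c(1, 0, 0))),
    as.numeric(X0 %*% skew(c(0, 1, 0))),
    as.numeric(X0 %*% skew(c(0, 0, 1))),
    as.numeric(X0))
  refl_vec <- function(v) {
    as.numeric(reflect_relabel(matrix(v, K, 3), template$pairs))
  }
  raw <- with_seed(substream_seed(seed, "landmarks"), {
    matrix(stats::rnorm(3 * K * p), ncol = p)
  })
  sym <- apply(raw, 2, function(v) (v + refl_vec(v)) / 2)
  qn <- qr.Q(qr(nuisance))
  resid <- sym - qn %*% crossprod(qn, sym)
  q <- qr.Q(qr(resid))[, seq_len(p), drop = FALSE]
  # Deterministic sign: largest-magnitude entry positive.
  for (j in seq_len(p)) {
    peak <- which.max(abs(q[, j]))
    if (q[peak, j] < 0) q[, j] <- -q[, j]
  }
  q
}

#' Render trait values as specimen landmark configurations
#'
#' Each species' mean shape is the template displaced along `n_basis`
#' orthonormal landmark-space directions by its trait values. Specimens are
#' the mean shape plus isotropic noise, then (optionally) an arbitrary
#' rotation, translation and positive scale. A `missing_fraction` of
#' specimens have all landmarks of one randomly chosen side deleted.
#'
#' @param traits Species x p trait matrix (rownames = species ids).
#' @param spec A [simulation_spec()].
#' @return A [landmark_set()] tibble.
#' @export
traits_to_landmarks <- function(traits, spec) {
  traits <- as_trait_matrix(traits)
  tmpl <- template_array(spec$landmark_template)
  K <- nrow(tmpl$coords)
  if (K < 4) abort("landmark template needs >= 4 landmarks for 3D superimposition")
  if (qr(center_config(tmpl$coords))$rank < 2) {
    abort("landmark template is collinear: superimposition undefined in 3D")
  }
  p <- min(ncol(traits), spec$n_basis)
  basis <- make_basis(tmpl, p, spec$seed)
  species <- rownames(traits)
  n_per <- spec$n_specimens_per_species
  recs <- with_seed(substream_seed(spec$seed, "missing"), {
    out <- vector("list", length(species) * n_per)
    k <- 0
    for (s in seq_along(species)) {
      mean_shape <- tmpl$coords +
        matrix(basis %*% traits[s, seq_len(p)], K, 3)
      for (r in seq_len(n_per)) {
        k <- k + 1
        cfg <- mean_shape
        if (spec$specimen_noise_sd > 0) {
          cfg <- cfg + matrix(stats::rnorm(K * 3, sd = spec$specimen_noise_sd),
                              K, 3)
        }
        if (isTRUE(spec$nuisance_transforms)) {
          rot <- random_rotation()
          scale <- exp(stats::rnorm(1, sd = 0.3))
          shift <- stats::runif(3, -5, 5)
          cfg <- scale * cfg %*% rot
          cfg <- sweep(cfg, 2, shift, "+")
        }
        miss <- rep(FALSE, K)
        if (spec$missing_fraction > 0 &&
            stats::runif(1) < spec$missing_fraction) {
          side <- if (stats::runif(1) < 0.5) "L" else "R"
          miss[tmpl$key$side == side] <- TRUE
          cfg[miss, ] <- NA_real_
        }
        out[[k]] <- tibble(
          specimen_id = sprintf("%s_s%02d", species[s], r),
          species_id = species[s],
          observer_id = NA_character_,
          landmark_id = tmpl$key$landmark_id,
          side = tmpl$key$side,
          x = cfg[, 1], y = cfg[, 2], z = cfg[, 3],
          missing = miss)
      }
    }
    out
  })
  landmark_set(list_rbind(recs))
}

# Uniform random rotation (det +1) from the QR decomposition of a Gaussian
# matrix with sign correction.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Simulate a complete dataset (tree, traits, landmarks)
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_traits()] and
#' [traits_to_landmarks()].
#'
#' @param spec A [simulation_spec()].
#' @param painting Optional regime painting forwarded to [simulate_traits()].
#' @return A list with `tree`, `traits`, `truth`, `landmarks`.
#' @export
simulate_dataset <- function(spec, painting = NULL) {
  tree <- simulate_tree(spec)
  tr <- simulate_traits(tree, spec, painting = painting)
  lms <- traits_to_landmarks(tr$traits, spec)
  list(tree = tree, traits = tr$traits, truth = tr$truth, landmarks = lms)
}

#' Write ground truth to TSV
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- as_tibble(truth$node_states)
  df <- bind_cols(tibble(node = rownames(truth$node_states)), df)
  write_tsv_provenance(df, path, provenance = paste0("seed=", truth$seed))
}
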