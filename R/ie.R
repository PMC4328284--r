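# Independent Evolution (IE): ancestral node values and branch-specific
# evolutionary rates from a gradual-mode expectation plus a triangulation
# whose inverse-branch-length-weighted barycentre best fits the ancestor
# expectation and the two descendant values. The branch rate is the distance
# between the barycentre and the descendant value; a time-standardized
# variant divides by branch length.

#' Gradual-mode ancestral expectations
#'
#' Maximum-likelihood BM ancestral states: the unique minimizer of
#' `sum over branches of (change)^2 / branch length` over all internal-node
#' assignments (branch-length-weighted squared change, equivalent to GLS
#' under Brownian motion). Tip values are fixed at the observations.
#'
#' @param tree A `phylo` object.
#' @param tip_values Named numeric vector (tip labels) or species x m matrix
#'   / data frame of trait values.
#' @return A matrix (all nodes x traits) of values; tip rows equal the
#'   input. Rownames are tip labels then internal node ids.
#' @export
gradual_expectations <- function(tree, tip_values) {
  y <- tip_values_matrix(tree, tip_values)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  len <- tree$edge.length
  floor_warned <- any(len < 1e-8)
  if (floor_warned) {
    warn("branch lengths floored at 1e-8 for the gradual-mode solve")
    len <- pmax(len, 1e-8)
  }
  w <- 1 / len
  # Normal equations over internal nodes: each internal node's value is the
  # inverse-length-weighted mean of its neighbours.
  A <- matrix(0, n_int, n_int)
  B <- matrix(0, n_int, ncol(y))
  idx <- function(node) node - n_tip
  for (e in seq_along(w)) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    A[idx(a), idx(a)] <- A[idx(a), idx(a)] + w[e]
    if (b > n_tip) {
      A[idx(b), idx(b)] <- A[idx(b), idx(b)] + w[e]
      A[idx(a), idx(b)] <- A[idx(a), idx(b)] - w[e]
      A[idx(b), idx(a)] <- A[idx(b), idx(a)] - w[e]
    } else {
      B[idx(a), ] <- B[idx(a), ] + w[e] * y[b, ]
    }
  }
  internal <- solve(A, B)
  out <- rbind(y, internal)
  rownames(out) <- c(tree$tip.label,
                     as.character(seq_len(n_int) + n_tip))
  out
}

tip_values_matrix <- function(tree, tip_values) {
  if (is.numeric(tip_values) && is.null(dim(tip_values))) {
    tip_values <- matrix(tip_values, ncol = 1,
                         dimnames = list(names(tip_values), "trait1"))
  }
  y <- as_trait_matrix(tip_values)
  y <- check_scores_tree(y, tree)
  y
}

#' Triangulation barycentre and branch rates at one node
#'
#' The barycentre is the inverse-branch-length-weighted mean of the
#' ancestor's gradual-mode expectation and the two descendant values
#' (minimizing `(b - A)^2/l_anc + (v1 - b)^2/l1 + (v2 - b)^2/l2`); at the
#' root the ancestor term is omitted. The rate on each descendant branch is
#' the absolute distance from the barycentre to the descendant value.
#'
#' @param A Ancestor gradual-mode expectation (use `NA` at the root).
#' @param l_anc Length (My) of the branch above the node (`NA` at the root).
#' @param v1,v2 Descendant values.
#' @param l1,l2 Descendant branch lengths (My), > 0.
#' @return A list with `barycentre`, `r1`, `r2`.
#' @export
ie_barycentre <- function(A, l_anc, v1, l1, v2, l2) {
  if (l1 <= 0 || l2 <= 0 || (!is.na(l_anc) && l_anc <= 0)) {
    abort("branch lengths must be > 0")
  }
  if (is.na(A) || is.na(l_anc)) {
    b <- (v1 / l1 + v2 / l2) / (1 / l1 + 1 / l2)
  } else {
    b <- (A / l_anc + v1 / l1 + v2 / l2) / (1 / l_anc + 1 / l1 + 1 / l2)
  }
  list(barycentre = b, r1 = abs(v1 - b), r2 = abs(v2 - b))
}

#' Independent Evolution node values and branch rates
#'
#' Post-order traversal: at each internal node the descendant inputs are tip
#' observations (terminal branches) or previously computed barycentre values
#' (internal branches); the node's own gradual-mode expectation (from
#' [gradual_expectations()]) anchors the triangulation through the branch
#' above it. Produces final node values and, per branch and trait, the IE
#' rate (distance from barycentre to descendant) and its time-standardized
#' version.
#'
#' @param tree A bifurcating `phylo` object.
#' @param tip_values Tip trait values (vector, matrix or data frame).
#' @return An object of class `ie_fit`: list with `node_states` (all nodes x
#'   traits matrix of final values: observations at tips, barycentres at
#'   internal nodes), `gradual` (the gradual-mode expectations), `rates`
#'   (tibble: `parent`, `child`, `branch_length`, `trait`, `rate`,
#'   `rate_per_my`), and `distances` (tibble: per-branch multivariate
#'   Euclidean displacement across all traits, raw and per My).
#' @export
ie_rates <- function(tree, tip_values) {
  if (!ape::is.binary(tree)) abort("ie_rates() requires a bifurcating tree")
  y <- tip_values_matrix(tree, tip_values)
  grad <- gradual_expectations(tree, y)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  p <- ncol(y)
  states <- grad  # tips stay observed; internals overwritten by barycentres
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])
  children_of <- split(tree$edge[, 2], tree$edge[, 1])

  rate_rows <- vector("list", nrow(tree$edge))
  # Post-order over internal nodes: children before parents.
  post <- ape::reorder.phylo(tree, "postorder")
  internal_order <- unique(post$edge[, 1])
  for (node in internal_order) {
    kids <- children_of[[as.character(node)]]
    anc_exp <- if (node == root) rep(NA_real_, p) else grad[node, ]
    l_anc <- if (node == root) NA_real_ else unname(edge_len[as.character(node)])
    l1 <- unname(edge_len[as.character(kids[1])])
    l2 <- unname(edge_len[as.character(kids[2])])
    for (j in seq_len(p)) {
      tri <- ie_barycentre(anc_exp[j], l_anc,
                           states[kids[1], j], l1,
                           states[kids[2], j], l2)
      states[node, j] <- tri$barycentre
    }
  }
  # Branch rates from final node values: rate = |descendant - parent
  # barycentre| per trait.
  rate_rows <- purrr::map(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    tibble(parent = a, child = b, branch_length = len,
           trait = colnames(y),
           rate = abs(states[b, ] - states[a, ]),
           rate_per_my = abs(states[b, ] - states[a, ]) / len)
  })
  rates <- list_rbind(rate_rows)
  distances <- multivariate_branch_distance(tree, states)
  structure(list(node_states = states, gradual = grad, rates = rates,
                 distances = distances, tree = tree),
            class = "ie_fit")
}

#' @export
print.ie_fit <- function(x, ...) {
  cat(sprintf("<ie_fit> %d tips, %d traits; max branch displacement %.4g\n",
              length(x$tree$tip.label), ncol(x$node_states),
              max(x$distances$displacement)))
  invisible(x)
}

#' @export
tidy.ie_fit <- function(x, ...) x$rates

#' @export
glance.ie_fit <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label), n_traits = ncol(x$node_states),
         total_displacement = sum(x$distances$displacement),
         max_displacement = max(x$distances$displacement))
}

#' Multivariate ancestor-descendant branch distances
#'
#' Euclidean distance across all traits between the states at the two ends
#' of every branch: an estimate of total evolutionary change along the
#' branch.
#'
#' @param tree A `phylo` object.
#' @param node_states All-nodes x traits matrix (e.g. `ie_fit$node_states`).
#' @return A tibble with `parent`, `child`, `branch_length`, `displacement`,
#'   `displacement_per_my`.
#' @export
multivariate_branch_distance <- function(tree, node_states) {
  if (anyNA(node_states)) abort("node_states contains missing values")
  d <- vapply(seq_len(nrow(tree$edge)), function(e) {
    sqrt(sum((node_states[tree$edge[e, 2], ] -
                node_states[tree$edge[e, 1], ])^2))
  }, numeric(1))
  tibble(parent = tree$edge[, 1], child = tree$edge[, 2],
         branch_length = tree$edge.length, displacement = d,
         displacement_per_my = d / tree$edge.length)
}

#' Time-sliced evolutionary morphospace frames
#'
#' For each time from the root age down to the present in steps of `dt` My,
#' every branch alive at that time contributes a point linearly interpolated
#' between its ancestor's and descendant's state in the chosen trait axes.
#' The frame at time 0 equals the tip values; the frame at the root age is
#' the single root state.
#'
#' @param tree A `phylo` object.
#' @param node_states All-nodes x traits matrix.
#' @param axes Trait columns (names or indices) to export.
#' @param dt Time step, My (> 0, at most the tree height).
#' @return A tibble of class `morphospace_frames`: `time` (My before
#'   present), `lineage` (child node id of the contributing branch; the root
#'   id for the root frame), and one column per axis.
#' @export
morphospace_frames <- function(tree, node_states, axes = NULL, dt = 1) {
  if (dt <= 0) abort("dt must be > 0")
  ages <- node_ages(tree)
  root_age <- max(ages)
  if (dt > root_age) abort("dt exceeds the tree height")
  if (is.null(axes)) axes <- colnames(node_states)
  st <- node_states[, axes, drop = FALSE]
  times <- sort(unique(c(seq(root_age, 0, by = -dt), 0)), decreasing = TRUE)
  root <- length(tree$tip.label) + 1L
  # Age comparisons tolerate jitter proportional to tree height (grafting and
  # Newick round trips perturb path sums at the 1e-9 level on ~100 My trees).
  eps <- 1e-8 * max(root_age, 1)
  frames <- purrr::map(times, function(t) {
    if (abs(t - root_age) < eps) {
      pos <- st[root, , drop = FALSE]
      return(bind_cols(tibble(time = t, lineage = root), as_tibble(pos)))
    }
    alive <- which(ages[tree$edge[, 2]] <= t + eps &
                     ages[tree$edge[, 1]] > t + eps)
    pos <- purrr::map(alive, function(e) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      frac <- (ages[a] - t) / (ages[a] - ages[b])
      st[a, , drop = FALSE] + frac * (st[b, , drop = FALSE] - st[a, , drop = FALSE])
    })
    pos <- do.call(rbind, pos)
    bind_cols(tibble(time = t, lineage = tree$edge[alive, 2]),
              as_tibble(pos))
  })
  out <- list_rbind(frames)
  class(out) <- c("morphospace_frames", class(tibble()))
  out
}

#' Plot evolutionary morphospace frames
#'
#' Lineage positions through time in two chosen axes, coloured by time.
#'
#' @param object A `morphospace_frames` tibble.
#' @param axes Character vector of length 2: axis columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morphospace_frames <- function(object, axes = NULL, ...) {
  ax <- axes %||% setdiff(names(object), c("time", "lineage"))[1:2]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                       colour = .data$time)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_viridis_c(direction = -1,
                                    name = "My before present") +
    ggplot2::labs(x = ax[1], y = ax[2]) +
    ggplot2::theme_minimal()
}

#' Write an annotated Newick with branch displacements
#'
#' Branch comments (`[&displacement=...]`) carry the multivariate
#' displacement of each branch.
#'
#' @param ie An `ie_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(ie, path) {
  tree <- ie$tree
  n_tip <- length(tree$tip.label)
  disp <- stats::setNames(ie$distances$displacement, ie$distances$child)
  len <- stats::setNames(tree$edge.length, tree$edge[, 2])
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    core <- if (node <= n_tip) {
      tree$tip.label[node]
    } else {
      kids <- children_of[[as.character(node)]]
      paste0("(", paste(vapply(kids, build, character(1)), collapse = ","), ")")
    }
    key <- as.character(node)
    if (key %in% names(len)) {
      sprintf("%s:%.10g[&displacement=%.8g]", core, len[[key]], disp[[key]])
    } else core  # root has no subtending branch
  }
  writeLines(paste0(build(n_tip + 1L), ";"), path)
  invisible(path)
}
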