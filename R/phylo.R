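# Time-tree input/output, fossil grafting, regime painting, and the
# Brownian-motion phylogenetic covariance.
#
# Trees are `ape::phylo` objects with branch lengths in millions of years.
# Internally nodes are addressed by ape's integer ids (tips 1..n, root n+1).
# "Depth" is time from the root; "age" is time before present, with the
# deepest tip defining the present (age 0).

#' Read a time-calibrated Newick tree
#'
#' @param path Path to a Newick file.
#' @param resolve_polytomies If `TRUE`, polytomies are resolved arbitrarily
#'   with tiny (`1e-8` My) internal branches; by default polytomies are an
#'   error because the downstream models assume bifurcation.
#' @return A rooted, bifurcating `phylo` object with positive branch lengths.
#' @export
read_newick <- function(path, resolve_polytomies = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("could not parse Newick file")
  validate_timetree(tree, resolve_polytomies = resolve_polytomies)
}

validate_timetree <- function(tree, resolve_polytomies = FALSE) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  neg <- which(tree$edge.length <= 0)
  if (length(neg) > 0) {
    abort(sprintf("non-positive branch length on edge to node %d (length %g)",
                  tree$edge[neg[1], 2], tree$edge.length[neg[1]]))
  }
  if (!ape::is.binary(tree)) {
    if (!resolve_polytomies) {
      abort("tree contains polytomies; models assume bifurcation (set resolve_polytomies = TRUE to resolve with epsilon branches)")
    }
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[tree$edge.length <= 0] <- 1e-8
  }
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @param digits Number of digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Node depths from the root (My)
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector over all node ids (tips then internals).
#' @export
node_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  names(d) <- c(tree$tip.label,
                as.character(seq_len(tree$Nnode) + length(tree$tip.label)))
  d
}

#' Node ages before present (My)
#'
#' The deepest tip defines the present (age 0); the root has the maximum age.
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector over all node ids.
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d) - d
}

#' Graft a fossil tip onto a branch
#'
#' Inserts a new tip diverging from `attach_branch` (the branch subtending
#' the given node or tip label) at `divergence_time` (age before present,
#' My), with the fossil tip ending at `tip_age` (its earliest appearance in
#' the fossil record). Existing path lengths are preserved.
#'
#' @param tree A `phylo` object.
#' @param attach_branch Tip label or integer node id; the branch grafted onto
#'   is the one ending in this node.
#' @param divergence_time Age (My before present) at which the fossil lineage
#'   diverges; must lie within the attach branch's time interval.
#' @param tip_age Age (My before present) of the fossil tip; must be younger
#'   than `divergence_time`.
#' @param label Tip label for the fossil.
#' @return A `phylo` object with one more tip.
#' @export
graft_fossil <- function(tree, attach_branch, divergence_time, tip_age, label) {
  ages <- node_ages(tree)
  node <- if (is.character(attach_branch)) {
    m <- match(attach_branch, tree$tip.label)
    if (is.na(m)) abort(paste0("unknown tip label: ", attach_branch))
    m
  } else as.integer(attach_branch)
  edge_row <- which(tree$edge[, 2] == node)
  if (length(edge_row) != 1) abort("attach node has no subtending branch (root?)")
  parent <- tree$edge[edge_row, 1]
  child_age <- ages[node]
  parent_age <- ages[parent]
  if (divergence_time < child_age - 1e-9 || divergence_time > parent_age + 1e-9) {
    abort(sprintf(
      "divergence time %.4g My outside the attach branch's interval [%.4g, %.4g] My",
      divergence_time, child_age, parent_age))
  }
  if (tip_age >= divergence_time) {
    abort(sprintf(
      "fossil tip age (%.4g My) must be younger than its divergence time (%.4g My)",
      tip_age, divergence_time))
  }
  out <- phytools::bind.tip(
    tree, label,
    edge.length = divergence_time - tip_age,
    where = node,
    position = divergence_time - child_age)
  validate_timetree(out)
}

#' Paint selective regimes onto branches
#'
#' Builds the branch-to-regime assignment for one of the four standard
#' hypotheses about a focal ecological transition:
#' \describe{
#'   \item{`BM`}{no painting (single-label placeholder); pure Brownian
#'     motion.}
#'   \item{`one_regime`}{one shared optimum on every branch.}
#'   \item{`terrestrial_aquatic`}{an `aquatic` regime on the focal clade's
#'     stem branch and all of its descendant branches, plus the designated
#'     convergent terminal branch (e.g. an otter-like taxon); `terrestrial`
#'     elsewhere.}
#'   \item{`pinniped_radiation`}{a `shifted` regime on the focal clade's stem
#'     branch and descendants only; `ancestral` elsewhere.}
#' }
#' A regime shift applies to the stem branch itself — the branch on which the
#' transition is reconstructed.
#'
#' @param tree A `phylo` object.
#' @param hypothesis One of `"BM"`, `"one_regime"`, `"terrestrial_aquatic"`,
#'   `"pinniped_radiation"`.
#' @param clade_tips Character vector of tip labels forming the focal
#'   (monophyletic) clade; required for the two shift hypotheses.
#' @param otter_tip Tip label of the convergent terminal branch, required for
#'   `terrestrial_aquatic`.
#' @return A tibble of class `regime_painting` with columns `parent`,
#'   `child`, `regime`, one row per branch, plus attributes `hypothesis` and
#'   `regimes` (regime labels, root regime first).
#' @export
paint_regimes <- function(tree, hypothesis = c("BM", "one_regime",
                                               "terrestrial_aquatic",
                                               "pinniped_radiation"),
                          clade_tips = NULL, otter_tip = NULL) {
  hypothesis <- match.arg(hypothesis)
  edges <- tibble(parent = tree$edge[, 1], child = tree$edge[, 2])
  base_label <- switch(hypothesis,
                       BM = "none",
                       one_regime = "global",
                       terrestrial_aquatic = "terrestrial",
                       pinniped_radiation = "ancestral")
  edges$regime <- base_label
  regimes <- base_label
  if (hypothesis %in% c("terrestrial_aquatic", "pinniped_radiation")) {
    if (is.null(clade_tips)) abort("clade_tips required for this hypothesis")
    if (!all(clade_tips %in% tree$tip.label)) {
      abort("clade_tips contains labels absent from the tree")
    }
    if (!ape::is.monophyletic(tree, clade_tips)) {
      abort("clade_tips is not a monophyletic group on this tree")
    }
    mrca <- if (length(clade_tips) == 1) {
      match(clade_tips, tree$tip.label)
    } else ape::getMRCA(tree, clade_tips)
    clade_nodes <- clade_descendant_nodes(tree, mrca)
    shift_label <- if (hypothesis == "terrestrial_aquatic") "aquatic" else "shifted"
    # Stem branch (ending at the MRCA) plus every descendant branch.
    painted <- edges$child %in% c(mrca, clade_nodes)
    edges$regime[painted] <- shift_label
    if (hypothesis == "terrestrial_aquatic") {
      if (is.null(otter_tip)) abort("otter_tip required for terrestrial_aquatic")
      ot <- match(otter_tip, tree$tip.label)
      if (is.na(ot)) abort(paste0("unknown otter_tip: ", otter_tip))
      edges$regime[edges$child == ot] <- shift_label
    }
    regimes <- c(base_label, shift_label)
  }
  structure(edges, hypothesis = hypothesis, regimes = regimes,
            class = c("regime_painting", class(tibble())))
}

# All node ids (internal and tip) strictly below `node`.
clade_descendant_nodes <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack) > 0) {
    cur <- stack[1]; stack <- stack[-1]
    out <- c(out, cur)
    if (cur > n_tip) stack <- c(stack, tree$edge[tree$edge[, 1] == cur, 2])
  }
  out
}

# Root regime of a painting: the regime of the branches incident to the root
# (the regime in force before any shift; shifts start on stem branches, so
# the root's children branches outside any shifted clade carry it). For a
# painting whose root children are all shifted, the first declared regime is
# used.
root_regime <- function(tree, painting) {
  root <- length(tree$tip.label) + 1L
  kids <- painting$regime[painting$parent == root]
  base <- attr(painting, "regimes")[1]
  if (base %in% kids || length(kids) == 0) base else kids[1]
}

#' Brownian-motion phylogenetic covariance structure
#'
#' Entry (i, j) is the depth (My from the root) of the most recent common
#' ancestor of tips i and j; the diagonal holds tip depths. Under BM with
#' rate `sigma2` the trait covariance is `sigma2` times this matrix.
#'
#' @param tree A `phylo` object.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames, units My.
#' @export
bm_vcv <- function(tree) {
  ape::vcv.phylo(tree)
}
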