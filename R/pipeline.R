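# End-to-end orchestration: landmarks -> aligned symmetric species means ->
# tangent PCA -> disparity -> model comparison -> IE rates and morphospace
# frames, with provenance-stamped TSV outputs.

#' Assemble a pipeline configuration
#'
#' @param landmarks Path to a landmark CSV or a [landmark_set()].
#' @param trees Named list of Newick paths or `phylo` objects (topology
#'   variants); a single path/tree is accepted.
#' @param groups Path to a TSV or a tibble with `species_id`, `group`, and
#'   optionally `fossil` (0/1).
#' @param out_dir Output directory for result tables.
#' @param clade_tips Focal-clade tip labels for the shift hypotheses.
#' @param otter_tip Convergent terminal tip for `terrestrial_aquatic`.
#' @param hypotheses Model hypotheses for [compare_models()].
#' @param n_boot Bootstrap replicates for disparity.
#' @param rarefy_to Rarefaction size (NULL disables).
#' @param pc_threshold Percent-variance threshold for PC truncation in model
#'   fits.
#' @param dt Time step (My) for morphospace frames.
#' @param frame_axes PC axes exported in the frames table.
#' @param seed Master seed recorded in all outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks, trees, groups, out_dir = tempdir(),
                            clade_tips = NULL, otter_tip = NULL,
                            hypotheses = c("BM", "one_regime",
                                           "terrestrial_aquatic",
                                           "pinniped_radiation"),
                            n_boot = 1000, rarefy_to = 5, pc_threshold = 95,
                            dt = 1, frame_axes = c("PC1", "PC2"), seed = 1) {
  if (inherits(trees, "phylo") || is.character(trees) && length(trees) == 1) {
    trees <- list(main = trees)
  }
  if (is.null(names(trees))) names(trees) <- paste0("topology", seq_along(trees))
  for (x in list(landmarks, groups)) {
    if (is.character(x) && !file.exists(x)) {
      abort(paste0("input file does not exist: ", x))
    }
  }
  structure(
    list(landmarks = landmarks, trees = trees, groups = groups,
         out_dir = out_dir, clade_tips = clade_tips, otter_tip = otter_tip,
         hypotheses = hypotheses, n_boot = n_boot, rarefy_to = rarefy_to,
         pc_threshold = pc_threshold, dt = dt, frame_axes = frame_axes,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

load_config_inputs <- function(config) {
  lms <- if (is.character(config$landmarks)) {
    read_landmarks(config$landmarks)
  } else config$landmarks
  trees <- purrr::map(config$trees, function(t) {
    if (is.character(t)) read_newick(t) else validate_timetree(t)
  })
  groups <- if (is.character(config$groups)) {
    as_tibble(utils::read.table(config$groups, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
  } else as_tibble(config$groups)
  if (!"fossil" %in% names(groups)) groups$fossil <- FALSE
  groups$fossil <- as.logical(groups$fossil)
  list(landmarks = lms, trees = trees, groups = groups)
}

#' Run the full analysis pipeline
#'
#' Executes mirror-filling, generalized Procrustes superimposition,
#' symmetrization, species means, tangent-space PCA, group disparity with
#' bootstrap and rarefaction (extant species only), AIC model comparison per
#' topology variant, and Independent Evolution rates with multivariate
#' branch distances and morphospace frames. All tables are written to
#' `config$out_dir` with a provenance header (seed, config hash, stage).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate and final result
#'   (`pca`, `disparity`, `models`, `ie` per topology, `frames`, `paths`).
#' @export
run_pipeline <- function(config) {
  inputs <- load_config_inputs(config)
  lms <- inputs$landmarks
  groups <- inputs$groups

  landmark_species <- unique(lms$species_id)
  for (nm in names(inputs$trees)) {
    tips <- inputs$trees[[nm]]$tip.label
    only_tree <- setdiff(tips, landmark_species)
    only_lms <- setdiff(landmark_species, tips)
    if (length(only_tree) > 0 || length(only_lms) > 0) {
      abort(paste0(
        "species mismatch between landmarks and tree `", nm, "`",
        if (length(only_tree)) paste0("; tree-only: ",
                                      paste(only_tree, collapse = ", ")),
        if (length(only_lms)) paste0("; landmarks-only: ",
                                     paste(only_lms, collapse = ", "))))
    }
  }
  bad_groups <- setdiff(groups$species_id, landmark_species)
  if (length(bad_groups) > 0) {
    abort(paste0("group map species absent from landmarks: ",
                 paste(bad_groups, collapse = ", ")))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  prov <- function(stage) {
    c(paste0("seed=", config$seed), paste0("config_hash=", hash),
      paste0("stage=", stage))
  }
  log_lines <- c(
    paste0("morphorates ", as.character(utils::packageVersion("morphorates"))),
    paste0("seed=", config$seed), paste0("config_hash=", hash))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }

  filled <- stage("mirror_fill", mirror_fill(lms))
  aligned <- stage("gpa", gpa(filled))
  sym <- stage("symmetrize", symmetrize(aligned))
  asym <- asymmetry_scores(aligned)
  means <- stage("species_means", species_means(sym))
  pca <- stage("tangent_pca", tangent_pca(means))
  log_lines <- c(log_lines,
                 sprintf("gpa: %d specimens, %d iterations",
                         dim(aligned$coords)[1], aligned$iterations),
                 sprintf("pca: %d species, %d axes", pca$n_species,
                         length(pca$eigenvalues)))

  scores_tbl <- pca_scores(pca)
  write_tsv_provenance(scores_tbl, file.path(config$out_dir, "scores.tsv"),
                       prov("tangent_pca"))
  write_tsv_provenance(tidy(pca, "eigenvalues"),
                       file.path(config$out_dir, "eigenvalues.tsv"),
                       prov("tangent_pca"))
  write_tsv_provenance(asym, file.path(config$out_dir, "asymmetry.tsv"),
                       prov("asymmetry_scores"))

  disp <- stage("disparity", disparity_table(
    pca, groups, n_boot = config$n_boot, rarefy_to = config$rarefy_to,
    exclude_fossils = TRUE, seed = config$seed))
  write_tsv_provenance(disp, file.path(config$out_dir, "disparity.tsv"),
                       prov("disparity_table"))

  models <- stage("compare_models", compare_models(
    pca, inputs$trees, clade_tips = config$clade_tips,
    otter_tip = config$otter_tip, hypotheses = config$hypotheses,
    pc_threshold = config$pc_threshold))
  write_tsv_provenance(models, file.path(config$out_dir, "models.tsv"),
                       prov("compare_models"))
  if (any(!models$converged)) {
    log_lines <- c(log_lines, paste0(
      "non-converged fits: ",
      paste(paste(models$topology, models$hypothesis)[!models$converged],
            collapse = "; ")))
  }

  ie_fits <- purrr::imap(inputs$trees, function(tree, nm) {
    fit <- stage(paste0("ie_rates[", nm, "]"),
                 ie_rates(tree, pca$scores))
    write_tsv_provenance(fit$rates,
                         file.path(config$out_dir,
                                   paste0("branch_rates_", nm, ".tsv")),
                         prov("ie_rates"))
    write_tsv_provenance(fit$distances,
                         file.path(config$out_dir,
                                   paste0("branch_distances_", nm, ".tsv")),
                         prov("ie_rates"))
    write_annotated_newick(fit, file.path(config$out_dir,
                                          paste0("tree_annotated_", nm, ".nwk")))
    fit
  })
  frames <- purrr::imap(inputs$trees, function(tree, nm) {
    fr <- stage(paste0("frames[", nm, "]"), morphospace_frames(
      tree, ie_fits[[nm]]$node_states,
      axes = intersect(config$frame_axes, colnames(pca$scores)),
      dt = config$dt))
    write_tsv_provenance(fr, file.path(config$out_dir,
                                       paste0("frames_", nm, ".tsv")),
                         prov("morphospace_frames"))
    fr
  })

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(
    aligned = aligned, symmetric = sym, means = means, pca = pca,
    asymmetry = asym, disparity = disp, models = models, ie = ie_fits,
    frames = frames, config = config,
    paths = list.files(config$out_dir, full.names = TRUE)))
}

#' Build a self-contained synthetic demonstration
#'
#' Generates a two-clade study design emulating a terrestrial-to-aquatic
#' transition: a large old clade under a `terrestrial` regime, a smaller,
#' younger nested clade under a shifted `aquatic` optimum, one convergent
#' ("otter-like") terminal branch also painted aquatic, and one fossil tip
#' inside the shifted clade. Writes landmark CSV, Newick tree and group map
#' to `dir` and returns a ready [pipeline_config()].
#'
#' @param seed Master seed.
#' @param dir Directory for the generated files.
#' @param n_tips Extant tips in the tree.
#' @param n_traits Simulated trait dimensions.
#' @param model `"OU"` for the shifted-optimum scenario, `"BM"` for a null
#'   scenario with no shift.
#' @param n_boot Bootstrap replicates stored in the config.
#' @return A list with `config` (class `pipeline_config`), `truth`
#'   (`synthetic_truth`), `clade_tips`, `otter_tip` and file `paths`.
#' @export
make_demo <- function(seed = 1, dir = tempfile("morphorates_demo"),
                      n_tips = 24, n_traits = 3, model = c("OU", "BM"),
                      n_boot = 500) {
  model <- match.arg(model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree_height <- 60
  base_spec <- simulation_spec(
    n_tips = n_tips, birth_rate = 0.08, tree_height = tree_height,
    n_traits = n_traits, model = "BM", seed = seed,
    n_specimens_per_species = 2, specimen_noise_sd = 0.015,
    missing_fraction = 0.2)
  extant <- simulate_tree(base_spec)
  clade <- pick_demo_clade(extant, target = max(5L, round(n_tips / 3)))
  otter <- pick_demo_otter(extant, clade)
  fossil_attach <- clade[1]
  fossils <- tibble(attach = fossil_attach, divergence_frac = 0.5,
                    tip_age = NA_real_, label = "fossil01")
  ages <- node_ages(extant)
  parent <- extant$edge[extant$edge[, 2] == match(fossil_attach,
                                                  extant$tip.label), 1]
  div <- 0.5 * ages[parent]
  fossils$tip_age <- div / 2

  # Study conditions: adaptation strong enough that alpha x height ~ 3 and
  # the optimum shift is 5 stationary SDs.
  alpha <- 3 / tree_height
  sigma2 <- 0.01
  shift <- 5 * sqrt(sigma2 / (2 * alpha))
  params <- if (model == "OU") {
    bind_rows(
      tibble(regime = "terrestrial", trait = seq_len(n_traits),
             sigma2 = sigma2, alpha = alpha, theta = 0),
      tibble(regime = "aquatic", trait = seq_len(n_traits),
             sigma2 = sigma2, alpha = alpha,
             theta = shift * c(1, -0.5, 0.25)[seq_len(n_traits)]))
  } else {
    tibble(regime = c("terrestrial", "aquatic")[rep(1:2, each = n_traits)],
           trait = rep(seq_len(n_traits), 2), sigma2 = sigma2, alpha = 0,
           theta = 0)
  }
  spec <- simulation_spec(
    n_tips = n_tips, birth_rate = 0.08, tree_height = tree_height,
    n_traits = n_traits, model = model, params = params, fossils = fossils,
    seed = seed, n_specimens_per_species = 2, specimen_noise_sd = 0.015,
    missing_fraction = 0.2)
  tree <- simulate_tree(spec)
  clade_full <- c(clade, "fossil01")
  painting <- paint_regimes(tree, "terrestrial_aquatic",
                            clade_tips = clade_full, otter_tip = otter)
  tr <- simulate_traits(tree, spec, painting = painting)
  lms <- traits_to_landmarks(tr$traits, spec)

  lm_path <- file.path(dir, "landmarks.csv")
  tree_path <- file.path(dir, "tree.nwk")
  groups_path <- file.path(dir, "groups.tsv")
  write_landmarks(lms, lm_path)
  write_newick(tree, tree_path)
  groups <- tibble(
    species_id = tree$tip.label,
    group = ifelse(tree$tip.label %in% c(clade_full, otter), "aquatic",
                   "terrestrial"),
    fossil = as.integer(tree$tip.label == "fossil01"))
  utils::write.table(groups, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_truth(tr$truth, file.path(dir, "truth.tsv"))

  config <- pipeline_config(
    landmarks = lm_path, trees = list(main = tree_path), groups = groups_path,
    out_dir = file.path(dir, "results"), clade_tips = clade_full,
    otter_tip = otter, n_boot = n_boot, rarefy_to = 5, dt = 2, seed = seed)
  list(config = config, truth = tr$truth, clade_tips = clade_full,
       otter_tip = otter, tree = tree,
       paths = c(landmarks = lm_path, tree = tree_path, groups = groups_path))
}

# Choose a young, mid-sized clade to play the transitioned group.
pick_demo_clade <- function(tree, target = 8L) {
  n_tip <- length(tree$tip.label)
  ages <- node_ages(tree)
  internal <- (n_tip + 2L):(n_tip + tree$Nnode)  # exclude the root
  best <- NULL; best_score <- Inf
  for (node in internal) {
    tips <- clade_descendant_nodes(tree, node)
    tips <- tips[tips <= n_tip]
    size <- length(tips)
    if (size < 3 || size > n_tip - 5) next
    score <- abs(size - target) + ages[node] / max(ages)
    if (score < best_score) {
      best_score <- score
      best <- tree$tip.label[tips]
    }
  }
  if (is.null(best)) abort("no suitable clade found; increase n_tips")
  best
}

# A terminal branch well outside the focal clade, playing the convergent
# semi-aquatic taxon.
pick_demo_otter <- function(tree, clade) {
  candidates <- setdiff(tree$tip.label, clade)
  candidates[length(candidates)]
}
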