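# Synthetic-data generator: trees, exact-transition traits, landmark rendering.

test_that("simulation is deterministic in the seed and stages are independent", {
  spec <- simulation_spec(n_tips = 8, seed = 42, n_specimens_per_species = 2)
  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  expect_equal(d1$traits, d2$traits)
  expect_equal(as.data.frame(d1$landmarks), as.data.frame(d2$landmarks))
  expect_equal(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  # a different seed changes the outcome
  d3 <- simulate_dataset(simulation_spec(n_tips = 8, seed = 43,
                                         n_specimens_per_species = 2))
  expect_false(isTRUE(all.equal(d1$traits, d3$traits)))
  # changing a downstream knob (specimen noise) leaves the tree and traits
  # untouched: stages draw from independent named substreams
  spec4 <- simulation_spec(n_tips = 8, seed = 42, n_specimens_per_species = 2,
                           specimen_noise_sd = 0.1)
  d4 <- simulate_dataset(spec4)
  expect_equal(ape::write.tree(d4$tree), ape::write.tree(d1$tree))
  expect_equal(d4$traits, d1$traits)
})

test_that("trees honour n_tips, tree_height, and fossil grafts", {
  fossils <- tibble::tibble(attach = "t001", divergence_frac = 0.5,
                            tip_age = 1, label = "fossil01")
  spec <- simulation_spec(n_tips = 10, tree_height = 60, fossils = fossils,
                          seed = 7)
  tr <- simulate_tree(spec)
  expect_equal(ape::Ntip(tr), 11L)
  expect_true("fossil01" %in% tr$tip.label)
  expect_equal(max(node_depths(tr)), 60, tolerance = 1e-9)
  ages <- node_ages(tr)
  expect_equal(unname(ages["fossil01"]), 1, tolerance = 1e-8)
  expect_true(all(tr$edge.length > 0))
})

test_that("BM transition sampling has the exact conditional moments", {
  n <- 40000
  withr::with_seed(55, {
    x_bm <- vapply(seq_len(n), function(i) {
      morphorates:::transition_sample(2, t = 4, sigma2 = 0.5, alpha = 0,
                                      theta = 99)
    }, numeric(1))
  })
  expect_equal(mean(x_bm), 2, tolerance = 0.05)
  expect_equal(var(x_bm), 0.5 * 4, tolerance = 0.08)
})

test_that("OU transition sampling has the exact conditional moments", {
  n <- 40000
  alpha <- 0.3; t <- 4; sigma2 <- 0.5; theta <- 1; parent <- 3
  withr::with_seed(56, {
    x_ou <- vapply(seq_len(n), function(i) {
      morphorates:::transition_sample(parent, t, sigma2, alpha, theta)
    }, numeric(1))
  })
  expect_equal(mean(x_ou), theta + (parent - theta) * exp(-alpha * t),
               tolerance = 0.02)
  expect_equal(var(x_ou), sigma2 * (1 - exp(-2 * alpha * t)) / (2 * alpha),
               tolerance = 0.03)
})

test_that("tip covariance across replicates matches sigma2 * bm_vcv under BM", {
  tr <- random_tree(5, seed = 201)
  n_rep <- 400
  sims <- vapply(seq_len(n_rep), function(r) {
    spec <- simulation_spec(n_tips = 5, n_traits = 1, seed = 10000 + r)
    simulate_traits(tr, spec)$traits[, 1]
  }, numeric(5))
  emp <- cov(t(sims))
  expect_equal(unname(emp), unname(bm_vcv(tr)), tolerance = 0.35)
})

test_that("an OU regime shift displaces clade tips toward the shifted optimum", {
  tr <- random_tree(20, seed = 203)
  # choose a clade of a few tips
  anc <- ape::getMRCA(tr, c("t001", "t002"))
  clade <- tr$tip.label[morphorates:::clade_descendant_nodes(tr, anc)]
  clade <- clade[!is.na(clade)]
  clade <- intersect(tr$tip.label, clade)
  H <- max(node_depths(tr))
  params <- tidyr::expand_grid(regime = c("ancestral", "shifted"), trait = 1L)
  params$sigma2 <- 0.05
  params$alpha <- 5 / H
  params$theta <- ifelse(params$regime == "shifted", 4, 0)
  painting <- paint_regimes(tr, "pinniped_radiation", clade_tips = clade)
  painting$regime <- ifelse(painting$regime == "shifted", "shifted", "ancestral")
  means <- vapply(1:30, function(r) {
    spec <- simulation_spec(n_tips = 20, model = "OU", n_traits = 1,
                            params = params, seed = 20000 + r)
    tips <- simulate_traits(tr, spec, painting = painting)$traits[, 1]
    c(mean(tips[clade]), mean(tips[setdiff(tr$tip.label, clade)]))
  }, numeric(2))
  expect_gt(mean(means[1, ]), mean(means[2, ]) + 1)
  expect_lt(abs(mean(means[2, ])), 1)
})

test_that("ground truth is internally consistent", {
  spec <- simulation_spec(n_tips = 7, seed = 71)
  tr <- simulate_tree(spec)
  out <- simulate_traits(tr, spec)
  truth <- out$truth
  expect_s3_class(truth, "synthetic_truth")
  # tips slice of node_states equals the returned trait matrix
  expect_equal(out$traits, truth$node_states[tr$tip.label, , drop = FALSE])
  # displacement rows equal child - parent states
  d <- truth$displacement
  st <- truth$node_states
  expect_equal(d$trait1,
               unname(st[d$child, "trait1"] - st[d$parent, "trait1"]))
  # TSV round trip of the truth table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  back <- read_tsv_provenance(path)
  expect_equal(back$trait1, unname(st[, "trait1"]), tolerance = 1e-12)
})

test_that("landmark rendering encodes traits recoverably despite nuisance transforms", {
  # Two species that differ only in trait values: after GPA, the Procrustes
  # distance between species means reflects the trait-space distance.
  spec <- simulation_spec(n_tips = 6, n_traits = 2, seed = 301,
                          specimen_noise_sd = 0, n_specimens_per_species = 1,
                          nuisance_transforms = TRUE)
  traits <- rbind(a = c(0, 0), b = c(0.3, 0), c = c(0.6, 0))
  lms <- traits_to_landmarks(traits, spec)
  g <- gpa(lms)
  d_ab <- procrustes_distance(g$coords[1, , ], g$coords[2, , ])
  d_ac <- procrustes_distance(g$coords[1, , ], g$coords[3, , ])
  expect_gt(d_ab, 0.01)
  # twice the trait displacement gives roughly twice the shape distance
  expect_equal(d_ac / d_ab, 2, tolerance = 0.15)
})

test_that("the trait basis is orthonormal, symmetric, and survives superimposition", {
  tmpl <- morphorates:::template_array(default_landmark_template())
  basis <- morphorates:::make_basis(tmpl, 3, seed = 5)
  expect_equal(unname(crossprod(basis)), diag(3), tolerance = 1e-10)
  K <- nrow(tmpl$coords)
  for (j in 1:3) {
    v <- matrix(basis[, j], K, 3)
    # bilaterally symmetric displacement field
    expect_equal(morphorates:::reflect_relabel(v, tmpl$pairs), v,
                 tolerance = 1e-10)
    # orthogonal to translations and to uniform scaling of the template
    expect_lt(max(abs(colSums(v))), 1e-10)
    X0 <- morphorates:::center_config(tmpl$coords)
    expect_lt(abs(sum(v * X0)), 1e-10)
  }
})

test_that("missing_fraction removes whole sides at roughly the requested rate", {
  spec <- simulation_spec(n_tips = 12, seed = 91, missing_fraction = 0.5,
                          n_specimens_per_species = 6)
  d <- simulate_dataset(spec)
  lm <- d$landmarks
  by_spec <- split(lm$missing, lm$specimen_id)
  frac_missing <- mean(vapply(by_spec, any, logical(1)))
  expect_gt(frac_missing, 0.3)
  expect_lt(frac_missing, 0.7)
  # each affected specimen misses exactly one full side (4 paired landmarks)
  n_miss <- vapply(by_spec, sum, integer(1))
  expect_true(all(n_miss %in% c(0L, 4L)))
  sides <- split(lm$side[lm$missing], lm$specimen_id[lm$missing])
  expect_true(all(vapply(sides, function(s) length(unique(s)) == 1, logical(1))))
})

test_that("invalid specifications are rejected", {
  expect_error(simulation_spec(n_tips = 2), "n_tips")
  expect_error(simulation_spec(birth_rate = 0), "birth_rate")
  expect_error(simulation_spec(missing_fraction = 1.5), "missing_fraction")
  bad <- tidyr::expand_grid(regime = "global", trait = 1:2)
  bad$sigma2 <- c(1, -1); bad$alpha <- 0; bad$theta <- 0
  expect_error(simulation_spec(n_traits = 2, params = bad), "sigma2")
  # painting regimes must exist in params
  spec <- simulation_spec(n_tips = 5, seed = 1)
  tr <- simulate_tree(spec)
  painting <- paint_regimes(tr, "BM")  # regime label "none" not in params
  expect_error(simulate_traits(tr, spec, painting = painting), "regimes absent")
})
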