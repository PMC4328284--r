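# Maximum-likelihood BM and multi-optima OU fits, AIC comparison.

test_that("BM fit matches the closed form on a two-tip star", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  y <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "trait1"))
  fit <- fit_bm(tr, y)
  # GLS root = mean = 1; sigma2 = [(0-1)^2 + (2-1)^2]/2 / 1 = 1
  expect_equal(fit$params$root_state, 1)
  expect_equal(fit$params$sigma2, 1)
  expect_equal(fit$n_params, 2L)
  expect_equal(fit$AIC, 2 * 2 - 2 * fit$logLik)
  # logLik equals the bivariate normal density at the ML parameters
  S <- 1 * bm_vcv(tr)
  expect_equal(fit$logLik, oracle_dmvnorm2(c(0, 2), c(1, 1), S),
               tolerance = 1e-9)
})

test_that("BM logLik matches the multivariate normal density on random trees", {
  for (s in c(301, 302)) {
    tr <- random_tree(6, seed = s)
    withr::with_seed(s + 1, {
      y <- matrix(rnorm(6), 6, 1, dimnames = list(tr$tip.label, "trait1"))
    })
    fit <- fit_bm(tr, y)
    C <- bm_vcv(tr)
    S <- fit$params$sigma2 * C
    mu <- rep(fit$params$root_state, 6)
    r <- y[, 1] - mu
    ll <- -3 * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
      0.5 * sum(r * solve(S, r))
    expect_equal(fit$logLik, ll, tolerance = 1e-8)
    # ML sigma2 is a stationary point: nearby values do worse
    ll_at <- function(s2) {
      -3 * log(2 * pi) - 0.5 * determinant(s2 * C)$modulus[1] -
        0.5 * sum(r * solve(s2 * C, r))
    }
    expect_gt(fit$logLik, ll_at(fit$params$sigma2 * 1.05))
    expect_gt(fit$logLik, ll_at(fit$params$sigma2 * 0.95))
  }
})

test_that("degenerate BM data hits the sigma2 boundary with a warning", {
  tr <- random_tree(5, seed = 311)
  y <- matrix(1, 5, 1, dimnames = list(tr$tip.label, "trait1"))
  expect_warning(fit <- fit_bm(tr, y), "boundary")
  expect_false(is.finite(fit$params$logLik[1]) && fit$params$sigma2[1] > 0)
})

test_that("single-regime OU at alpha -> 0 approaches the BM likelihood", {
  tr <- random_tree(8, seed = 321)
  withr::with_seed(322, {
    y <- matrix(rnorm(8), 8, 1, dimnames = list(tr$tip.label, "trait1"))
  })
  painting <- paint_regimes(tr, "one_regime")
  bm <- fit_bm(tr, y)
  # profile the OU likelihood directly at a tiny alpha
  depths <- node_depths(tr)
  tip_depths <- depths[1:8]
  paths <- morphorates:::tip_paths(tr, painting)
  W_fun <- function(a) morphorates:::hansen_weights(
    a, paths, tip_depths, "global", "global")
  V0_fun <- function(a) morphorates:::ou_vcv0(a, bm_vcv(tr), tip_depths)
  prof <- morphorates:::ou_profile(1e-8, y[, 1], W_fun, V0_fun)
  # as alpha -> 0 the OU model nests BM with a free root, so its profiled
  # likelihood cannot fall below BM's and converges to it
  expect_equal(prof$logLik, bm$logLik, tolerance = 1e-4)
})

test_that("two-regime OU matches a hand-built density on a two-tip tree", {
  tr <- ape::read.tree(text = "(a:2,b:2);")
  # paint the branch to `b` as shifted
  painting <- paint_regimes(tr, "pinniped_radiation", clade_tips = "b")
  y_vals <- c(a = 0.4, b = 2.2)
  alpha <- 0.7; sigma2 <- 0.3
  th <- c(ancestral = 0.1, shifted = 2.5)
  # Hansen expectations: root at ancestral optimum
  mu_a <- th["ancestral"]
  mu_b <- th["ancestral"] * exp(-alpha * 2) + th["shifted"] * (1 - exp(-alpha * 2))
  # two-tip OU covariance (MRCA at the root, depth 0): independent tips
  v <- sigma2 * (1 - exp(-2 * alpha * 2)) / (2 * alpha)
  ll_hand <- sum(dnorm(y_vals, mean = c(mu_a, mu_b), sd = sqrt(v), log = TRUE))
  # package internals at the same (alpha, theta, sigma2):
  depths <- node_depths(tr)
  paths <- morphorates:::tip_paths(tr, painting)
  W <- morphorates:::hansen_weights(alpha, paths, depths[1:2],
                                    c("ancestral", "shifted"), "ancestral")
  V0 <- morphorates:::ou_vcv0(alpha, bm_vcv(tr), depths[1:2])
  mu_pkg <- as.numeric(W %*% th)
  S <- sigma2 * V0
  ll_pkg <- sum(dnorm(y_vals, mean = mu_pkg, sd = sqrt(diag(S)), log = TRUE))
  expect_equal(mu_pkg, unname(c(mu_a, mu_b)), tolerance = 1e-12)
  expect_lt(max(abs(S[1, 2]), abs(S[2, 1])), 1e-12)
  expect_equal(ll_pkg, ll_hand, tolerance = 1e-12)
})

test_that("fit_ou recovers a strong simulated two-regime shift", {
  H <- 50
  spec <- simulation_spec(n_tips = 40, tree_height = H, seed = 401)
  tr <- simulate_tree(spec)
  # focal clade: descendants of one child of the root (monophyletic, >3 tips)
  root <- length(tr$tip.label) + 1L
  kid <- tr$edge[tr$edge[, 1] == root, 2][1]
  clade <- tr$tip.label[intersect(seq_along(tr$tip.label),
                                  morphorates:::clade_descendant_nodes(tr, kid))]
  painting <- paint_regimes(tr, "pinniped_radiation", clade_tips = clade)
  alpha_true <- 4 / H; sigma2_true <- 0.05
  sd_stat <- sqrt(sigma2_true / (2 * alpha_true))
  theta_shift <- 6 * sd_stat
  params <- tidyr::expand_grid(regime = c("ancestral", "shifted"), trait = 1L)
  params$sigma2 <- sigma2_true
  params$alpha <- alpha_true
  params$theta <- ifelse(params$regime == "shifted", theta_shift, 0)
  spec_ou <- simulation_spec(n_tips = 40, model = "OU", n_traits = 1,
                             params = params, seed = 402)
  y <- simulate_traits(tr, spec_ou, painting = painting)$traits
  fit <- fit_ou(tr, y, painting)
  expect_true(fit$converged)
  th_hat <- fit$params$theta[match(c("ancestral", "shifted"),
                                   fit$params$regime)]
  expect_lt(abs(th_hat[1] - 0), 1.5 * sd_stat)
  expect_lt(abs(th_hat[2] - theta_shift), 1.5 * sd_stat)
  expect_gt(th_hat[2] - th_hat[1], 3 * sd_stat)
  expect_equal(fit$n_params, 1L * (2L + 2L))
})

test_that("compare_models tabulates AIC coherently across topologies", {
  d <- make_demo(seed = 5, dir = withr::local_tempdir(), n_boot = 100)
  m <- d$truth$node_states[d$tree$tip.label, , drop = FALSE]
  trees <- list(reference = d$tree, alternative = d$tree)
  cmp <- compare_models(m, trees, clade_tips = d$clade_tips,
                        otter_tip = d$otter_tip)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(nrow(cmp), 8L)  # 2 topologies x 4 hypotheses
  for (topo in unique(cmp$topology)) {
    sub <- cmp[cmp$topology == topo, ]
    expect_equal(min(sub$delta_AIC), 0)
    expect_equal(sum(sub$best), 1L)
    expect_equal(sub$AIC, 2 * sub$n_params - 2 * sub$logLik)
    # identical trees give identical fits across "topologies"
  }
  expect_equal(cmp$AIC[cmp$topology == "reference"],
               cmp$AIC[cmp$topology == "alternative"])
  # BM is nested in one_regime OU: OU logLik cannot be lower (up to tol)
  expect_gte(cmp$logLik[cmp$topology == "reference" &
                          cmp$hypothesis == "one_regime"],
             cmp$logLik[cmp$topology == "reference" &
                          cmp$hypothesis == "BM"] - 1e-4)
  pl <- ggplot2::autoplot(cmp)
  expect_s3_class(pl, "ggplot")
})

test_that("species mismatches between scores and tree are reported", {
  tr <- random_tree(5, seed = 501)
  y <- matrix(rnorm(5), 5, 1,
              dimnames = list(c(tr$tip.label[-1], "zzz"), "trait1"))
  expect_error(fit_bm(tr, y), "zzz")
  expect_error(fit_bm(tr, y), tr$tip.label[1])
})
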