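# Independent Evolution: gradual expectations, barycentres, rates, frames.

test_that("gradual expectations match the hand example on a 4-node tree", {
  tr <- ape::read.tree(text = "((b:1,c:1)n:1,a:1);")
  tips <- c(a = 0, b = 2, c = 4)
  g <- gradual_expectations(tr, tips)
  # interior node n: neighbours b (2), c (4), root; root: neighbours n, a (0)
  # with unit lengths: n = (2 + 4 + R)/3, R = (n + 0)/2 -> n = 2.4, R = 1.2
  expect_equal(unname(g["5", 1]), 2.4, tolerance = 1e-10)  # n
  expect_equal(unname(g["4", 1]), 1.2, tolerance = 1e-10)  # root
  expect_equal(unname(g[c("a", "b", "c"), 1]), c(0, 2, 4))
})

test_that("gradual expectations match a dense WLS oracle on random trees", {
  for (s in 601:606) {
    n <- sample(5:20, 1)
    tr <- random_tree(n, seed = s)
    withr::with_seed(s + 1000, tips <- stats::setNames(rnorm(n), tr$tip.label))
    g <- gradual_expectations(tr, tips)
    oracle <- oracle_gradual(tr, tips)
    expect_equal(unname(g[(n + 1):(n + tr$Nnode), 1]), oracle,
                 tolerance = 1e-5)
  }
})

test_that("ie_barycentre solves the weighted three-point problem", {
  # Minimizer of (b-A)^2/la + (v1-b)^2/l1 + (v2-b)^2/l2 found numerically
  A <- 1; la <- 2; v1 <- 4; l1 <- 1; v2 <- -2; l2 <- 0.5
  f <- function(b) (b - A)^2 / la + (v1 - b)^2 / l1 + (v2 - b)^2 / l2
  num <- stats::optimize(f, c(-10, 10), tol = 1e-12)$minimum
  tri <- ie_barycentre(A, la, v1, l1, v2, l2)
  expect_equal(tri$barycentre, num, tolerance = 1e-6)
  expect_equal(tri$r1, abs(v1 - tri$barycentre))
  expect_equal(tri$r2, abs(v2 - tri$barycentre))
  # root case: ancestor omitted
  tri0 <- ie_barycentre(NA, NA, 4, 1, -2, 1)
  expect_equal(tri0$barycentre, 1)
  expect_error(ie_barycentre(1, 0, 4, 1, -2, 1), "> 0")
})

test_that("ie_rates reproduces the worked example on the 4-node tree", {
  tr <- ape::read.tree(text = "((b:1,c:1)n:1,a:1);")
  tips <- c(a = 0, b = 2, c = 4)
  fit <- ie_rates(tr, tips)
  # post-order: node n uses gradual(n) = 2.4 as its own anchor
  # n barycentre = (2.4 + 2 + 4)/3 = 2.8; root = (0 + 2.8)/2 = 1.4
  expect_equal(unname(fit$node_states["5", 1]), 2.8, tolerance = 1e-10)
  expect_equal(unname(fit$node_states["4", 1]), 1.4, tolerance = 1e-10)
  rates <- fit$rates
  key <- paste(rates$parent, rates$child)
  expect_equal(rates$rate[key == "4 5"], 1.4, tolerance = 1e-10)  # root -> n
  expect_equal(rates$rate[key == "5 1"], 0.8, tolerance = 1e-10)  # n -> b
  expect_equal(rates$rate[key == "5 2"], 1.2, tolerance = 1e-10)  # n -> c
  expect_equal(rates$rate[key == "4 3"], 1.4, tolerance = 1e-10)  # root -> a
  expect_equal(rates$rate_per_my, rates$rate / rates$branch_length)
})

test_that("multivariate distances equal the per-trait Euclidean norm", {
  tr <- random_tree(8, seed = 611)
  withr::with_seed(612, {
    y <- matrix(rnorm(24), 8, 3,
                dimnames = list(tr$tip.label, paste0("PC", 1:3)))
  })
  fit <- ie_rates(tr, y)
  d <- fit$distances
  for (e in seq_len(nrow(d))) {
    per_trait <- fit$rates$rate[fit$rates$parent == d$parent[e] &
                                  fit$rates$child == d$child[e]]
    expect_equal(d$displacement[e], sqrt(sum(per_trait^2)), tolerance = 1e-12)
  }
  expect_equal(d$displacement_per_my, d$displacement / d$branch_length)
})

test_that("a tenfold burst branch carries a conspicuous IE rate", {
  tr <- random_tree(30, seed = 621)
  spec <- simulation_spec(n_tips = 30, n_traits = 1, seed = 622)
  sim <- simulate_traits(tr, spec)
  st <- sim$truth$node_states
  # inject a large displacement on one terminal branch
  burst_tip <- "t007"
  y <- st[tr$tip.label, 1]
  disp_scale <- stats::sd(y)
  y[burst_tip] <- y[burst_tip] + 8 * disp_scale
  fit <- ie_rates(tr, stats::setNames(y, names(y)))
  rates <- fit$rates
  burst_rate <- rates$rate_per_my[rates$child == match(burst_tip, tr$tip.label)]
  expect_gte(mean(rates$rate_per_my <= burst_rate), 0.95)
})

test_that("morphospace frames interpolate linearly and bracket the data", {
  tr <- ape::read.tree(text = "((b:1,c:1)n:1,a:2);")
  st <- matrix(c(0, 2, 4, 1, 3), 5, 1,
               dimnames = list(c("b", "c", "a", "4", "5"), "PC1"))
  # node ids: tips b=1, c=2, a=3; root=4; n=5
  fr <- morphospace_frames(tr, st, dt = 0.5)
  expect_s3_class(fr, "morphospace_frames")
  # root frame: single point with the root state
  top <- fr[fr$time == 2, ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$PC1, 1)
  # at t = 0.5: branches root->a (1 -> 4 over [2,0], frac 0.75) and
  # n->b, n->c (3 -> 0 / 3 -> 2 over [1,0], frac 0.5)
  mid <- fr[fr$time == 0.5, ]
  expect_equal(sort(mid$PC1), sort(c(1 + 0.75 * (4 - 1), 1.5, 2.5)),
               tolerance = 1e-12)
  # present-day frame equals tip values
  now <- fr[fr$time == 0, ]
  expect_equal(sort(now$PC1), c(0, 2, 4))
  pl <- ggplot2::autoplot(fr, axes = c("PC1", "PC1"))
  expect_s3_class(pl, "ggplot")
  expect_error(morphospace_frames(tr, st, dt = 0), "dt")
  expect_error(morphospace_frames(tr, st, dt = 10), "height")
})

test_that("annotated Newick round-trips topology and carries displacements", {
  tr <- random_tree(6, seed = 631)
  withr::with_seed(632, {
    y <- matrix(rnorm(12), 6, 2,
                dimnames = list(tr$tip.label, c("PC1", "PC2")))
  })
  fit <- ie_rates(tr, y)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_newick(fit, path)
  txt <- readLines(path)
  expect_match(txt, "&displacement=")
  # stripping the comments yields the same tree
  clean <- gsub("\\[&displacement=[^]]*\\]", "", txt)
  back <- ape::read.tree(text = clean)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(unname(bm_vcv(back)[tr$tip.label, tr$tip.label]),
               unname(bm_vcv(tr)), tolerance = 1e-6)
  # every non-root branch is annotated
  expect_equal(lengths(regmatches(txt, gregexpr("displacement=", txt))),
               nrow(tr$edge))
})

test_that("ie_rates validates its inputs", {
  tr <- random_tree(5, seed = 641)
  y <- stats::setNames(rnorm(5), tr$tip.label)
  names(y)[1] <- "wrong"
  expect_error(ie_rates(tr, y), "mismatch")
  poly <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")
  expect_error(ie_rates(poly, c(a = 1, b = 2, c = 3, d = 4)), "bifurcating")
})
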