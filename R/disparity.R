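# Morphological disparity: sum of per-axis score ranges (range-based) and
# mean multivariate distance to the group centroid (variance-based), with
# bootstrap confidence intervals and rarefaction to a fixed sample size.

scores_matrix <- function(scores) {
  if (inherits(scores, "shape_pca")) return(scores$scores)
  as_trait_matrix(scores)
}

#' Sum of ranges across all axes
#'
#' Range-based disparity: the sum over every axis of (max - min) score.
#' Sensitive to outliers and sample size.
#'
#' @param scores Species x m score matrix (or `shape_pca`, or tibble with a
#'   `species_id` column). All axes are used.
#' @return A non-negative scalar in score units.
#' @export
sum_of_ranges <- function(scores) {
  m <- scores_matrix(scores)
  if (nrow(m) == 0) abort("empty group")
  sum(apply(m, 2, function(v) max(v) - min(v)))
}

#' Mean multivariate distance to the group centroid
#'
#' Variance-based disparity: the mean over species of the Euclidean distance
#' (across all axes) to the group mean vector. Robust to sample-size bias.
#'
#' @inheritParams sum_of_ranges
#' @return A non-negative scalar in score units.
#' @export
mean_dist_centroid <- function(scores) {
  m <- scores_matrix(scores)
  if (nrow(m) == 0) abort("empty group")
  ctr <- colMeans(m)
  mean(sqrt(rowSums(sweep(m, 2, ctr)^2)))
}

boot_summary <- function(values, level = 0.95) {
  qs <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(mean = mean(values), lower = qs[1], upper = qs[2])
}

#' Bootstrap a disparity metric
#'
#' Resamples species with replacement to the original sample size `n_boot`
#' times and reports the replicate mean and percentile 95% interval.
#'
#' @inheritParams sum_of_ranges
#' @param metric A disparity function of a score matrix, e.g.
#'   [sum_of_ranges()] or [mean_dist_centroid()].
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return A tibble with `boot_mean`, `lower95`, `upper95`, `n_boot`, `seed`.
#' @export
bootstrap_disparity <- function(scores, metric = sum_of_ranges, n_boot = 1000,
                                seed = 1) {
  m <- scores_matrix(scores)
  if (n_boot < 100) abort("n_boot must be >= 100")
  n <- nrow(m)
  reps <- with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      metric(m[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  s <- boot_summary(reps)
  tibble(boot_mean = s$mean, lower95 = s$lower, upper95 = s$upper,
         n_boot = n_boot, seed = seed)
}

#' Rarefy a disparity metric to a fixed sample size
#'
#' Each replicate draws `m` species (with replacement by default, mirroring
#' a bootstrap-style rarefaction; set `replace = FALSE` for classical
#' subsampling) and computes the metric.
#'
#' @inheritParams bootstrap_disparity
#' @param m Rarefied sample size (<= number of species).
#' @param replace Sample with replacement?
#' @return A tibble with `boot_mean`, `lower95`, `upper95`, `n_boot`,
#'   `rarefaction_size`, `seed`.
#' @export
rarefy_disparity <- function(scores, metric = sum_of_ranges, m = 5,
                             n_boot = 1000, replace = TRUE, seed = 1) {
  sm <- scores_matrix(scores)
  n <- nrow(sm)
  if (m > n) abort("rarefaction size m exceeds the number of species")
  if (m < 2 && identical(metric, mean_dist_centroid)) {
    warn("rarefying the centroid metric to m < 2: a single point has zero distance to its own centroid")
  }
  reps <- with_seed(substream_seed(seed, "rarefy"), {
    vapply(seq_len(n_boot), function(i) {
      metric(sm[sample.int(n, m, replace = replace), , drop = FALSE])
    }, numeric(1))
  })
  s <- boot_summary(reps)
  tibble(boot_mean = s$mean, lower95 = s$lower, upper95 = s$upper,
         n_boot = n_boot, rarefaction_size = m, seed = seed)
}

#' Group disparity table
#'
#' Computes, per group, the observed sum of ranges and mean distance to
#' centroid with bootstrap 95% intervals, plus (optionally) rarefied rows for
#' groups larger than `rarefy_to`.
#'
#' @param scores Species x m scores (matrix, `shape_pca`, or tibble with
#'   `species_id`).
#' @param groups Tibble with `species_id`, `group`, and optionally `fossil`
#'   (logical); fossil species are excluded when `exclude_fossils = TRUE`.
#' @param n_boot Bootstrap replicates.
#' @param rarefy_to Rarefaction sample size; `NULL` disables rarefied rows.
#' @param rarefy_groups Groups to rarefy (default: all groups with more than
#'   `rarefy_to` species).
#' @param exclude_fossils Drop species flagged `fossil` before computing
#'   disparity.
#' @param seed RNG seed.
#' @return A tibble of class `disparity_table`: one row per group (and per
#'   rarefied group), columns `group`, `n`, `rarefied`, `sum_of_ranges`,
#'   `sor_lower95`, `sor_upper95`, `mean_dist_centroid`, `mdc_lower95`,
#'   `mdc_upper95`, `n_boot`, `seed`.
#' @export
disparity_table <- function(scores, groups, n_boot = 1000, rarefy_to = 5,
                            rarefy_groups = NULL, exclude_fossils = TRUE,
                            seed = 1) {
  m <- scores_matrix(scores)
  groups <- as_tibble(groups)
  unknown <- setdiff(groups$species_id, rownames(m))
  if (length(unknown) > 0) {
    abort(paste0("group map species absent from scores: ",
                 paste(unknown, collapse = ", ")))
  }
  if (exclude_fossils && "fossil" %in% names(groups)) {
    groups <- groups[!as.logical(groups$fossil), , drop = FALSE]
  }
  if (nrow(groups) == 0) abort("empty group map")
  glist <- split(groups$species_id, groups$group)

  one_row <- function(label, sp, rarefied_m = NA_integer_) {
    sub <- m[sp, , drop = FALSE]
    if (is.na(rarefied_m)) {
      sor <- bootstrap_disparity(sub, sum_of_ranges, n_boot, seed)
      mdc <- bootstrap_disparity(sub, mean_dist_centroid, n_boot, seed)
      sor_obs <- sum_of_ranges(sub)
      mdc_obs <- mean_dist_centroid(sub)
    } else {
      sor <- rarefy_disparity(sub, sum_of_ranges, rarefied_m, n_boot, seed = seed)
      mdc <- rarefy_disparity(sub, mean_dist_centroid, rarefied_m, n_boot,
                              seed = seed)
      sor_obs <- sor$boot_mean
      mdc_obs <- mdc$boot_mean
    }
    tibble(group = label, n = length(sp), rarefied = !is.na(rarefied_m),
           rarefaction_size = rarefied_m,
           sum_of_ranges = sor_obs, sor_boot_mean = sor$boot_mean,
           sor_lower95 = sor$lower95, sor_upper95 = sor$upper95,
           mean_dist_centroid = mdc_obs, mdc_boot_mean = mdc$boot_mean,
           mdc_lower95 = mdc$lower95, mdc_upper95 = mdc$upper95,
           n_boot = n_boot, seed = seed)
  }

  rows <- purrr::imap(glist, function(sp, label) one_row(label, sp))
  if (!is.null(rarefy_to)) {
    to_rarefy <- rarefy_groups %||%
      names(glist)[vapply(glist, length, integer(1)) > rarefy_to]
    rare <- purrr::map(to_rarefy, function(label) {
      one_row(label, glist[[label]], rarefied_m = as.integer(rarefy_to))
    })
    rows <- c(rows, rare)
  }
  out <- list_rbind(rows)
  class(out) <- c("disparity_table", class(tibble()))
  out
}

#' Plot a disparity table
#'
#' Point estimates with bootstrap intervals for both metrics, one panel per
#' metric.
#'
#' @param object A `disparity_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disparity_table <- function(object, ...) {
  df <- bind_rows(
    tibble(group = object$group, rarefied = object$rarefied,
           metric = "sum of ranges", value = object$sum_of_ranges,
           lower = object$sor_lower95, upper = object$sor_upper95),
    tibble(group = object$group, rarefied = object$rarefied,
           metric = "mean dist. to centroid", value = object$mean_dist_centroid,
           lower = object$mdc_lower95, upper = object$mdc_upper95))
  df$label <- ifelse(df$rarefied, paste0(df$group, " (rarefied)"), df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "disparity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
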