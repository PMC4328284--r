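# Bundled reference table: the carnivoran museum-sampling scheme of the
# motivating case study (fissiped vs pinniped skulls), used for taxonomic
# sampling-coverage arithmetic and as a realistic group map template.

#' Carnivoran cranial sampling scheme
#'
#' One row per sampled species: `group` (Fissiped/Pinniped), `family`,
#' `species`, `n_specimens` digitized, and `fossil` (logical).
#'
#' @return A tibble.
#' @export
carnivora_sampling <- function() {
  path <- system.file("extdata", "carnivora_sampling.tsv",
                      package = "morphorates", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df$fossil <- as.logical(df$fossil)
  as_tibble(df)
}

#' Extant taxonomic richness of the two carnivoran grades
#'
#' Literature richness figures used as denominators for sampling coverage:
#' fissipeds span 10 families, 105 genera, 241 species; pinnipeds 3
#' families, 21 genera, 36 species.
#'
#' @return A tibble with `group`, `n_families`, `n_genera`, `n_species`.
#' @export
carnivora_richness <- function() {
  tibble(group = c("Fissiped", "Pinniped"),
         n_families = c(10L, 3L),
         n_genera = c(105L, 21L),
         n_species = c(241L, 36L))
}

#' Sampling coverage of the carnivoran scheme
#'
#' Percent of extant species and genera sampled per group, computed from
#' [carnivora_sampling()] (extant species only; genus = first word of the
#' species binomial) against [carnivora_richness()].
#'
#' @return A tibble with `group`, `n_species_sampled`, `n_genera_sampled`,
#'   `pct_species`, `pct_genera`.
#' @export
sampling_coverage <- function() {
  s <- carnivora_sampling()
  s <- s[!s$fossil, , drop = FALSE]
  s$genus <- vapply(strsplit(s$species, " "), `[[`, character(1), 1)
  cov <- s |>
    group_by(.data$group) |>
    summarise(n_species_sampled = dplyr::n_distinct(.data$species),
              n_genera_sampled = dplyr::n_distinct(.data$genus),
              .groups = "drop")
  rich <- carnivora_richness()
  out <- left_join(cov, rich, by = "group")
  out$pct_species <- 100 * out$n_species_sampled / out$n_species
  out$pct_genera <- 100 * out$n_genera_sampled / out$n_genera
  out
}
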