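# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr arrange bind_cols bind_rows distinct filter group_by
#'   left_join mutate n pull rename select summarise ungroup across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_lgl map2 imap list_rbind
NULL

# Derive a reproducible substream seed for a named stage from a master seed.
# Keeps derived seeds inside the 32-bit integer range.
substream_seed <- function(seed, stage) {
  offsets <- c(
    tree = 101L, traits = 211L, landmarks = 307L, missing = 401L,
    bootstrap = 503L, rarefy = 601L, demo = 701L, pipeline = 809L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown substream stage: ", stage))
  }
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 97 + off) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Coerce a trait table to a numeric matrix with species rownames.
# Accepts a matrix with rownames or a data frame with a species id column.
as_trait_matrix <- function(x, species_col = "species_id") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("trait matrix must have species rownames")
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    if (!species_col %in% names(x)) {
      abort(paste0("expected a `", species_col, "` column in the trait table"))
    }
    sp <- as.character(x[[species_col]])
    num <- x[setdiff(names(x), species_col)]
    keep <- vapply(num, is.numeric, logical(1))
    m <- as.matrix(num[keep])
    rownames(m) <- sp
    return(m)
  }
  abort("traits must be a matrix with rownames or a data frame")
}

# Stable short hash of an R object (provenance headers in output files).
config_hash <- function(x) rlang::hash(x)

# Write a TSV with '#'-prefixed provenance header lines.
write_tsv_provenance <- function(df, path, provenance = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in provenance) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_provenance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
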