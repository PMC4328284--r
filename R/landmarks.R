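# Landmark data container and file input/output.
#
# A landmark set is a long-format tibble: one row per landmark observation on
# one specimen. Bilateral structure is encoded by the `side` column: a
# landmark_id appears either once with side "M" (midline) or twice with sides
# "L" and "R" (a bilateral pair). Missing landmarks keep their row with
# missing = TRUE and NA coordinates, so the missingness mask survives
# round-trips through files.

LANDMARK_COLS <- c("specimen_id", "species_id", "observer_id",
                   "landmark_id", "side", "x", "y", "z", "missing")

#' Build a landmark set from a long-format data frame
#'
#' @param df A data frame with columns `specimen_id`, `species_id`,
#'   `landmark_id`, `side` (one of `"L"`, `"R"`, `"M"`), `x`, `y`, `z`, and
#'   optionally `observer_id` and `missing` (logical or 0/1).
#'
#' @details Every specimen must carry the same set of `(landmark_id, side)`
#'   keys. A `landmark_id` is either midline (side `"M"` only) or bilateral
#'   (sides `"L"` and `"R"`, never `"M"`). A missing landmark has `missing =
#'   TRUE` and all three coordinates `NA`.
#'
#' @return A tibble of class `landmark_set`.
#' @export
landmark_set <- function(df) {
  df <- as_tibble(df)
  if (!"observer_id" %in% names(df)) df$observer_id <- NA_character_
  if (!"missing" %in% names(df)) df$missing <- FALSE
  missing_cols <- setdiff(LANDMARK_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark data lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[LANDMARK_COLS]
  df$specimen_id <- as.character(df$specimen_id)
  df$species_id <- as.character(df$species_id)
  df$observer_id <- as.character(df$observer_id)
  df$landmark_id <- as.character(df$landmark_id)
  df$side <- as.character(df$side)
  df$missing <- as.logical(df$missing)
  for (ax in c("x", "y", "z")) {
    if (!is.numeric(df[[ax]])) abort(paste0("non-numeric coordinates in `", ax, "`"))
  }
  validate_landmark_set(df)
  df$x[df$missing] <- NA_real_
  df$y[df$missing] <- NA_real_
  df$z[df$missing] <- NA_real_
  class(df) <- c("landmark_set", class(tibble()))
  df
}

validate_landmark_set <- function(df) {
  if (!all(df$side %in% c("L", "R", "M"))) {
    bad <- unique(df$side[!df$side %in% c("L", "R", "M")])
    abort(paste0("invalid side codes: ", paste(bad, collapse = ", ")))
  }
  key <- paste(df$specimen_id, df$landmark_id, df$side)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (specimen_id, landmark_id, side) rows, e.g.: ",
                 key[duplicated(key)][1]))
  }
  # Same landmark key set for all specimens.
  lk <- paste(df$landmark_id, df$side)
  tab <- table(df$specimen_id)
  if (length(unique(tab)) > 1) {
    abort("specimens have inconsistent landmark counts (inconsistent K)")
  }
  by_spec <- split(lk, df$specimen_id)
  ref <- sort(by_spec[[1]])
  ok <- vapply(by_spec, function(v) identical(sort(v), ref), logical(1))
  if (!all(ok)) abort("specimens do not share the same (landmark_id, side) keys")
  # Side structure per landmark id: {M} or {L, R}.
  sides <- split(df$side, df$landmark_id)
  for (id in names(sides)) {
    s <- sort(unique(sides[[id]]))
    if (!identical(s, "M") && !identical(s, c("L", "R"))) {
      abort(paste0("landmark `", id,
                   "` must be midline-only (M) or a full bilateral pair (L,R)"))
    }
  }
  # Missing rows must have NA in all three coordinates or be fillable as such.
  obs <- df[!df$missing, , drop = FALSE]
  if (anyNA(obs$x) || anyNA(obs$y) || anyNA(obs$z)) {
    abort("non-missing landmark rows contain NA coordinates")
  }
  invisible(df)
}

#' @export
print.landmark_set <- function(x, ...) {
  info <- landmark_info(x)
  cat(sprintf(
    "<landmark_set> %d specimens, %d species, K = %d landmarks (%d bilateral pairs, %d midline), %d missing\n",
    nrow(info$specimens), length(unique(info$specimens$species_id)),
    nrow(info$key), nrow(info$pairs), length(info$midline), sum(x$missing)))
  NextMethod()
}

# Landmark bookkeeping: ordered key table, pair map, midline ids, specimens.
landmark_info <- function(lms) {
  key <- distinct(tibble(landmark_id = lms$landmark_id, side = lms$side))
  key <- key[order(key$landmark_id, key$side), ]
  key$label <- paste(key$landmark_id, key$side, sep = "|")
  pairs_ids <- unique(key$landmark_id[key$side %in% c("L", "R")])
  pairs <- tibble(
    landmark_id = pairs_ids,
    left = match(paste(pairs_ids, "L", sep = "|"), key$label),
    right = match(paste(pairs_ids, "R", sep = "|"), key$label)
  )
  midline <- which(key$side == "M")
  specs <- distinct(tibble(specimen_id = lms$specimen_id,
                           species_id = lms$species_id,
                           observer_id = lms$observer_id))
  specs <- specs[order(match(specs$specimen_id, unique(lms$specimen_id))), ]
  list(key = key, pairs = pairs, midline = midline, specimens = specs)
}

# Convert a landmark_set to an n x K x 3 array plus missing mask.
landmark_array <- function(lms) {
  info <- landmark_info(lms)
  n <- nrow(info$specimens)
  K <- nrow(info$key)
  coords <- array(NA_real_, dim = c(n, K, 3),
                  dimnames = list(info$specimens$specimen_id, info$key$label,
                                  c("x", "y", "z")))
  miss <- matrix(FALSE, n, K,
                 dimnames = list(info$specimens$specimen_id, info$key$label))
  i <- match(lms$specimen_id, info$specimens$specimen_id)
  j <- match(paste(lms$landmark_id, lms$side, sep = "|"), info$key$label)
  coords[cbind(i, j, 1)] <- lms$x
  coords[cbind(i, j, 2)] <- lms$y
  coords[cbind(i, j, 3)] <- lms$z
  miss[cbind(i, j)] <- lms$missing
  list(coords = coords, missing = miss, key = info$key, pairs = info$pairs,
       midline = info$midline, specimens = info$specimens)
}

# Rebuild a landmark_set tibble from an array bundle (inverse of
# landmark_array for the same key ordering).
array_to_landmark_set <- function(arr) {
  n <- dim(arr$coords)[1]
  K <- dim(arr$coords)[2]
  grid <- expand.grid(j = seq_len(K), i = seq_len(n))
  df <- tibble(
    specimen_id = arr$specimens$specimen_id[grid$i],
    species_id = arr$specimens$species_id[grid$i],
    observer_id = arr$specimens$observer_id[grid$i],
    landmark_id = arr$key$landmark_id[grid$j],
    side = arr$key$side[grid$j],
    x = arr$coords[cbind(grid$i, grid$j, 1)],
    y = arr$coords[cbind(grid$i, grid$j, 2)],
    z = arr$coords[cbind(grid$i, grid$j, 3)],
    missing = arr$missing[cbind(grid$i, grid$j)]
  )
  landmark_set(df)
}

#' Read landmarks from file
#'
#' Reads the landmark CSV dialect (one row per landmark observation with
#' columns `specimen_id, species_id, observer_id, landmark_id, side, x, y, z,
#' missing`) or a TPS file with `LM3` blocks.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tps"`.
#' @return A [landmark_set()] tibble.
#' @export
read_landmarks <- function(path, format = c("csv", "tps")) {
  format <- match.arg(format)
  if (format == "tps") return(read_tps(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("NA", ""))
  needed <- setdiff(LANDMARK_COLS, c("observer_id", "missing"))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark CSV lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (ax in c("x", "y", "z")) {
    v <- raw[[ax]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0) {
        abort(paste0("non-numeric `", ax, "` at data line(s): ",
                     paste(utils::head(bad, 5), collapse = ", ")))
      }
      raw[[ax]] <- num
    }
  }
  if (!"missing" %in% names(raw)) {
    raw$missing <- is.na(raw$x) | is.na(raw$y) | is.na(raw$z)
  } else {
    raw$missing <- raw$missing %in% c(1, "1", TRUE, "TRUE") |
      is.na(raw$x) | is.na(raw$y) | is.na(raw$z)
  }
  landmark_set(raw)
}

#' Write landmarks to the landmark CSV dialect
#'
#' @param lms A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly. `read_landmarks(write_landmarks(x))` round-trips
#'   coordinates and the missing mask exactly.
#' @export
write_landmarks <- function(lms, path) {
  out <- as_tibble(lms)
  out$missing <- as.integer(out$missing)
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

# TPS reader: LM3 blocks with ID= keys; SCALE= applied when present.
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0) abort("no LM3 blocks found in TPS file")
  ends <- c(starts[-1] - 1, length(lines))
  blocks <- purrr::map2(starts, ends, function(s, e) lines[s:e])
  recs <- purrr::imap(blocks, function(block, bi) {
    k <- as.integer(sub("^LM3\\s*=\\s*", "", block[1], ignore.case = TRUE))
    coord_lines <- block[2:(1 + k)]
    xyz <- do.call(rbind, lapply(coord_lines, function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]])
    }))
    if (ncol(xyz) != 3 || anyNA(xyz[rowSums(is.na(xyz)) < 3, , drop = FALSE])) {
      abort(paste0("malformed coordinate rows in TPS block ", bi))
    }
    rest <- block[-(1:(1 + k))]
    id_line <- grep("^ID\\s*=", rest, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line)) sub("^ID\\s*=\\s*", "", id_line[1], ignore.case = TRUE)
          else paste0("spec", bi)
    scale_line <- grep("^SCALE\\s*=", rest, ignore.case = TRUE, value = TRUE)
    if (length(scale_line)) {
      xyz <- xyz * as.numeric(sub("^SCALE\\s*=\\s*", "", scale_line[1],
                                  ignore.case = TRUE))
    }
    tibble(specimen_id = id, species_id = id, observer_id = NA_character_,
           landmark_id = sprintf("lm%02d", seq_len(k)), side = "M",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
           missing = rowSums(is.na(xyz)) == 3)
  })
  landmark_set(list_rbind(recs))
}
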