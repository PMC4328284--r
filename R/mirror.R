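# Mirror-filling of one-sided missing landmarks.
#
# Specimens frequently miss all landmarks of one side (damaged material, or
# digitizing protocols that capture only one side). For bilaterally symmetric
# objects the missing landmark can be recovered by reflecting its bilateral
# partner across the specimen's symmetry plane, estimated from the midline
# landmarks.

# Total-least-squares plane through points (rows of `pts`): returns centroid
# and unit normal (smallest principal direction). Degenerate (collinear)
# point sets return NULL.
fit_symmetry_plane <- function(pts) {
  if (nrow(pts) < 3) return(NULL)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen)
  # Collinear midline points leave the plane normal unidentified: the two
  # smallest singular values are then both ~0 relative to the largest.
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) return(NULL)
  list(centroid = ctr, normal = sv$v[, 3])
}

reflect_across_plane <- function(p, plane) {
  d <- sum((p - plane$centroid) * plane$normal)
  p - 2 * d * plane$normal
}

#' Fill one-sided missing landmarks by mirroring
#'
#' For each specimen with missing bilateral landmarks, fits a
#' total-least-squares symmetry plane through its present midline landmarks
#' and replaces every missing landmark whose bilateral partner is present by
#' the partner's reflection across that plane. Filled entries have their
#' missing flag cleared.
#'
#' @param lms A [landmark_set()].
#' @return A `landmark_set` with filled entries. Specimens that cannot be
#'   filled (fewer than 3 present midline landmarks, collinear midline, or a
#'   missing landmark whose partner is also missing) keep their missing
#'   entries and are reported in the `unfillable` attribute and via a warning.
#' @export
mirror_fill <- function(lms) {
  arr <- landmark_array(lms)
  n <- dim(arr$coords)[1]
  unfillable <- character()
  partner <- integer(dim(arr$coords)[2])
  partner[arr$pairs$left] <- arr$pairs$right
  partner[arr$pairs$right] <- arr$pairs$left

  for (i in seq_len(n)) {
    miss_j <- which(arr$missing[i, ])
    if (length(miss_j) == 0) next
    mid_present <- arr$midline[!arr$missing[i, arr$midline]]
    plane <- if (length(mid_present) >= 3) {
      fit_symmetry_plane(arr$coords[i, mid_present, , drop = TRUE])
    } else NULL
    if (is.null(plane)) {
      unfillable <- c(unfillable, arr$specimens$specimen_id[i])
      next
    }
    filled_any <- FALSE
    leftover <- character()
    for (j in miss_j) {
      pj <- partner[j]
      if (pj == 0 || arr$missing[i, pj]) {
        leftover <- c(leftover, arr$key$label[j])
        next
      }
      arr$coords[i, j, ] <- reflect_across_plane(arr$coords[i, pj, ], plane)
      arr$missing[i, j] <- FALSE
      filled_any <- TRUE
    }
    if (length(leftover) > 0) {
      warn(paste0("specimen `", arr$specimens$specimen_id[i],
                  "`: cannot mirror-fill unpaired/both-missing landmarks: ",
                  paste(leftover, collapse = ", ")))
    }
  }
  if (length(unfillable) > 0) {
    warn(paste0("specimens flagged unfillable (midline missing or collinear): ",
                paste(unfillable, collapse = ", ")))
  }
  out <- array_to_landmark_set(arr)
  attr(out, "unfillable") <- unfillable
  out
}
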