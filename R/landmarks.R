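#' Landmark names used by the measurement pipeline
#'
#' @return Named list with character vectors `required` and `optional`.
#'   The required set carries the scapular-plane landmarks
#'   (`inferior_angle`, `glenoid_center`, `medial_point`), both axis origins
#'   (`medial_border_tip` for the conventional scapular axis, `vault_tip`
#'   for the vault axis) and the standard glenoid line endpoints
#'   (`anterior_rim`, `posterior_rim`). The optional set holds the Walch B2
#'   intermediate glenoid line endpoints.
#' @export
gv_landmark_names <- function() {
  list(
    required = c(
      "inferior_angle", "glenoid_center", "medial_point",
      "medial_border_tip", "vault_tip", "anterior_rim", "posterior_rim"
    ),
    optional = c("anterior_rim_intermediate", "posterior_rim_intermediate")
  )
}

.gv_sides <- c("left", "right")
.gv_dominance <- c("dominant", "nondominant", "unknown")

#' Validate a landmark table
#'
#' Checks the long landmark table used throughout the package: one row per
#' (shoulder, landmark) with world coordinates in millimetres.
#'
#' @param landmarks A data frame with columns `shoulder_id`, `side`,
#'   `dominance`, `landmark`, `x`, `y`, `z` (and optionally `subject_id`).
#' @return The validated table as a tibble, invisibly unchanged apart from
#'   column order; aborts with class `gv_validation_error` on problems
#'   (missing required landmarks, unknown landmark names, non-finite or
#'   duplicated coordinates, degenerate scapular-plane triangles).
#' @export
validate_landmarks <- function(landmarks) {
  landmarks <- tibble::as_tibble(landmarks)
  needed <- c("shoulder_id", "side", "dominance", "landmark", "x", "y", "z")
  missing_cols <- setdiff(needed, names(landmarks))
  if (length(missing_cols)) {
    abort(
      paste0("landmark table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  known <- unlist(gv_landmark_names(), use.names = FALSE)
  unknown <- setdiff(unique(landmarks$landmark), known)
  if (length(unknown)) {
    abort(
      paste0(
        "unknown landmark name(s): ", paste(unknown, collapse = ", "),
        "; known names are: ", paste(known, collapse = ", ")
      ),
      class = "gv_validation_error"
    )
  }
  bad_side <- setdiff(unique(landmarks$side), .gv_sides)
  if (length(bad_side)) {
    abort(paste0("side must be one of left/right, got: ", paste(bad_side, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  bad_dom <- setdiff(unique(landmarks$dominance), .gv_dominance)
  if (length(bad_dom)) {
    abort(
      paste0(
        "dominance must be dominant/nondominant/unknown, got: ",
        paste(bad_dom, collapse = ", ")
      ),
      class = "gv_validation_error"
    )
  }
  if (!all(is.finite(landmarks$x) & is.finite(landmarks$y) & is.finite(landmarks$z))) {
    abort("non-finite landmark coordinates", class = "gv_validation_error")
  }
  dup <- landmarks |>
    dplyr::count(.data$shoulder_id, .data$landmark) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(
      paste0(
        "duplicated landmark(s): ",
        paste(paste0(dup$shoulder_id, "/", dup$landmark), collapse = ", ")
      ),
      class = "gv_validation_error"
    )
  }
  req <- gv_landmark_names()$required
  by_shoulder <- split(landmarks, landmarks$shoulder_id)
  for (sh in names(by_shoulder)) {
    have <- by_shoulder[[sh]]$landmark
    lack <- setdiff(req, have)
    if (length(lack)) {
      abort(
        paste0(
          "shoulder '", sh, "' lacks required landmark(s): ",
          paste(lack, collapse = ", ")
        ),
        class = "gv_validation_error"
      )
    }
    m <- landmarks_matrix(by_shoulder[[sh]])
    if (vnorm(m["anterior_rim", ] - m["posterior_rim", ]) < 1e-9) {
      abort(paste0("shoulder '", sh, "': anterior_rim equals posterior_rim"),
        class = "gv_validation_error"
      )
    }
  }
  dplyr::relocate(landmarks, dplyr::any_of(
    c("shoulder_id", "subject_id", "side", "dominance", "landmark", "x", "y", "z")
  ))
}

# long rows for one shoulder -> named coordinate matrix (landmarks x 3)
landmarks_matrix <- function(rows) {
  m <- as.matrix(rows[, c("x", "y", "z")])
  rownames(m) <- rows$landmark
  m
}
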