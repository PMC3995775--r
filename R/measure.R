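#' Glenoid line endpoints and center in the corrected slice
#'
#' Projects the glenoid line — anterior rim to posterior rim, or the Walch
#' B2 intermediate endpoints — into the corrected slice and returns the two
#' endpoints and their midpoint (the center of the glenoid line, which is
#' the lateral end of both measurement axes).
#'
#' @param points Named coordinate matrix (one shoulder's landmarks, rows
#'   named, columns x/y/z in mm).
#' @param slice Corrected slice from [corrected_slice()].
#' @param variant `"standard"` (native rims) or `"intermediate"` (Walch B2
#'   intermediate line endpoints `anterior_rim_intermediate` /
#'   `posterior_rim_intermediate`).
#' @return List with 2D slice coordinates `anterior`, `posterior`,
#'   `midpoint`.
#' @export
glenoid_line <- function(points, slice, variant = c("standard", "intermediate")) {
  variant <- match.arg(variant)
  nms <- if (variant == "standard") {
    c("anterior_rim", "posterior_rim")
  } else {
    c("anterior_rim_intermediate", "posterior_rim_intermediate")
  }
  lack <- setdiff(nms, rownames(points))
  if (length(lack)) {
    abort(
      paste0(
        "variant '", variant, "' needs landmark(s) ",
        paste(lack, collapse = ", "), " which are absent"
      ),
      class = "gv_missing_landmark"
    )
  }
  ant <- project_to_slice(points[nms[1], ], slice)
  post <- project_to_slice(points[nms[2], ], slice)
  list(anterior = ant, posterior = post, midpoint = (ant + post) / 2)
}

measure_one <- function(points, method, variant) {
  scap <- scapular_plane(points)
  slice <- corrected_slice(points, scap)
  gl <- glenoid_line(points, slice, variant)
  origin_name <- switch(method,
    conventional = "medial_border_tip",
    vault = "vault_tip"
  )
  if (!origin_name %in% rownames(points)) {
    abort(paste0("landmark '", origin_name, "' missing"),
      class = "gv_missing_landmark"
    )
  }
  axis_origin <- project_to_slice(points[origin_name, ], slice)
  signed_version_angle(gl$anterior, gl$posterior, axis_origin, gl$midpoint)
}

#' Measure glenoid version for every shoulder in a landmark table
#'
#' For each shoulder the scapular plane and three-dimensionally corrected
#' slice are reconstructed, all landmarks are projected into the slice, and
#' the signed version angle (retroversion positive) is computed against the
#' requested axis: the conventional (Friedman) scapular axis from the tip
#' of the medial border of the scapula to the center of the glenoid line,
#' and/or the glenoid vault axis from the tip of the scapular vault to the
#' same center.
#'
#' @param landmarks Long landmark table (see [validate_landmarks()]).
#' @param method `"both"` (default), `"conventional"` or `"vault"`.
#' @param variant Glenoid line variant, `"standard"` or `"intermediate"`
#'   (Walch B2), applied to every shoulder.
#' @return A tibble with one row per shoulder and method: `shoulder_id`,
#'   `subject_id` (if present), `side`, `dominance`, `method`, `variant`,
#'   `version_deg` (signed degrees, retroversion positive).
#' @examples
#' cohort <- generate_cohort(cohort_spec(preset = "normal", n_shoulders = 3), seed = 1)
#' measure_version(cohort$landmarks)
#' @export
measure_version <- function(landmarks,
                            method = c("both", "conventional", "vault"),
                            variant = c("standard", "intermediate")) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  landmarks <- validate_landmarks(landmarks)
  methods <- if (method == "both") c("conventional", "vault") else method
  meta_cols <- intersect(
    c("shoulder_id", "subject_id", "side", "dominance"),
    names(landmarks)
  )
  landmarks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::group_modify(function(rows, key) {
      pts <- landmarks_matrix(rows)
      vals <- unname(
        vapply(methods, function(m) measure_one(pts, m, variant), numeric(1))
      )
      tibble::tibble(method = methods, variant = variant, version_deg = vals)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$shoulder_id, .data$method)
}

#' Per-shoulder difference between vault and conventional version
#'
#' Pairs the two methods per shoulder and returns the signed difference
#' vault minus conventional, in degrees. Both methods share the identical
#' glenoid line, so the difference isolates the influence of the scapular
#' body shape on the conventional axis.
#'
#' @param results Version table from [measure_version()] containing both
#'   methods for every shoulder.
#' @return A tibble with `shoulder_id`, `conventional_deg`, `vault_deg` and
#'   `difference_deg` (vault - conventional).
#' @examples
#' res <- tibble::tibble(
#'   shoulder_id = c("a", "a"),
#'   method = c("conventional", "vault"),
#'   version_deg = c(6.2, 9.7)
#' )
#' method_difference(res) # difference_deg = 3.5
#' @export
method_difference <- function(results) {
  results <- tibble::as_tibble(results)
  wide <- results |>
    dplyr::select(dplyr::any_of(c("shoulder_id", "method", "version_deg"))) |>
    tidyr::pivot_wider(names_from = "method", values_from = "version_deg")
  lack <- setdiff(c("conventional", "vault"), names(wide))
  if (length(lack)) {
    abort(paste0("results lack method(s): ", paste(lack, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  incomplete <- wide$shoulder_id[is.na(wide$conventional) | is.na(wide$vault)]
  if (length(incomplete)) {
    abort(
      paste0(
        "shoulder(s) without both methods: ",
        paste(incomplete, collapse = ", ")
      ),
      class = "gv_validation_error"
    )
  }
  wide |>
    dplyr::transmute(
      .data$shoulder_id,
      conventional_deg = .data$conventional,
      vault_deg = .data$vault,
      difference_deg = .data$vault - .data$conventional
    )
}
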