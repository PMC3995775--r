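.gv_schema <- "glenoidvault/landmarks-v1"

#' Read a landmark file
#'
#' Landmark files are JSON (primary format) or long CSV. The JSON layout is
#'
#' ```json
#' {
#'   "schema": "glenoidvault/landmarks-v1",
#'   "shoulders": [
#'     {
#'       "shoulder_id": "shoulder_001",
#'       "subject_id": "subject_001",
#'       "side": "right",
#'       "dominance": "unknown",
#'       "landmarks": {"glenoid_center": [x, y, z], "...": [x, y, z]}
#'     }
#'   ]
#' }
#' ```
#'
#' with coordinates always in millimetres. The CSV alternative has columns
#' `shoulder_id, subject_id, side, dominance, landmark, x, y, z`. The file
#' type is inferred from the extension unless `format` is given.
#'
#' @param path File path.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return Validated long landmark tibble (see [validate_landmarks()]);
#'   record order preserved.
#' @export
read_landmarks <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("landmark file not found: ", path), class = "gv_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    doc <- tryCatch(
      jsonlite::read_json(path),
      error = function(e) {
        abort(paste0("cannot parse ", path, ": ", conditionMessage(e)),
          class = "gv_io_error"
        )
      }
    )
    if (!identical(doc$schema, .gv_schema)) {
      abort(
        paste0(
          "unsupported landmark schema '", doc$schema %||% "<missing>",
          "' in ", path, " (expected ", .gv_schema, ")"
        ),
        class = "gv_validation_error"
      )
    }
    rows <- purrr::imap(doc$shoulders, function(rec, i) {
      for (fld in c("shoulder_id", "side", "dominance", "landmarks")) {
        if (is.null(rec[[fld]])) {
          abort(
            paste0("shoulder record ", i, " in ", path, " lacks '", fld, "'"),
            class = "gv_validation_error"
          )
        }
      }
      tibble::tibble(
        shoulder_id = rec$shoulder_id,
        subject_id = rec$subject_id %||% NA_character_,
        side = rec$side,
        dominance = rec$dominance,
        landmark = names(rec$landmarks),
        coord = purrr::map(rec$landmarks, \(p) as.numeric(unlist(p)))
      )
    })
    out <- purrr::list_rbind(rows)
    if (any(lengths(out$coord) != 3)) {
      abort("every landmark needs exactly 3 coordinates",
        class = "gv_validation_error"
      )
    }
    out <- out |>
      dplyr::mutate(
        x = purrr::map_dbl(.data$coord, 1),
        y = purrr::map_dbl(.data$coord, 2),
        z = purrr::map_dbl(.data$coord, 3)
      ) |>
      dplyr::select(-"coord")
  } else {
    out <- readr::read_csv(path,
      show_col_types = FALSE,
      col_types = readr::cols(
        x = readr::col_double(), y = readr::col_double(),
        z = readr::col_double(), .default = readr::col_character()
      )
    )
  }
  validate_landmarks(out)
}

#' Write a landmark table
#'
#' Inverse of [read_landmarks()]; `write_landmarks()` then
#' `read_landmarks()` round-trips to identical records.
#'
#' @param landmarks Long landmark tibble.
#' @param path Output path (`.json` or `.csv`).
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  landmarks <- validate_landmarks(landmarks)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(landmarks, path)
    return(invisible(path))
  }
  recs <- landmarks |>
    dplyr::group_split(.data$shoulder_id) |>
    purrr::map(function(rows) {
      rec <- list(
        shoulder_id = rows$shoulder_id[1],
        side = rows$side[1],
        dominance = rows$dominance[1],
        landmarks = setNames(
          purrr::pmap(rows[, c("x", "y", "z")], \(x, y, z) c(x, y, z)),
          rows$landmark
        )
      )
      subj <- if ("subject_id" %in% names(rows)) rows$subject_id[1] else NA
      if (!is.na(subj)) rec <- append(rec, list(subject_id = subj), after = 1)
      rec
    })
  jsonlite::write_json(
    list(schema = .gv_schema, shoulders = recs),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read and write rating / version-result CSV tables
#'
#' Thin readers with column checks: version results have columns
#' `shoulder_id, method, version_deg` (plus optional metadata); ratings
#' additionally need `rater` and `session`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  lack <- setdiff(c("shoulder_id", "method", "version_deg"), names(out))
  if (length(lack)) {
    abort(paste0("results file lacks column(s): ", paste(lack, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  out
}

#' @rdname read_results
#' @export
read_ratings <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  lack <- setdiff(
    c("shoulder_id", "rater", "session", "version_deg"),
    names(out)
  )
  if (length(lack)) {
    abort(paste0("ratings file lacks column(s): ", paste(lack, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  out
}
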