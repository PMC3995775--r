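# Canonical scapular geometry (mm). Angles are scale invariant, so these
# only set the leverage of landmark noise on measured angles.
.gv_geom_defaults <- list(
  glenoid_width_mm = 28,
  vault_depth_mm = 30,
  medial_border_mm = 100,
  medial_pole_mm = 90,
  inferior_angle_mm = c(-60, 0, -80)
)

random_rotation <- function() {
  # QR-based uniform random rotation; det forced to +1
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build one synthetic shoulder with known ground-truth version
#'
#' Constructs a landmark set whose measured vault version and conventional
#' (Friedman) version are exactly the requested angles. The configuration
#' is laid out in the corrected slice — glenoid line of the stated width
#' centred on the glenoid center, vault tip on the vault axis at the
#' stated depth, medial border tip on the conventional axis (rotated off
#' the vault axis by the body-shape offset) at the stated length — then
#' tilted by the scapular inclination and embedded in 3D with an arbitrary
#' rigid placement. Left shoulders are built as the mirror image of the
#' right-handed template.
#'
#' @param true_vault_deg Ground-truth vault version (degrees, retroversion
#'   positive), |value| < 90.
#' @param body_offset_deg Angle between the vault axis and the conventional
#'   scapular axis in the slice; the conventional version equals
#'   `true_vault_deg - body_offset_deg`, which must stay within (-90, 90).
#' @param inclination_deg Out-of-slice scapular inclination (degrees).
#' @param side `"right"` or `"left"`.
#' @param dominance `"dominant"`, `"nondominant"` or `"unknown"`.
#' @param shoulder_id,subject_id Identifiers carried into the output.
#' @param rotation 3x3 rotation matrix for the rigid placement (identity if
#'   `NULL`).
#' @param translation Length-3 translation in mm (zero if `NULL`).
#' @param intermediate_version_deg If non-`NULL`, also emit Walch B2
#'   intermediate glenoid line endpoints realising this version.
#' @param geometry Named list overriding the default scapular dimensions
#'   (`glenoid_width_mm` 28, `vault_depth_mm` 30, `medial_border_mm` 100).
#' @return List with `landmarks` (long tibble rows for this shoulder) and
#'   `ground_truth` (one-row tibble: true vault/conventional version and
#'   the body offset).
#' @export
build_shoulder <- function(true_vault_deg,
                           body_offset_deg = 0,
                           inclination_deg = 10,
                           side = c("right", "left"),
                           dominance = "unknown",
                           shoulder_id = "shoulder_001",
                           subject_id = NA_character_,
                           rotation = NULL,
                           translation = NULL,
                           intermediate_version_deg = NULL,
                           geometry = list()) {
  side <- match.arg(side)
  if (abs(true_vault_deg) >= 90) {
    abort("|true_vault_deg| must be < 90", class = "gv_validation_error")
  }
  if (abs(true_vault_deg - body_offset_deg) >= 90) {
    abort("implied conventional version out of (-90, 90)",
      class = "gv_validation_error"
    )
  }
  geom <- utils::modifyList(.gv_geom_defaults, geometry)
  deg2rad <- pi / 180
  vv <- true_vault_deg * deg2rad
  off <- body_offset_deg * deg2rad
  iota <- inclination_deg * deg2rad

  # anatomical template frame: x lateral, y anterior, z superior.
  # slice frame axes (medial->lateral u tilted by the inclination):
  u <- c(cos(iota), 0, -sin(iota))
  v <- c(0, 1, 0)
  in_slice <- function(px, py) px * u + py * v

  w2 <- geom$glenoid_width_mm / 2
  pts <- list(
    glenoid_center = c(0, 0, 0),
    anterior_rim = in_slice(w2 * sin(vv), w2 * cos(vv)),
    posterior_rim = in_slice(-w2 * sin(vv), -w2 * cos(vv)),
    vault_tip = in_slice(-geom$vault_depth_mm, 0),
    medial_border_tip = in_slice(
      -geom$medial_border_mm * cos(off),
      geom$medial_border_mm * sin(off)
    ),
    medial_point = in_slice(-geom$medial_pole_mm, 0),
    inferior_angle = geom$inferior_angle_mm
  )
  if (!is.null(intermediate_version_deg)) {
    iv <- intermediate_version_deg * deg2rad
    pts$anterior_rim_intermediate <- in_slice(w2 * sin(iv), w2 * cos(iv))
    pts$posterior_rim_intermediate <- in_slice(-w2 * sin(iv), -w2 * cos(iv))
  }
  m <- do.call(rbind, pts)
  if (side == "left") m[, 3] <- -m[, 3] # mirror image of the template
  if (!is.null(rotation)) m <- m %*% t(rotation)
  if (!is.null(translation)) m <- sweep(m, 2, as.numeric(translation), "+")

  landmarks <- tibble::tibble(
    shoulder_id = shoulder_id,
    subject_id = subject_id,
    side = side,
    dominance = dominance,
    landmark = rownames(m),
    x = unname(m[, 1]), y = unname(m[, 2]), z = unname(m[, 3])
  )
  ground_truth <- tibble::tibble(
    shoulder_id = shoulder_id,
    subject_id = subject_id,
    side = side,
    dominance = dominance,
    true_vault_version_deg = true_vault_deg,
    true_conventional_version_deg = true_vault_deg - body_offset_deg,
    body_offset_deg = body_offset_deg,
    inclination_deg = inclination_deg
  )
  list(landmarks = landmarks, ground_truth = ground_truth)
}

#' Specify a synthetic cohort
#'
#' Generative parameters for [generate_cohort()]. Ground-truth vault
#' version and the scapular body-shape offset (vault axis vs conventional
#' scapular axis) are Gaussian; conventional version is their difference.
#' The shipped presets reproduce reported normal and arthritic cohort
#' distributions:
#'
#' * `"normal"` — vault 8.9 +/- 2.7 deg; body offset 7.8 +/- 1.72 deg, so
#'   conventional version is 1.1 +/- 3.2 deg.
#' * `"arthritic"` — vault 18.2 +/- 9.1 deg; offset 7.4 +/- 1.92 deg, so
#'   conventional version is 10.8 +/- 9.3 deg.
#' * `"paired_dominance"` — 75 subjects with both shoulders; nondominant
#'   vault mean 8.2 deg with a +1.4 deg dominance shift, subject baseline
#'   SD 2.25 deg and within-subject SD 1.5 deg (marginal SD 2.7 deg).
#'
#' Offset SDs follow from the variance decomposition
#' `sd_conventional^2 = sd_vault^2 + sd_offset^2` under independence.
#'
#' @param preset `"normal"`, `"arthritic"`, `"paired_dominance"`, or `NULL`
#'   for a fully manual spec.
#' @param ... Named overrides of any preset field: `n_shoulders`,
#'   `vault_version_mean_deg`, `vault_version_sd_deg`,
#'   `body_offset_mean_deg`, `body_offset_sd_deg`, `paired`,
#'   `dominance_shift_deg`, `between_subject_sd_deg`,
#'   `within_subject_sd_deg`, `inclination_range_deg` (length 2),
#'   `landmark_noise_sd_mm`, `prop_left`, `seed`.
#' @return A `gv_cohort_spec` list.
#' @export
cohort_spec <- function(preset = NULL, ...) {
  base <- list(
    n_shoulders = 150,
    vault_version_mean_deg = 8.9,
    vault_version_sd_deg = 2.7,
    body_offset_mean_deg = 7.8,
    body_offset_sd_deg = 1.72,
    paired = FALSE,
    dominance_shift_deg = 0,
    between_subject_sd_deg = 2.25,
    within_subject_sd_deg = 1.5,
    inclination_range_deg = c(0, 30),
    landmark_noise_sd_mm = 0,
    prop_left = 0.5,
    seed = NULL
  )
  if (!is.null(preset)) {
    path <- system.file("extdata", "presets", paste0(preset, ".yaml"),
      package = "glenoidvault"
    )
    if (!nzchar(path)) {
      abort(paste0("unknown preset '", preset, "'"),
        class = "gv_validation_error"
      )
    }
    base <- utils::modifyList(base, yaml::read_yaml(path))
  }
  spec <- utils::modifyList(base, list(...))
  if (spec$n_shoulders < 1) {
    abort("n_shoulders must be >= 1", class = "gv_validation_error")
  }
  sds <- c(
    spec$vault_version_sd_deg, spec$body_offset_sd_deg,
    spec$between_subject_sd_deg, spec$within_subject_sd_deg,
    spec$landmark_noise_sd_mm
  )
  if (any(sds < 0)) {
    abort("standard deviations must be >= 0", class = "gv_validation_error")
  }
  if (spec$paired && spec$n_shoulders %% 2 != 0) {
    abort("paired cohorts need an even n_shoulders",
      class = "gv_validation_error"
    )
  }
  structure(spec, class = "gv_cohort_spec")
}

#' Generate a synthetic cohort of shoulders
#'
#' Draws ground-truth vault versions and body-shape offsets from the spec's
#' distributions, builds each shoulder with a random scapular inclination
#' and a random rigid placement (rotation + translation), and optionally
#' perturbs the landmarks with isotropic Gaussian noise. In paired mode
#' each subject contributes a dominant and a nondominant shoulder sharing a
#' subject-level baseline, with the dominance shift added to the dominant
#' side's true vault version.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; overrides `spec$seed`. Identical seeds give
#'   bitwise-identical cohorts.
#' @return A `gv_cohort` list: `landmarks` (long tibble over all
#'   shoulders), `ground_truth` (one row per shoulder), `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(preset = "normal", n_shoulders = 4), seed = 7)
#' cohort$ground_truth
#' @export
generate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "gv_cohort_spec")) {
    abort("`spec` must come from cohort_spec()", class = "gv_validation_error")
  }
  seed <- seed %||% spec$seed
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  n <- spec$n_shoulders
  if (spec$paired) {
    n_subj <- n / 2
    baseline <- stats::rnorm(n_subj, spec$vault_version_mean_deg,
      spec$between_subject_sd_deg
    )
    grid <- tidyr::expand_grid(
      subject = seq_len(n_subj),
      dominance = c("dominant", "nondominant")
    )
    truth <- grid |>
      dplyr::mutate(
        subject_id = sprintf("subject_%03d", .data$subject),
        # right side dominant for every synthetic subject
        side = ifelse(.data$dominance == "dominant", "right", "left"),
        shoulder_id = paste0(
          .data$subject_id, "_",
          ifelse(.data$side == "right", "R", "L")
        ),
        true_vault = baseline[.data$subject] +
          stats::rnorm(dplyr::n(), 0, spec$within_subject_sd_deg) +
          ifelse(.data$dominance == "dominant", spec$dominance_shift_deg, 0),
        offset = stats::rnorm(dplyr::n(), spec$body_offset_mean_deg,
          spec$body_offset_sd_deg
        )
      )
  } else {
    truth <- tibble::tibble(
      shoulder_id = sprintf("shoulder_%03d", seq_len(n)),
      subject_id = sprintf("subject_%03d", seq_len(n)),
      side = ifelse(stats::runif(n) < spec$prop_left, "left", "right"),
      dominance = "unknown",
      true_vault = stats::rnorm(n, spec$vault_version_mean_deg,
        spec$vault_version_sd_deg
      ),
      offset = stats::rnorm(n, spec$body_offset_mean_deg,
        spec$body_offset_sd_deg
      )
    )
  }
  built <- purrr::pmap(
    list(
      truth$true_vault, truth$offset, truth$shoulder_id,
      truth$subject_id, truth$side, truth$dominance
    ),
    function(vv, off, sid, subj, side, dom) {
      build_shoulder(
        true_vault_deg = vv,
        body_offset_deg = off,
        inclination_deg = stats::runif(
          1, spec$inclination_range_deg[1], spec$inclination_range_deg[2]
        ),
        side = side,
        dominance = dom,
        shoulder_id = sid,
        subject_id = subj,
        rotation = random_rotation(),
        translation = stats::runif(3, -200, 200)
      )
    }
  )
  landmarks <- purrr::list_rbind(purrr::map(built, "landmarks"))
  if (spec$landmark_noise_sd_mm > 0) {
    nr <- nrow(landmarks)
    landmarks$x <- landmarks$x + stats::rnorm(nr, 0, spec$landmark_noise_sd_mm)
    landmarks$y <- landmarks$y + stats::rnorm(nr, 0, spec$landmark_noise_sd_mm)
    landmarks$z <- landmarks$z + stats::rnorm(nr, 0, spec$landmark_noise_sd_mm)
  }
  structure(
    list(
      landmarks = landmarks,
      ground_truth = purrr::list_rbind(purrr::map(built, "ground_truth")),
      spec = spec
    ),
    class = "gv_cohort"
  )
}

#' @export
print.gv_cohort <- function(x, ...) {
  cat(
    "<gv_cohort>", nrow(x$ground_truth), "shoulders;",
    "true vault version", sprintf("%.1f +/- %.1f deg",
      mean(x$ground_truth$true_vault_version_deg),
      stats::sd(x$ground_truth$true_vault_version_deg)
    ), "\n"
  )
  invisible(x)
}

#' Simulate a multi-rater, multi-session measurement study
#'
#' Emulates independent observers re-measuring every shoulder: for each
#' rater and session, every landmark is perturbed with isotropic Gaussian
#' noise (the rater's landmark placement error) and the full measurement
#' pipeline is re-run. The default 0.25 mm noise propagates to roughly a
#' 1-degree angle standard deviation with the default scapular dimensions.
#'
#' @param landmarks Landmark table (e.g. `generate_cohort(...)$landmarks`).
#' @param n_raters Number of raters (default 3); `noise_sd_mm` may be a
#'   single value or one value per rater.
#' @param n_sessions Sessions per rater (default 2).
#' @param noise_sd_mm Isotropic landmark noise SD in mm per rater.
#' @param method,variant Passed to [measure_version()].
#' @param seed Optional integer seed for reproducibility.
#' @return Long rating tibble: `shoulder_id`, `rater`, `session`, `method`,
#'   `variant`, `version_deg`, plus shoulder metadata.
#' @export
simulate_raters <- function(landmarks,
                            n_raters = 3,
                            n_sessions = 2,
                            noise_sd_mm = 0.25,
                            method = "both",
                            variant = "standard",
                            seed = NULL) {
  if (any(noise_sd_mm < 0)) {
    abort("noise_sd_mm must be >= 0", class = "gv_validation_error")
  }
  noise_sd_mm <- rep_len(noise_sd_mm, n_raters)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  grid <- tidyr::expand_grid(rater = seq_len(n_raters), session = seq_len(n_sessions))
  purrr::pmap(grid, function(rater, session) {
    noisy <- landmarks
    sdr <- noise_sd_mm[rater]
    if (sdr > 0) {
      nr <- nrow(noisy)
      noisy$x <- noisy$x + stats::rnorm(nr, 0, sdr)
      noisy$y <- noisy$y + stats::rnorm(nr, 0, sdr)
      noisy$z <- noisy$z + stats::rnorm(nr, 0, sdr)
    }
    measure_version(noisy, method = method, variant = variant) |>
      dplyr::mutate(
        rater = sprintf("rater_%d", rater),
        session = session,
        .before = "method"
      )
  }) |>
    purrr::list_rbind()
}
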