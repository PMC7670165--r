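# End-to-end orchestration: per-subject frame construction, fragment
# trimming and measurement on both sides, mirror matching, and cohort
# batch processing with CSV/JSON reporting.

#' Pipeline configuration
#'
#' All tunable defaults of the analysis stages, validated once and
#' serialised into every report for provenance.
#'
#' @param fraction Fragment fraction of total coronoid height.
#' @param proximity_mm Proximity distance for the covering percentage (mm).
#' @param k_neighbors Neighbourhood size for curvature/normal estimation.
#' @param n_shaft_sections Cross-sections for the shaft axis fit.
#' @param n_ridge_sections Cross-sections for the sigmoid-notch ridge.
#' @param shaft_fraction Distal fraction of the axial extent treated as
#'   shaft.
#' @param slab_halfwidth Cross-section slab half-width for length/width and
#'   facet sections (mm).
#' @param cone_deg Articular extraction cone half-angle (degrees).
#' @param tie_tol Tip-selection near-tie width (mm).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fraction = 0.40, proximity_mm = 2.0,
                            k_neighbors = 20L, n_shaft_sections = 3L,
                            n_ridge_sections = 5L, shaft_fraction = 0.5,
                            slab_halfwidth = 0.5, cone_deg = 60,
                            tie_tol = 4.0) {
  cfg <- list(fraction = fraction, proximity_mm = proximity_mm,
              k_neighbors = as.integer(k_neighbors),
              n_shaft_sections = as.integer(n_shaft_sections),
              n_ridge_sections = as.integer(n_ridge_sections),
              shaft_fraction = shaft_fraction,
              slab_halfwidth = slab_halfwidth, cone_deg = cone_deg,
              tie_tol = tie_tol)
  if (!(cfg$fraction > 0 && cfg$fraction < 1)) {
    rlang::abort("fraction must be in (0, 1)", class = "coronoid_validation_error")
  }
  if (cfg$proximity_mm <= 0 || cfg$slab_halfwidth <= 0) {
    rlang::abort("distances must be positive", class = "coronoid_validation_error")
  }
  if (cfg$k_neighbors < 6L || cfg$n_shaft_sections < 2L || cfg$n_ridge_sections < 1L) {
    rlang::abort("invalid neighbourhood/section counts", class = "coronoid_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Analyse one side: frame, fragment, articular subset
#'
#' Runs the frame construction (shaft axis, curvature ridge, ridge plane,
#' coronoid tip), transforms the model into its local frame, locates the
#' posterior flat spot and base plane, trims the upper-fraction fragment
#' and extracts its articular surface. The greater-sigmoid-notch centre is
#' estimated from the circle through the mid-channel ridge points in the
#' sagittal plane.
#'
#' @param model A [surface_model()] in world (CT) coordinates.
#' @param config A [pipeline_config()].
#' @return List with `local` (local-frame model), `frame`, `fragment`
#'   (with articular indices and notch centre attached), `ridge_points`,
#'   `flat_spot`, `base_plane`.
#' @export
analyze_side <- function(model, config = pipeline_config()) {
  stopifnot(inherits(model, "surface_model"))
  # canonicalise the pose first: every rigid placement of the same cloud
  # maps to the same canonical coordinates (to ~1e-13), so the discrete
  # selections inside the detectors cannot flip between near-tied samples
  # and the whole pipeline commutes with rigid motion of the input
  can <- canonical_pose(model)
  model <- can$model
  axis <- fit_shaft_axis(model, n_sections = config$n_shaft_sections,
                         shaft_fraction = config$shaft_fraction)
  ridge <- find_ridge_points(model, axis, n_sections = config$n_ridge_sections,
                             k_neighbors = config$k_neighbors)
  ridge_plane <- fit_ridge_plane(ridge, axis)
  tip <- find_coronoid_tip(model, ridge_plane, axis, tie_tol = config$tie_tol)
  frame <- build_local_frame(axis, tip)
  local <- to_local(model, frame)
  Rloc <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  ridge_local <- sweep(ridge, 2, frame$origin) %*% t(Rloc)
  flat <- find_posterior_flat_spot(local, k_neighbors = config$k_neighbors)
  base <- fit_base_plane(local, ridge_local, flat_spot = flat)
  tip_local <- attr(local, "tip_local")
  frag <- trim_fragment(local, flat, base, tip_local, fraction = config$fraction)
  # notch centre: circle through the ridge points in the sagittal (y, z) plane
  notch_center <- tryCatch({
    cf <- fit_circle_taubin(ridge_local[, 2:3, drop = FALSE])
    c(0, cf$center)
  }, error = function(e) {
    c(0, mean(ridge_local[, 2]), mean(ridge_local[, 3]) + 5)
  })
  frag$notch_center <- notch_center
  frag$articular <- extract_articular_surface(frag, notch_center,
                                              k_neighbors = config$k_neighbors,
                                              cone_deg = config$cone_deg)
  # report the anatomical frame in the caller's (world) coordinates
  frame_world <- frame
  frame_world$origin <- drop(t(can$rotation) %*% frame$origin) + can$centroid
  frame_world$tip <- drop(t(can$rotation) %*% frame$tip) + can$centroid
  frame_world$x_axis <- drop(t(can$rotation) %*% frame$x_axis)
  frame_world$y_axis <- drop(t(can$rotation) %*% frame$y_axis)
  frame_world$z_axis <- drop(t(can$rotation) %*% frame$z_axis)
  attr(local, "frame") <- frame_world
  list(local = local, frame = frame_world, fragment = frag,
       ridge_points = ridge_local, flat_spot = flat, base_plane = base)
}

#' Deterministic canonical pose
#'
#' Centres the cloud and aligns it with its principal axes, with axis
#' signs fixed by the sign of the third moment (skewness) along each
#' principal direction and a right-handed third axis. Any rigid placement
#' of the same cloud maps to the same canonical coordinates.
#'
#' @param model A [surface_model()].
#' @return List with the transformed `model`, the `rotation` (rows =
#'   canonical axes) and the original `centroid`.
#' @export
canonical_pose <- function(model) {
  pts <- model$points
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  a1 <- ev$vectors[, 1]
  a2 <- ev$vectors[, 2]
  if (sum(drop(x %*% a1)^3) < 0) a1 <- -a1
  if (sum(drop(x %*% a2)^3) < 0) a2 <- -a2
  R <- rbind(a1, a2, cross3(a1, a2))
  out <- model
  # quantise at 1e-6 mm: rigid placements of the same cloud differ here by
  # ~1e-13 mm of floating-point noise, so after rounding they yield
  # bit-identical canonical coordinates and the (deterministic) detector
  # chain returns bit-identical results
  out$points <- round(x %*% t(R), 6)
  list(model = out, rotation = R, centroid = ctr)
}

#' Run the full bilateral pipeline for one subject
#'
#' Analyses both sides independently in their own anatomical frames,
#' measures the two target fragments, mirror-aligns the left onto the
#' right and computes the covering percentage.
#'
#' @param left,right [surface_model()] objects (world coordinates), or
#'   `NULL` when a side is missing (raises a structured error).
#' @param config A [pipeline_config()].
#' @return List of class `coronoid_subject`: `measurements` (two-row
#'   tibble), `match` (a `coronoid_match`), `match_table` (tidy one-row
#'   tibble), `alignment` (tip offset diagnostics), `sides` (per-side
#'   stage output).
#' @export
run_subject <- function(left, right, config = pipeline_config()) {
  if (is.null(left) || is.null(right)) {
    rlang::abort("both sides are required for bilateral matching",
                 class = "coronoid_missing_side_error")
  }
  stopifnot(inherits(left, "surface_model"), inherits(right, "surface_model"))
  stage <- function(side_name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("[%s/%s] %s", right$subject_id, side_name,
                           conditionMessage(e)),
                   class = c("coronoid_stage_error", class(e)[1]))
    })
  }
  L <- stage("left", analyze_side(left, config))
  R <- stage("right", analyze_side(right, config))
  meas <- dplyr::bind_rows(
    stage("left", measure_fragment(L$fragment, slab_halfwidth = config$slab_halfwidth)),
    stage("right", measure_fragment(R$fragment, slab_halfwidth = config$slab_halfwidth))
  )
  al <- align_bilateral(L$local, R$local)
  # carry the aligned (mirrored) coordinates into the left fragment
  fragL <- L$fragment
  fragL$points[, 1] <- -fragL$points[, 1]
  fragL$points[, 3] <- fragL$points[, 3] + al$tip_dz_mm
  fragL$notch_center[1] <- -fragL$notch_center[1]
  match <- stage("match", match_pair(fragL, R$fragment, d = config$proximity_mm))
  structure(list(measurements = meas, match = match,
                 match_table = tidy(match),
                 alignment = list(tip_offset_mm = al$tip_offset_mm,
                                  tip_dz_mm = al$tip_dz_mm),
                 sides = list(left = L, right = R),
                 config = config),
            class = "coronoid_subject")
}

#' @export
print.coronoid_subject <- function(x, ...) {
  cat(sprintf("<coronoid_subject> %s\n", x$measurements$subject_id[1]))
  print(x$measurements)
  print(x$match)
  invisible(x)
}

#' Run a cohort from a manifest
#'
#' The manifest is a CSV (or tibble) with columns `subject_id`, `sex`,
#' `age`, `left_path`, `right_path`. Each subject is processed with
#' [run_subject()]; per-subject failures are logged and skipped, manifest
#' problems are fatal. Writes the per-subject measurement/match CSV, the
#' comparison-report CSV and a JSON provenance sidecar when `out_dir` is
#' given.
#'
#' @param manifest CSV path or data frame.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for report files.
#' @return List with `measurements`, `matches`, `comparisons`, `skipped`.
#' @export
run_cohort <- function(manifest, config = pipeline_config(), out_dir = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      rlang::abort("manifest file not found", class = "coronoid_io_error")
    }
    manifest <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  }
  needed <- c("subject_id", "sex", "age", "left_path", "right_path")
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    rlang::abort("manifest is empty", class = "coronoid_manifest_error")
  }
  if (!all(needed %in% names(manifest))) {
    rlang::abort(paste("manifest needs columns:", paste(needed, collapse = ", ")),
                 class = "coronoid_manifest_error")
  }
  meas <- list(); matches <- list(); skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      lm <- read_surface(row$left_path, side = "left", subject_id = row$subject_id)
      rm_ <- read_surface(row$right_path, side = "right", subject_id = row$subject_id)
      run_subject(lm, rm_, config)
    }, error = function(e) {
      rlang::inform(sprintf("skipping %s: %s", row$subject_id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      skipped <- c(skipped, row$subject_id)
      next
    }
    meas[[length(meas) + 1L]] <- dplyr::mutate(res$measurements,
                                               sex = row$sex, age = row$age)
    matches[[length(matches) + 1L]] <- res$match_table
  }
  if (length(meas) == 0L) {
    rlang::abort("no subject could be processed", class = "coronoid_manifest_error")
  }
  measurements <- dplyr::bind_rows(meas)
  match_tbl <- dplyr::bind_rows(matches)
  cohort_tbl <- measurements |>
    dplyr::left_join(dplyr::select(match_tbl, "subject_id", "covering_pct"),
                     by = "subject_id")
  comparisons <- build_report(cohort_tbl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(measurements, file.path(out_dir, "measurements.csv"), config)
    write_report(match_tbl, file.path(out_dir, "matches.csv"), config)
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    jsonlite::write_json(list(config = unclass(config),
                              n_subjects = dplyr::n_distinct(measurements$subject_id),
                              skipped = skipped,
                              r_version = as.character(getRversion())),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(measurements = measurements, matches = match_tbl,
       comparisons = comparisons, skipped = skipped)
}
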