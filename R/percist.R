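#' Convert body-weight SUV to SUL
#'
#' SUL is SUV normalised by lean body mass instead of total body weight:
#' `SUL = SUV * LBM / W`.
#'
#' @param suv_bw body-weight SUV, g/mL.
#' @param lbm_kg lean body mass, kg.
#' @param weight_kg body weight, kg.
#' @return SUL in g/mL.
#' @export
suv_to_sul <- function(suv_bw, lbm_kg, weight_kg) {
  if (any(suv_bw <= 0) || any(lbm_kg <= 0) || any(weight_kg <= 0)) {
    abort("all inputs must be positive", class = "lbmct_domain_error")
  }
  suv_bw * lbm_kg / weight_kg
}

#' Re-normalise a SUL peak under a different LBM algorithm
#'
#' Because SUL is proportional to the LBM used, a SUL peak computed with one
#' LBM algorithm converts to another by a pure ratio (body weight cancels):
#' `SUL_lc = SUL_pe * LBM_lc / LBM_pe`. This is how limited-coverage SUL
#' values are obtained from the scanner's predictive-equation SUL without
#' touching the PET data.
#'
#' @param sul_pe SUL peak under the source LBM algorithm, g/mL.
#' @param lbm_pe_kg LBM used by the source algorithm, kg.
#' @param lbm_lc_kg LBM of the target algorithm, kg.
#' @return Rescaled SUL peak, g/mL.
#' @export
rescale_sul_peak <- function(sul_pe, lbm_pe_kg, lbm_lc_kg) {
  if (any(sul_pe <= 0) || any(lbm_pe_kg <= 0) || any(lbm_lc_kg <= 0)) {
    abort("all inputs must be positive", class = "lbmct_domain_error")
  }
  sul_pe * lbm_lc_kg / lbm_pe_kg
}

#' Iterative adaptive lesion segmentation
#'
#' Finds a threshold separating lesion from background by iterating
#' `T <- w * max(values in mask) + (1 - w) * mean(values in mask)` with the
#' mask updated at every step to the voxels `>= T` that are 26-connected to
#' the hottest seed voxel. Iteration stops when the threshold moves by less
#' than `tol` or after `max_iter` steps (non-convergence yields a warning
#' and the last mask).
#'
#' @param pet a PET [image_volume()].
#' @param seed_mask logical array containing the lesion maximum (the
#'   user-placed VOI).
#' @param weight_factor weighting `w` between max and mean, in (0, 1);
#'   default 0.5.
#' @param tol convergence tolerance on the threshold (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return The final logical mask, with attributes `threshold` (converged
#'   value), `thresholds` (full sequence), `iterations`, and `converged`.
#' @export
adaptive_threshold_segment <- function(pet, seed_mask, weight_factor = 0.5,
                                       tol = 1e-6, max_iter = 100) {
  stopifnot_volume(pet)
  d <- dim(pet$voxels)
  if (!identical(dim(seed_mask), d)) abort("`seed_mask` shape mismatch")
  if (!any(seed_mask)) {
    abort("empty seed mask", class = "lbmct_segmentation_error")
  }
  if (weight_factor <= 0 || weight_factor >= 1) {
    abort("`weight_factor` must be in (0, 1)")
  }
  w <- weight_factor
  vox <- pet$voxels
  # the hottest voxel inside the seed region anchors connectivity throughout
  seed_idx <- which(seed_mask)[which.max(vox[seed_mask])]
  cur <- seed_mask
  thresholds <- numeric(0)
  t_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    vals <- vox[cur]
    t_new <- w * max(vals) + (1 - w) * mean(vals)
    thresholds <- c(thresholds, t_new)
    cand <- vox >= t_new
    if (!cand[seed_idx]) {
      abort("segmentation lost the seed maximum: empty mask",
            class = "lbmct_segmentation_error")
    }
    labels <- label_components_3d(as.logical(cand), as.integer(d), 26L)
    cur <- array(labels == labels[seed_idx], d)
    if (is.finite(t_prev) && abs(t_new - t_prev) < tol) {
      converged <- TRUE
      break
    }
    t_prev <- t_new
  }
  if (!converged) {
    warn(sprintf("adaptive segmentation did not converge in %d iterations",
                 max_iter))
  }
  structure(cur, threshold = thresholds[length(thresholds)],
            thresholds = thresholds, iterations = length(thresholds),
            converged = converged)
}

# Integer voxel offsets whose physical center lies within a sphere of the
# given diameter, for anisotropic spacing.
sphere_offsets <- function(spacing, diameter_mm) {
  r <- diameter_mm / 2
  half <- floor(r / spacing)
  g <- expand.grid(
    d1 = -half[1]:half[1], d2 = -half[2]:half[2], d3 = -half[3]:half[3]
  )
  keep <- (g$d1 * spacing[1])^2 + (g$d2 * spacing[2])^2 +
    (g$d3 * spacing[3])^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

#' SUL peak within a lesion
#'
#' The PERCIST SUL peak: the highest mean SUL over a sphere (default 12 mm
#' diameter, about 1 cm^3) centred on any voxel inside the lesion mask. The
#' sphere may extend beyond the lesion boundary, per PERCIST convention;
#' voxels falling outside the image are excluded from the mean.
#'
#' @param pet a PET [image_volume()] whose voxel values are already SUL.
#' @param lesion_mask non-empty logical array (e.g. from
#'   [adaptive_threshold_segment()]).
#' @param sphere_diameter_mm averaging-sphere diameter; default 12.
#' @return SUL peak, g/mL.
#' @export
sul_peak <- function(pet, lesion_mask, sphere_diameter_mm = 12) {
  stopifnot_volume(pet)
  d <- dim(pet$voxels)
  if (!identical(dim(lesion_mask), d)) abort("`lesion_mask` shape mismatch")
  if (!any(lesion_mask)) abort("empty lesion mask",
                               class = "lbmct_content_error")
  if (any(sphere_diameter_mm > d * pet$spacing)) {
    abort("averaging sphere larger than the image",
          class = "lbmct_geometry_error")
  }
  off <- sphere_offsets(pet$spacing, sphere_diameter_mm)
  centers <- which(array(lesion_mask, d), arr.ind = TRUE)
  sums <- numeric(nrow(centers))
  counts <- numeric(nrow(centers))
  vox <- pet$voxels
  for (k in seq_len(nrow(off))) {
    i1 <- centers[, 1] + off[k, 1]
    i2 <- centers[, 2] + off[k, 2]
    i3 <- centers[, 3] + off[k, 3]
    ok <- i1 >= 1 & i1 <= d[1] & i2 >= 1 & i2 <= d[2] & i3 >= 1 & i3 <= d[3]
    lin <- (i3[ok] - 1) * d[1] * d[2] + (i2[ok] - 1) * d[1] + i1[ok]
    sums[ok] <- sums[ok] + vox[lin]
    counts[ok] <- counts[ok] + 1
  }
  max(sums / counts)
}

#' Background statistics from a spherical ROI
#'
#' Mean and SD of SUL within a sphere, as used for the PERCIST liver
#' background (3-cm-diameter ROI in the right hepatic lobe) or, manually,
#' the blood-pool reference. SD is the sample SD by default, matching
#' clinical software; population SD is available via `sd_type`.
#'
#' @param pet a PET [image_volume()] in SUL units.
#' @param center_mm physical coordinate of the sphere center (mm, same frame
#'   as the volume origin, `(slice, row, column)` axis order).
#' @param diameter_mm sphere diameter; default 30 (the PERCIST liver ROI).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A one-row tibble: `liver_sul_mean`, `liver_sul_sd`, `n_voxels`,
#'   `roi_center`, `roi_diameter_mm`, `sd_type`.
#' @export
liver_background <- function(pet, center_mm, diameter_mm = 30,
                             sd_type = c("sample", "population")) {
  stopifnot_volume(pet)
  sd_type <- match.arg(sd_type)
  d <- dim(pet$voxels)
  r <- diameter_mm / 2
  extent_lo <- pet$origin
  extent_hi <- pet$origin + (d - 1) * pet$spacing
  if (any(center_mm - r < extent_lo - pet$spacing / 2) ||
      any(center_mm + r > extent_hi + pet$spacing / 2)) {
    abort("background sphere does not fit inside the volume",
          class = "lbmct_geometry_error")
  }
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  pos <- sweep(sweep(idx - 1, 2, pet$spacing, `*`), 2, pet$origin, `+`)
  inside <- rowSums(sweep(pos, 2, center_mm, `-`)^2) <= r^2
  vals <- pet$voxels[inside]
  if (length(vals) == 0) {
    abort("background sphere contains no voxel centers",
          class = "lbmct_geometry_error")
  }
  s <- if (length(vals) < 2) 0 else sd(vals)
  if (sd_type == "population") {
    s <- sqrt(mean((vals - mean(vals))^2))
  }
  tibble(
    liver_sul_mean = mean(vals), liver_sul_sd = s,
    n_voxels = length(vals),
    roi_center = list(as.numeric(center_mm)),
    roi_diameter_mm = diameter_mm, sd_type = sd_type
  )
}

#' Manually-specified background statistics
#'
#' Convenience constructor for [is_measurable()] when background values come
#' from a report rather than a volume.
#'
#' @param liver_sul_mean,liver_sul_sd liver background mean and SD, g/mL.
#' @param blood_sul_mean optional blood-pool mean SUL, g/mL (1-cm-diameter
#'   aortic ROI over a 2-cm z extent in the clinical setting).
#' @return A one-row tibble compatible with [liver_background()] output.
#' @export
background_stats <- function(liver_sul_mean, liver_sul_sd,
                             blood_sul_mean = NA_real_) {
  if (liver_sul_sd < 0) abort("`liver_sul_sd` must be non-negative")
  tibble(liver_sul_mean = liver_sul_mean, liver_sul_sd = liver_sul_sd,
         blood_sul_mean = blood_sul_mean)
}

#' PERCIST lesion measurability
#'
#' Liver rule: the baseline lesion SUL peak must be at least
#' `1.5 * liver mean + 2 * liver SD` (the standard PERCIST 1.0 reading; the
#' stricter parse `1.5 * (mean + 2 SD)` is available via `alternate_parse`).
#' Blood-pool rule (for abnormal livers): uptake must exceed
#' `2.0 * blood-pool mean SUL`.
#'
#' @param baseline_sul_peak lesion SUL peak at baseline, g/mL.
#' @param bg background tibble from [liver_background()] or
#'   [background_stats()].
#' @param use_blood_pool use the blood-pool rule instead of the liver rule.
#' @param alternate_parse apply the threshold as `1.5 * (mean + 2 SD)`.
#' @return A tibble: `measurable`, `threshold`, `rule`.
#' @export
is_measurable <- function(baseline_sul_peak, bg, use_blood_pool = FALSE,
                          alternate_parse = FALSE) {
  if (use_blood_pool) {
    blood <- bg$blood_sul_mean
    if (is.null(blood) || !all(is.finite(blood))) {
      abort("blood-pool rule requested but `blood_sul_mean` is missing",
            class = "lbmct_config_error")
    }
    thr <- 2.0 * blood
    ok <- baseline_sul_peak > thr
    rule <- "blood_pool"
  } else {
    thr <- if (alternate_parse) {
      1.5 * (bg$liver_sul_mean + 2 * bg$liver_sul_sd)
    } else {
      1.5 * bg$liver_sul_mean + 2 * bg$liver_sul_sd
    }
    ok <- baseline_sul_peak >= thr
    rule <- "liver"
  }
  tibble(measurable = ok, threshold = thr, rule = rule)
}

#' Percent change between paired SUL peaks
#'
#' @param baseline,followup SUL peaks, g/mL; `baseline` must be positive.
#' @return `100 * (followup - baseline) / baseline`.
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline <= 0)) {
    abort("`baseline` must be positive", class = "lbmct_domain_error")
  }
  100 * (followup - baseline) / baseline
}

#' PERCIST response classification
#'
#' Three-class PERCIST 1.0 response from a paired SUL-peak measurement:
#' partial metabolic response (PMR) when the SUL peak falls by at least
#' `threshold_pct` percent AND by at least `min_abs_change` g/mL;
#' progressive metabolic disease (PMD) when it rises by at least as much;
#' stable metabolic disease (SMD) otherwise. Both gates are inclusive at the
#' boundary. Complete metabolic response is not emitted: the intended
#' setting is cohorts selected for persisting FDG-avid disease, so the
#' three-class scheme is native; a follow-up SUL at or below background can
#' be flagged separately.
#'
#' @param baseline,followup SUL peaks, g/mL (vectorised).
#' @param threshold_pct percent-change threshold; default 30.
#' @param min_abs_change minimal absolute SUL change gate; default 0.8.
#' @return A tibble: `baseline`, `followup`, `percent_change`, `abs_change`,
#'   `response` (ordered factor PMD < SMD < PMR).
#' @export
#' @examples
#' classify_response(5, 3.5)$response   # PMR (-30%, |change| 1.5)
#' classify_response(2, 1.4)$response   # SMD (-30% but |change| 0.6 < 0.8)
classify_response <- function(baseline, followup, threshold_pct = 30,
                              min_abs_change = 0.8) {
  if (any(followup <= 0)) {
    abort("`followup` must be positive", class = "lbmct_domain_error")
  }
  pc <- percent_change(baseline, followup)
  abs_change <- followup - baseline
  gate <- abs(abs_change) >= min_abs_change
  cls <- rep("SMD", length(pc))
  cls[pc <= -threshold_pct & gate] <- "PMR"
  cls[pc >= threshold_pct & gate] <- "PMD"
  tibble(
    baseline = as.numeric(baseline), followup = as.numeric(followup),
    percent_change = pc, abs_change = abs_change,
    response = as_response(cls)
  )
}

#' Select the target lesion (hottest-lesion rule)
#'
#' Picks the lesion with the maximal SUL peak from one scan's lesion table.
#' The follow-up target may be a different lesion than baseline's. Ties are
#' broken deterministically by lexicographic `lesion_id`.
#'
#' @param lesions data frame with at least `sul_peak` and `lesion_id`; if a
#'   `timepoint` column is present it must be constant.
#' @return The selected row (one-row tibble).
#' @export
select_target_lesion <- function(lesions) {
  if (nrow(lesions) == 0) {
    abort("empty lesion list", class = "lbmct_content_error")
  }
  if ("timepoint" %in% names(lesions) &&
      length(unique(lesions$timepoint)) > 1) {
    abort("lesions must all come from the same timepoint")
  }
  out <- dplyr::arrange(lesions, dplyr::desc(.data$sul_peak), .data$lesion_id)
  as_tibble(out[1, , drop = FALSE])
}

#' Classify a paired-timepoint lesion table under both LBM algorithms
#'
#' The full dual-algorithm PERCIST pipeline on a tidy lesion table: per
#' patient and timepoint the hottest lesion is selected as target, the
#' predictive-equation SUL peak is re-normalised to the limited-coverage LBM
#' by [rescale_sul_peak()], and the response is classified under both
#' algorithms.
#'
#' @param lesions data frame with columns `patient_id`, `timepoint`
#'   (`"baseline"`/`"followup"`), `lesion_id`, `sul_peak_pe`, `lbm_pe_kg`,
#'   `lbm_lc_kg` (and optionally `weight_kg`, carried through).
#' @param threshold_pct,min_abs_change see [classify_response()].
#' @return A tibble, one row per patient: SUL peaks and percent changes
#'   under both algorithms, `response_pe`, `response_lc`, `discordant`.
#' @export
percist_compare <- function(lesions, threshold_pct = 30,
                            min_abs_change = 0.8) {
  need <- c("patient_id", "timepoint", "lesion_id", "sul_peak_pe",
            "lbm_pe_kg", "lbm_lc_kg")
  missing_cols <- setdiff(need, names(lesions))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!all(lesions$timepoint %in% c("baseline", "followup"))) {
    abort("`timepoint` must be 'baseline' or 'followup'")
  }
  targets <- lesions |>
    mutate(sul_peak = .data$sul_peak_pe) |>
    group_by(.data$patient_id, .data$timepoint) |>
    dplyr::group_modify(~ select_target_lesion(.x)) |>
    ungroup() |>
    mutate(sul_peak_lc = rescale_sul_peak(
      .data$sul_peak_pe, .data$lbm_pe_kg, .data$lbm_lc_kg
    ))
  wide <- targets |>
    select(dplyr::all_of(c("patient_id", "timepoint", "lesion_id",
                           "sul_peak_pe", "sul_peak_lc",
                           "lbm_pe_kg", "lbm_lc_kg"))) |>
    tidyr::pivot_wider(
      id_cols = "patient_id", names_from = "timepoint",
      values_from = c("lesion_id", "sul_peak_pe", "sul_peak_lc",
                      "lbm_pe_kg", "lbm_lc_kg")
    )
  if (!all(c("sul_peak_pe_baseline", "sul_peak_pe_followup") %in%
           names(wide))) {
    abort("every patient needs both a baseline and a followup timepoint")
  }
  pe <- classify_response(wide$sul_peak_pe_baseline,
                          wide$sul_peak_pe_followup,
                          threshold_pct, min_abs_change)
  lc <- classify_response(wide$sul_peak_lc_baseline,
                          wide$sul_peak_lc_followup,
                          threshold_pct, min_abs_change)
  wide |>
    mutate(
      percent_change_pe = pe$percent_change,
      percent_change_lc = lc$percent_change,
      response_pe = pe$response,
      response_lc = lc$response,
      discordant = pe$response != lc$response
    )
}
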