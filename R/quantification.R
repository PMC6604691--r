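#' Convert activity concentration to SUV
#'
#' Standardized uptake value: tissue activity concentration normalized by
#' injected activity per unit body mass, assuming 1 g/mL tissue density, so
#' a uniform distribution of the injected activity over the whole body gives
#' SUV = 1 everywhere.
#'
#' @param conc activity concentration in kBq/mL (>= 0).
#' @param injected_activity_MBq injected activity in MBq (> 0).
#' @param body_weight_kg body weight in kg (> 0).
#' @return dimensionless SUV.
#' @export
suv_from_activity <- function(conc, injected_activity_MBq, body_weight_kg) {
  check_scalar(injected_activity_MBq, "injected_activity_MBq", positive = TRUE)
  check_scalar(body_weight_kg, "body_weight_kg", positive = TRUE)
  if (any(conc < 0)) stop_domain("'conc' must be >= 0")
  # injected activity per gram of tissue, in kBq/g (= kBq/mL at 1 g/mL)
  conc / (injected_activity_MBq * 1000 / (body_weight_kg * 1000))
}

#' SUV image volume
#'
#' A small voxel grid of SUV values with isotropic-or-not voxel spacing,
#' sufficient for VOI statistics (no scanner geometry beyond spacing).
#'
#' @param voxel_values 3D numeric array of SUVs.
#' @param voxel_size_mm voxel edge lengths in mm, length 1 or 3.
#' @param origin_mm world coordinate of the first voxel center, length 3.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxel_values, voxel_size_mm = 4, origin_mm = c(0, 0, 0)) {
  if (!is.array(voxel_values) || length(dim(voxel_values)) != 3L)
    stop_domain("'voxel_values' must be a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop_domain("'voxel_size_mm' must be > 0")
  structure(list(voxel_values = voxel_values,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "image_volume")
}

#' Volume-of-interest mask
#'
#' @param membership logical 3D array, same shape as its volume.
#' @param label organ or lesion name.
#' @param nominal_volume_ml optional target volume of a fixed-size VOI.
#' @return an object of class `voi_mask`.
#' @export
voi_mask <- function(membership, label = "voi", nominal_volume_ml = NULL) {
  if (!is.array(membership) || length(dim(membership)) != 3L)
    stop_domain("'membership' must be a 3D logical array")
  membership <- array(as.logical(membership), dim(membership))
  if (!any(membership)) stop_domain("mask selects no voxels")
  structure(list(membership = membership, label = label,
                 nominal_volume_ml = nominal_volume_ml),
            class = "voi_mask")
}

#' Spherical fixed-size VOI at a given center
#'
#' Builds the mask of voxels whose centers fall inside a sphere of the given
#' volume, the convention used for fixed-size reference VOIs (e.g. 7.5 mL in
#' a lumbar vertebra for marrow, 1.6 mL in the aortic arch for blood pool).
#' Placement is user-given; automatic placement is out of scope.
#'
#' @param volume an [image_volume()].
#' @param center_mm sphere center in world mm.
#' @param volume_ml sphere volume in mL (1 mL = 1 cm^3).
#' @param label mask label.
#' @return a [voi_mask()].
#' @export
sphere_voi <- function(volume, center_mm, volume_ml, label = "sphere") {
  stopifnot(inherits(volume, "image_volume"))
  r_mm <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)  # mL -> mm^3
  d <- dim(volume$voxel_values)
  co <- voxel_centers(volume)
  dist2 <- outer_dist2(co, center_mm)
  voi_mask(array(dist2 <= r_mm^2, d), label = label,
           nominal_volume_ml = volume_ml)
}

## voxel center coordinate arrays for a volume
voxel_centers <- function(volume) {
  d <- dim(volume$voxel_values)
  vs <- volume$voxel_size_mm; o <- volume$origin_mm
  list(x = o[1] + (seq_len(d[1]) - 1) * vs[1],
       y = o[2] + (seq_len(d[2]) - 1) * vs[2],
       z = o[3] + (seq_len(d[3]) - 1) * vs[3])
}

## squared distance of every voxel center to a point, as a 3D array
outer_dist2 <- function(co, p) {
  dx2 <- (co$x - p[1])^2; dy2 <- (co$y - p[2])^2; dz2 <- (co$z - p[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Mean SUV within a VOI
#'
#' @param volume an [image_volume()].
#' @param mask a [voi_mask()] of the same shape.
#' @return arithmetic mean of the masked voxel SUVs.
#' @export
suv_mean <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$voxel_values), dim(mask$membership)))
    stop_domain("mask shape does not match volume")
  mean(volume$voxel_values[mask$membership])
}

#' Maximum SUV within a VOI
#'
#' @inheritParams suv_mean
#' @export
suv_max <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  max(volume$voxel_values[mask$membership])
}

#' Peak SUV within a VOI
#'
#' SUVpeak: the maximum, over sphere centers placed at masked voxel centers,
#' of the mean SUV of all voxels whose centers fall within a sphere of the
#' given volume (default 1 mL, the common convention). The sphere may
#' extend beyond the mask; its center may not. If the mask itself is smaller
#' than the sphere, the function falls back to the mask mean and flags the
#' result (attribute `fallback`, plus a warning), since peak averaging would
#' be dominated by surround.
#'
#' @inheritParams suv_mean
#' @param sphere_volume_ml averaging-sphere volume in mL.
#' @return SUVpeak (numeric); attribute `fallback` is TRUE when the mask
#'   mean was substituted.
#' @export
suv_peak <- function(volume, mask, sphere_volume_ml = 1.0) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$voxel_values), dim(mask$membership)))
    stop_domain("mask shape does not match volume")
  vox_ml <- prod(volume$voxel_size_mm) / 1000
  n_mask <- sum(mask$membership)
  if (n_mask * vox_ml < sphere_volume_ml) {
    warning("lesion smaller than averaging sphere: returning mask mean")
    return(structure(suv_mean(volume, mask), fallback = TRUE))
  }
  r_mm <- (3 * sphere_volume_ml * 1000 / (4 * pi))^(1 / 3)
  co <- voxel_centers(volume)
  idx <- which(mask$membership, arr.ind = TRUE)
  vals <- volume$voxel_values
  best <- -Inf
  for (i in seq_len(nrow(idx))) {
    p <- c(co$x[idx[i, 1]], co$y[idx[i, 2]], co$z[idx[i, 3]])
    inside <- outer_dist2(co, p) <= r_mm^2
    m <- mean(vals[inside])
    if (m > best) best <- m
  }
  structure(best, fallback = FALSE)
}

#' Filter lesions by minimum diameter
#'
#' Small lesions suffer partial-volume underestimation, so only lesions at
#' least `min_diameter_cm` across (default 2 cm, inclusive) are quantified.
#'
#' @param records data.frame with at least a `diameter_cm` column (plus
#'   typically `lesion_id`, `tissue_class`, `patient_id`).
#' @param min_diameter_cm inclusive threshold, cm.
#' @return the retained rows, original order preserved.
#' @export
filter_lesions <- function(records, min_diameter_cm = 2.0) {
  if (nrow(records) == 0) return(records)
  if (any(records$diameter_cm <= 0, na.rm = TRUE))
    stop_domain("lesion diameters must be > 0")
  records[!is.na(records$diameter_cm) &
          records$diameter_cm >= min_diameter_cm, , drop = FALSE]
}

#' Immunohistochemistry H-score
#'
#' Intensity-weighted staining score on a 0-300 scale:
#' `1 * (% weak) + 2 * (% moderate) + 3 * (% strong)`.
#'
#' @param pct_weak,pct_moderate,pct_strong percentages of tumor cells at
#'   staining intensities 1+, 2+ and 3+; each in \[0, 100\], sum <= 100.
#' @return H-score in \[0, 300\].
#' @export
hscore <- function(pct_weak, pct_moderate, pct_strong) {
  p <- c(pct_weak, pct_moderate, pct_strong)
  if (length(p) != 3L || any(!is.finite(p)))
    stop_domain("three finite percentages are required")
  if (any(p < 0) || any(p > 100))
    stop_domain("percentages must lie in [0, 100]")
  if (sum(p) > 100 + 1e-9)
    stop_domain("staining percentages sum to more than 100")
  1 * pct_weak + 2 * pct_moderate + 3 * pct_strong
}

#' Read a lesion SUVpeak table
#'
#' Long-format CSV with columns `patient_id`, `lesion_id`, `tissue_class`,
#' `administration`, `time_h`, `suv_peak` (and optionally `dose_mg_kg`).
#' The tokens `BLQ` (below limit of quantification) and `NA` in `suv_peak`
#' become explicit missing values that summaries exclude.
#'
#' @param path CSV file path.
#' @return data.frame with numeric `suv_peak` (NA for BLQ/NA cells).
#' @export
read_lesion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(suv_peak = "character"))
  raw <- trimws(df$suv_peak)
  df$suv_peak <- suppressWarnings(as.numeric(ifelse(
    raw %in% c("BLQ", "NA", ""), NA_character_, raw)))
  df$time_h <- as.numeric(df$time_h)
  df
}

#' SUVpeak range over a lesion table
#'
#' Minimum and maximum SUVpeak across all lesions and scan times of one
#' administration, after excluding below-limit-of-quantification and
#' not-assessed entries, reported rounded half-up to one decimal (the
#' convention under which 15.66 prints as 15.7).
#'
#' @param lesions data.frame as from [read_lesion_table()] (or the
#'   `lesions` table of a [generate_study()] result).
#' @param administration `"first"` or `"second"`.
#' @param digits decimals for the rounded report (default 1).
#' @return list with `min` and `max` (rounded), plus `n` quantified values.
#' @export
suv_table_summary <- function(lesions, administration = c("first", "second"),
                              digits = 1) {
  administration <- match.arg(administration)
  v <- lesions$suv_peak[lesions$administration == administration]
  v <- v[is.finite(v)]
  if (length(v) == 0)
    stop_domain("no quantifiable SUV values for this administration")
  list(min = round_half_up(min(v), digits),
       max = round_half_up(max(v), digits),
       n = length(v))
}

#' Path to the packaged lesion SUVpeak fixture table
#'
#' A small long-format CSV of per-lesion SUVpeak values across scan times
#' for a 6-patient, two-administration study, including `BLQ`/`NA` cells,
#' used by examples and tests.
#'
#' @return file path inside the installed package.
#' @export
lesion_table_fixture <- function() {
  system.file("extdata", "lesion_suvpeak_table.csv", package = "immunopet",
              mustWork = TRUE)
}
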