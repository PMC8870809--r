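# Reading PET/CT volumes and fixing them onto the CNN input grid.
#
# The network consumes a fixed physical field: 128 x 128 x 256 voxels at
# 4 mm isotropic spacing (a 512 x 512 x 1024 mm box, covering whole-body
# acquisition fields up to ~102 cm axially), with CT and PET aligned at one
# origin and affinely rescaled to [0,1].

#' Fixed CNN input grid
#'
#' @return List with `shape` (128, 128, 256) and `spacing` (4, 4, 4) mm.
#' @export
cnn_grid <- function() list(shape = c(128L, 128L, 256L), spacing = c(4, 4, 4))

#' Check axial slice geometry
#'
#' Quality check applied before any volume enters the pipeline: axial slice
#' positions must be complete (no missing slices) and regularly spaced.
#' Fails with a message naming the defect.
#'
#' @param z_positions_mm Sorted or unsorted axial slice positions (mm).
#' @param tol_mm Allowed deviation of any gap from the median gap.
#' @return The common slice interval (mm), invisibly.
#' @export
qc_slice_positions <- function(z_positions_mm, tol_mm = 0.01) {
  z <- sort(as.numeric(z_positions_mm))
  if (length(z) < 2) stop("quality check failed: fewer than 2 axial slices")
  gaps <- diff(z)
  if (any(gaps <= tol_mm))
    stop("quality check failed: duplicate axial slice positions")
  ref <- median(gaps)
  bad <- which(abs(gaps - ref) > tol_mm)
  if (length(bad)) {
    if (any(abs(gaps[bad] / ref - round(gaps[bad] / ref)) < tol_mm / ref &
              gaps[bad] > 1.5 * ref))
      stop(sprintf("quality check failed: missing axial slice(s) near z = %.2f mm",
                   z[bad[1]]))
    stop(sprintf("quality check failed: irregular slice interval near z = %.2f mm (gap %.3f vs %.3f mm)",
                 z[bad[1]], gaps[bad[1]], ref))
  }
  invisible(ref)
}

#' Load a NIfTI volume
#'
#' Reads values and geometry from the header and normalizes to the package
#' convention: 0-based voxel indices map to world coordinates through
#' `origin + index * spacing`, axes ordered (x, y, z-axial). Negative-
#' determinant (flipped) axes are not reoriented; the pipeline assumes the
#' axis-aligned geometry it writes itself.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param modality `"PET_SUV"` or `"CT_HU"`.
#' @return A [volume_grid()].
#' @export
load_volume <- function(path, modality = c("PET_SUV", "CT_HU")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("quality check failed: expected a 3D volume, got %dD",
                 length(dim(img))))
  geom <- read_nifti_geometry(img)
  if (any(!is.finite(geom$spacing)) || any(geom$spacing <= 0))
    stop("quality check failed: non-positive voxel spacing in header")
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  if (modality == "PET_SUV") vals[vals < 0] <- 0
  volume_grid(vals, geom$spacing, geom$origin, modality)
}

#' Body-weight SUV from activity concentration
#'
#' SUVbw = activity / (decay-corrected injected dose / body weight), with
#' the dose decay-corrected from injection to series start:
#' `dose * 2^(-delay / half-life)`. For 18F the half-life is 109.77 min.
#'
#' @param activity_bqml Measured activity concentration (Bq/mL).
#' @param injected_dose_bq Injected dose at injection time (Bq).
#' @param weight_kg Patient body weight (kg).
#' @param delay_s Seconds from injection to series start.
#' @param half_life_s Radionuclide half-life (s); default 18F.
#' @return SUV (g/mL), same shape as `activity_bqml`.
#' @export
suv_from_activity <- function(activity_bqml, injected_dose_bq, weight_kg,
                              delay_s = 0, half_life_s = 6586.2) {
  if (injected_dose_bq <= 0 || weight_kg <= 0 || half_life_s <= 0)
    stop("dose, weight and half-life must be positive")
  dose_at_scan <- injected_dose_bq * 2^(-delay_s / half_life_s)
  activity_bqml * (weight_kg * 1000) / dose_at_scan
}

# affine map from 0-based output voxel index to 0-based input index, for a
# resampling between two axis-aligned grids
index_affine <- function(in_spacing, in_origin, out_spacing, out_origin) {
  A <- diag(out_spacing / in_spacing)
  b <- (out_origin - in_origin) / in_spacing
  list(A = A, b = b)
}

#' Resample a volume onto the fixed CNN grid
#'
#' Trilinear interpolation onto `shape` voxels at `spacing` mm. The output
#' physical field is centred on the input field's centre; voxels falling
#' outside the input field are filled with the modality background (0 SUV
#' for PET, -1000 HU for CT).
#'
#' @param v A [volume_grid()].
#' @param shape,spacing Target grid; defaults to [cnn_grid()].
#' @return A [volume_grid()] on the target grid.
#' @export
resample_to_grid <- function(v, shape = cnn_grid()$shape,
                             spacing = cnn_grid()$spacing) {
  stopifnot(inherits(v, "volume_grid"))
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  fill <- if (v$modality == "CT_HU") -1000 else 0
  out_origin <- grid_center_mm(v) - (shape - 1) / 2 * spacing
  m <- index_affine(v$spacing, v$origin, spacing, out_origin)
  vals <- resample_affine_cpp(as.numeric(v$values), dim(v$values), shape,
                              m$A, m$b, TRUE, fill)
  dim(vals) <- shape
  if (v$modality == "PET_SUV") vals[vals < 0] <- 0
  volume_grid(vals, spacing, out_origin, v$modality)
}

#' Resample a mask or ROI set with nearest-neighbour interpolation
#'
#' Labels are never interpolated: each output voxel takes the value of its
#' nearest input voxel, so the label set can shrink but never grow.
#'
#' @param mask A [binary_mask()], [prob_mask()] or [roi_set()].
#' @param target A grid-bearing object (e.g. a resampled [volume_grid()])
#'   defining shape, spacing and origin.
#' @return The mask resampled onto `target`'s grid.
#' @export
resample_mask <- function(mask, target) {
  tshape <- grid_shape(target)
  m <- index_affine(mask$spacing, mask$origin, target$spacing, target$origin)
  nn <- function(arr, fill = 0) {
    v <- resample_affine_cpp(as.numeric(arr), dim(arr), tshape, m$A, m$b,
                             FALSE, fill)
    dim(v) <- tshape
    v
  }
  if (inherits(mask, "roi_set")) {
    rois <- lapply(mask$rois, function(r) nn(r) > 0.5)
    return(roi_set(rois, target$spacing, target$origin))
  }
  if (inherits(mask, "prob_mask"))
    return(prob_mask(nn(mask$values), target$spacing, target$origin))
  binary_mask(nn(mask$values) > 0.5, target$spacing, target$origin)
}

#' Scale an aligned CT/PET pair to the network input range
#'
#' Affine maps CT \[-1000, 1000\] HU and PET \[0, 25\] SUV onto \[0, 1\],
#' clipping values outside those ranges, and stacks the two channels. Both
#' volumes must already live on one grid with one origin.
#'
#' @param ct,pet [volume_grid()]s on the same grid.
#' @return An object of class `scaled_input`: list with `ct`, `pet`
#'   (arrays in \[0,1\]), `spacing`, `origin`.
#' @export
scale_intensities <- function(ct, pet) {
  stopifnot(inherits(ct, "volume_grid"), inherits(pet, "volume_grid"))
  if (ct$modality != "CT_HU" || pet$modality != "PET_SUV")
    stop("`ct` must be CT_HU and `pet` PET_SUV")
  stop_unless_same_grid(ct, pet, "CT and PET")
  structure(list(ct = pmin(pmax((ct$values + 1000) / 2000, 0), 1),
                 pet = pmin(pmax(pet$values / 25, 0), 1),
                 spacing = ct$spacing, origin = ct$origin),
            class = "scaled_input")
}

#' Invert the PET intensity scaling
#'
#' @param scaled Values in \[0,1\] produced by [scale_intensities()].
#' @return SUV values (exact for SUV in \[0,25\]; clipped values are not
#'   recoverable).
#' @export
unscale_pet <- function(scaled) scaled * 25

#' Full preprocessing of one PET/CT pair
#'
#' Convenience wrapper: resample both volumes to the fixed grid (centred on
#' the PET field) and scale to \[0,1\].
#'
#' @param pet,ct [volume_grid()]s in native geometry.
#' @param shape,spacing Target grid; defaults to [cnn_grid()].
#' @return List with `input` (a `scaled_input`), `pet_grid`, `ct_grid`
#'   (the resampled unscaled volumes).
#' @export
preprocess_case <- function(pet, ct, shape = cnn_grid()$shape,
                            spacing = cnn_grid()$spacing) {
  pet_rs <- resample_to_grid(pet, shape, spacing)
  ct_rs <- resample_to_grid(ct, shape, spacing)
  # align CT onto the PET-centred grid if the native fields differed
  if (!same_grid(ct_rs, pet_rs)) {
    m <- index_affine(ct$spacing, ct$origin, pet_rs$spacing, pet_rs$origin)
    vals <- resample_affine_cpp(as.numeric(ct$values), dim(ct$values),
                                grid_shape(pet_rs), m$A, m$b, TRUE, -1000)
    dim(vals) <- grid_shape(pet_rs)
    ct_rs <- volume_grid(vals, pet_rs$spacing, pet_rs$origin, "CT_HU")
  }
  list(input = scale_intensities(ct_rs, pet_rs), pet_grid = pet_rs,
       ct_grid = ct_rs)
}
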