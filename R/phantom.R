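# Synthetic whole-body PET/CT phantoms with analytic ground truth.
#
# Real baseline lymphoma PET/CT with expert delineations is restricted data;
# the phantom generator stands in for it. It emulates the features the TMTV
# pipeline must cope with: FDG-avid lesions (including coalescent double-peak
# masses and heterogeneous uptake profiles), physiological uptakes (brain,
# bladder) that must not enter the tumor mask, an optional injection-site
# artifact at the arm edge (a classic false-positive source), Gaussian image
# noise, and a schematic CT giving plausible Hounsfield ranges.

#' Specify one ellipsoidal lesion
#'
#' A lesion is an axis-aligned ellipsoid with half-axes `radii_mm` around
#' `center_mm` (world coordinates, mm). Its noise-free uptake profile is
#' either `"flat"` (uniform `peak_suv` inside the ellipsoid) or `"gaussian"`
#' (peaking at `peak_suv` in the centre and decaying so that the profile
#' crosses the phantom's background SUV exactly at the ellipsoid surface —
#' both profiles therefore share the same analytic truth region). An
#' optional `partner_offset_mm` adds a second identical peak at
#' `center_mm + partner_offset_mm` under the same lesion id, producing the
#' coalescent double-peak masses that the watershed post-processing is
#' designed to split.
#'
#' @param center_mm Lesion centre, length-3 world coordinate (mm).
#' @param radii_mm Ellipsoid half-axes (mm), strictly positive, length 3
#'   (a scalar is recycled to a sphere).
#' @param peak_suv Peak SUV, strictly positive.
#' @param profile `"flat"` or `"gaussian"`.
#' @param partner_offset_mm Optional length-3 offset (mm) of a partner peak.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radii_mm, peak_suv, profile = c("flat", "gaussian"),
                        partner_offset_mm = NULL) {
  profile <- match.arg(profile)
  center_mm <- as.numeric(center_mm)
  radii_mm <- rep_len(as.numeric(radii_mm), 3L)
  if (length(center_mm) != 3L) stop("`center_mm` must have length 3")
  if (any(radii_mm <= 0)) stop("`radii_mm` must be strictly positive")
  if (peak_suv <= 0) stop("`peak_suv` must be strictly positive")
  if (!is.null(partner_offset_mm)) {
    partner_offset_mm <- as.numeric(partner_offset_mm)
    if (length(partner_offset_mm) != 3L) stop("`partner_offset_mm` must have length 3")
  }
  structure(list(center_mm = center_mm, radii_mm = radii_mm,
                 peak_suv = peak_suv, profile = profile,
                 partner_offset_mm = partner_offset_mm),
            class = "lesion_spec")
}

#' Analytic lesion volume in mL
#'
#' Ellipsoid volume 4/3*pi*r1*r2*r3; a double-peak lesion counts the union
#' of its two (possibly overlapping) ellipsoids, evaluated analytically for
#' disjoint peaks and numerically (fine fixed lattice) when they overlap.
#'
#' @param lesion A `lesion_spec`.
#' @return Volume in mL.
#' @export
lesion_analytic_volume_ml <- function(lesion) {
  v1 <- 4 / 3 * pi * prod(lesion$radii_mm) / 1000
  if (is.null(lesion$partner_offset_mm)) return(v1)
  off <- lesion$partner_offset_mm
  # separated peaks: volumes add; overlapping: integrate on a 0.5 mm lattice
  if (sum((off / (2 * lesion$radii_mm))^2) >= 1) return(2 * v1)
  r <- lesion$radii_mm
  lo <- pmin(-r, off - r); hi <- pmax(r, off + r)
  step <- min(r) / 10
  gx <- seq(lo[1], hi[1], by = step); gy <- seq(lo[2], hi[2], by = step)
  gz <- seq(lo[3], hi[3], by = step)
  inside <- 0
  for (z in gz) {
    d1z <- (z / r[3])^2; d2z <- ((z - off[3]) / r[3])^2
    m1 <- outer((gx / r[1])^2, (gy / r[2])^2, `+`) + d1z < 1
    m2 <- outer(((gx - off[1]) / r[1])^2, ((gy - off[2]) / r[2])^2, `+`) + d2z < 1
    inside <- inside + sum(m1 | m2)
  }
  inside * step^3 / 1000
}

#' Specify a synthetic whole-body PET/CT phantom
#'
#' @param grid_shape Integer length 3, voxel counts per axis.
#' @param voxel_spacing_mm Numeric length 3, voxel spacing (mm).
#' @param lesions List of [lesion_spec()] objects.
#' @param organ_uptakes List of physiological uptake spheres, each a list
#'   with `center_mm`, `radius_mm`, `suv`. Excluded from the truth masks.
#' @param background_suv Soft-tissue background SUV; must be below every
#'   lesion peak (lesions are FDG-avid).
#' @param noise_sd SD of additive Gaussian noise on the PET (SUV units),
#'   clipped so SUV stays >= 0.
#' @param artifact Optional injection-site artifact, a list with
#'   `center_mm`, `radius_mm`, `suv`; use [default_injection_artifact()] for
#'   a canonical arm-edge site. Excluded from the truth masks.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm, lesions = list(),
                         organ_uptakes = list(), background_suv = 1.0,
                         noise_sd = 0.15, artifact = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("`voxel_spacing_mm` must be 3 positive reals")
  if (background_suv <= 0) stop("`background_suv` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  extent <- (grid_shape - 1) * voxel_spacing_mm
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    if (!inherits(les, "lesion_spec")) stop("`lesions` must contain lesion_spec objects")
    if (any(les$center_mm < 0) || any(les$center_mm > extent))
      stop(sprintf("lesion %d: center (%s) mm lies outside the grid", i,
                   paste(format(les$center_mm), collapse = ", ")))
    if (les$peak_suv <= background_suv)
      stop(sprintf("lesion %d: peak SUV %.3g not above background %.3g (lesions are FDG-avid)",
                   i, les$peak_suv, background_suv))
  }
  for (org in organ_uptakes) {
    if (any(org$center_mm < 0) || any(org$center_mm > extent))
      stop("organ uptake centre lies outside the grid")
  }
  structure(list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
                 lesions = lesions, organ_uptakes = organ_uptakes,
                 background_suv = background_suv, noise_sd = noise_sd,
                 artifact = artifact, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Canonical injection-site artifact
#'
#' A small hot blob near the lateral (arm) edge of the field, roughly at
#' shoulder height — FDG extravasated at the injection site. It is part of
#' the PET signal but never of the tumor truth, so it exercises the
#' pipeline's false-positive behaviour.
#'
#' @param grid_shape,voxel_spacing_mm Phantom geometry.
#' @param suv Artifact peak SUV.
#' @param radius_mm Artifact radius (mm).
#' @return A list usable as the `artifact` field of [phantom_spec()].
#' @export
default_injection_artifact <- function(grid_shape, voxel_spacing_mm,
                                       suv = 10, radius_mm = 8) {
  extent <- (as.integer(grid_shape) - 1) * as.numeric(voxel_spacing_mm)
  list(center_mm = c(0.06 * extent[1], extent[2] / 2, 0.72 * extent[3]),
       radius_mm = radius_mm, suv = suv)
}

# world coordinate lists per axis for a spec grid (origin at 0)
phantom_axes <- function(spec) {
  lapply(1:3, function(a) (seq_len(spec$grid_shape[a]) - 1) * spec$voxel_spacing_mm[a])
}

# squared normalized ellipsoid distance field, as a 3D array
ellipsoid_rho2 <- function(axes, center, radii) {
  dx2 <- ((axes[[1]] - center[1]) / radii[1])^2
  dy2 <- ((axes[[2]] - center[2]) / radii[2])^2
  dz2 <- ((axes[[3]] - center[3]) / radii[3])^2
  d <- outer(dx2, dy2, `+`)
  arr <- array(0, c(length(dx2), length(dy2), length(dz2)))
  for (k in seq_along(dz2)) arr[, , k] <- d + dz2[k]
  arr
}

lesion_profile_field <- function(axes, les, background_suv) {
  peaks <- list(les$center_mm)
  if (!is.null(les$partner_offset_mm))
    peaks <- c(peaks, list(les$center_mm + les$partner_offset_mm))
  field <- NULL
  for (ctr in peaks) {
    rho2 <- ellipsoid_rho2(axes, ctr, les$radii_mm)
    f <- if (les$profile == "flat") {
      les$peak_suv * (rho2 < 1)
    } else {
      # decays from peak_suv to background_suv at the ellipsoid surface
      les$peak_suv * exp(rho2 * log(background_suv / les$peak_suv))
    }
    field <- if (is.null(field)) f else pmax(field, f)
  }
  field
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic PET/CT phantom
#'
#' Builds the noise-free SUV field as the voxel-wise maximum of the
#' background, all lesion profiles, all organ uptakes and the optional
#' injection artifact, then adds Gaussian noise (clipped at 0). The truth
#' mask of a lesion contains exactly the voxels where its noise-free profile
#' exceeds the background SUV — for both profiles this is the analytic
#' ellipsoid, so voxelized truth volumes converge to
#' 4/3*pi*r1*r2*r3 as the grid is refined. Organs and the artifact are
#' never part of the truth. The CT is schematic: an elliptical soft-tissue
#' body (~40 HU) in air (-1000 HU) with two bone rods (+700 HU).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `pet` and `ct` ([volume_grid()]s), `truth_masks`
#'   (a [roi_set()] keyed by lesion index) and `truth_volumes_ml` (named
#'   numeric, analytic union volumes per lesion).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  axes <- phantom_axes(spec)
  shp <- spec$grid_shape
  pet0 <- array(spec$background_suv, shp)

  truth <- list()
  vols <- numeric(0)
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    f <- lesion_profile_field(axes, les, spec$background_suv)
    pet0 <- pmax(pet0, f)
    truth[[as.character(i)]] <- f > spec$background_suv
    vols[as.character(i)] <- lesion_analytic_volume_ml(les)
  }
  for (org in spec$organ_uptakes) {
    rho2 <- ellipsoid_rho2(axes, org$center_mm, rep(org$radius_mm, 3))
    pet0 <- pmax(pet0, org$suv * (rho2 < 1))
  }
  if (!is.null(spec$artifact)) {
    a <- spec$artifact
    rho2 <- ellipsoid_rho2(axes, a$center_mm, rep(a$radius_mm, 3))
    pet0 <- pmax(pet0, a$suv * (rho2 < 1))
  }

  pet_vals <- with_preserved_rng(spec$seed, {
    noisy <- pet0 + if (spec$noise_sd > 0) rnorm(length(pet0), 0, spec$noise_sd) else 0
    array(pmax(noisy, 0), shp)
  })

  # schematic CT: body ellipse spanning 75% x / 90% y of the field, full z
  extent <- (shp - 1) * spec$voxel_spacing_mm
  ctr <- extent / 2
  body <- ellipsoid_rho2(axes, c(ctr[1], ctr[2], ctr[3]),
                         c(0.375 * max(extent[1], 1), 0.45 * max(extent[2], 1),
                           1e6)) < 1
  ct_vals <- array(-1000, shp)
  ct_vals[body] <- 40
  for (sgn in c(-1, 1)) {    # femur-like bone rods along z
    rod <- ellipsoid_rho2(axes, c(ctr[1] + sgn * 0.15 * extent[1], ctr[2], ctr[3]),
                          c(8, 8, 1e6)) < 1
    ct_vals[rod & body] <- 700
  }

  sp <- spec$voxel_spacing_mm
  list(pet = volume_grid(pet_vals, sp, modality = "PET_SUV"),
       ct = volume_grid(ct_vals, sp, modality = "CT_HU"),
       truth_masks = roi_set(truth, sp),
       truth_volumes_ml = vols)
}

#' Loose box ROIs around the truth lesions
#'
#' Emulates the loose manual regions of interest a physician draws around
#' each uptake: the lesion's bounding box dilated by `margin_mm` and clipped
#' to the grid. Empty truth masks produce no ROI; overlapping boxes are
#' allowed and keep their distinct ids.
#'
#' @param truth_masks A [roi_set()] of per-lesion truth masks.
#' @param margin_mm Non-negative dilation margin in mm.
#' @return A [roi_set()] of box ROIs with the same ids.
#' @export
manual_roi_boxes <- function(truth_masks, margin_mm = 8) {
  stopifnot(inherits(truth_masks, "roi_set"))
  if (margin_mm < 0) stop("`margin_mm` must be non-negative")
  sp <- truth_masks$spacing
  marg <- ceiling(margin_mm / sp)
  out <- list()
  for (id in names(truth_masks$rois)) {
    m <- truth_masks$rois[[id]]
    if (!any(m)) next
    idx <- which(m, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - marg, 1)
    hi <- pmin(apply(idx, 2, max) + marg, dim(m))
    box <- array(FALSE, dim(m))
    box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    out[[id]] <- box
  }
  roi_set(out, sp, truth_masks$origin)
}

#' Write a phantom to disk
#'
#' PET and CT as NIfTI, truth as an integer-label NIfTI plus a JSON sidecar
#' listing per-lesion centre, radii, peak SUV and analytic volume.
#'
#' @param phantom Result of [generate_phantom()].
#' @param spec The [phantom_spec()] that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti_volume(phantom$pet, file.path(dir, "pet.nii.gz"))
  write_nifti_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  if (length(phantom$truth_masks$rois)) {
    lab <- as_label_array(phantom$truth_masks)
    write_nifti_volume(binary_mask(lab > 0, spec$voxel_spacing_mm), # support
                       file.path(dir, "truth_support.nii.gz"))
    img <- RNifti::asNifti(lab)
    RNifti::pixdim(img) <- spec$voxel_spacing_mm
    RNifti::writeNifti(img, file.path(dir, "truth_labels.nii.gz"),
                       datatype = "int16")
  }
  sidecar <- lapply(seq_along(spec$lesions), function(i) {
    les <- spec$lesions[[i]]
    list(lesion_id = i, center = les$center_mm, radii = les$radii_mm,
         peak_suv = les$peak_suv, profile = les$profile,
         analytic_volume_ml = phantom$truth_volumes_ml[[as.character(i)]])
  })
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Draw a randomized phantom specification
#'
#' The stochastic study population for property tests and desk-scale
#' training: 1-4 ellipsoidal lesions with mixed flat/gaussian profiles,
#' peak SUV 5-15 on a background of SUV 1, brain- and bladder-like
#' physiological uptakes, measurement noise of SD 0.15 SUV, and (with
#' probability `artifact_prob`) an injection-site artifact.
#'
#' @param seed Integer seed controlling both the drawn spec and (via the
#'   spec's own seed) the voxel noise.
#' @param grid_shape,voxel_spacing_mm Phantom geometry.
#' @param n_lesions Range (length 2) of the lesion count.
#' @param radii_range_mm Range of ellipsoid half-axes (mm).
#' @param peak_suv_range Range of lesion peak SUV.
#' @param background_suv,noise_sd Passed to [phantom_spec()].
#' @param artifact_prob Probability of including the injection artifact.
#' @param coalescent_prob Probability that a lesion carries a partner peak.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, grid_shape = c(64, 64, 128),
                                voxel_spacing_mm = c(4, 4, 4),
                                n_lesions = c(1, 4),
                                radii_range_mm = c(10, 28),
                                peak_suv_range = c(5, 15),
                                background_suv = 1.0, noise_sd = 0.15,
                                artifact_prob = 0.3, coalescent_prob = 0.2) {
  extent <- (as.integer(grid_shape) - 1) * as.numeric(voxel_spacing_mm)
  with_preserved_rng(seed, {
    n <- if (n_lesions[1] == n_lesions[2]) n_lesions[1] else
      sample(n_lesions[1]:n_lesions[2], 1)
    lesions <- lapply(seq_len(n), function(i) {
      ctr <- runif(3, 0.25 * extent, 0.75 * extent)
      radii <- runif(3, radii_range_mm[1], radii_range_mm[2])
      peak <- runif(1, peak_suv_range[1], peak_suv_range[2])
      prof <- sample(c("flat", "gaussian"), 1)
      partner <- if (runif(1) < coalescent_prob)
        runif(3, -1, 1) * radii else NULL
      lesion_spec(ctr, radii, peak, prof, partner_offset_mm = partner)
    })
    organs <- list(
      list(center_mm = c(extent[1] / 2, extent[2] / 2, 0.93 * extent[3]),
           radius_mm = min(30, 0.1 * extent[3]), suv = 7),    # brain
      list(center_mm = c(extent[1] / 2, extent[2] / 2, 0.12 * extent[3]),
           radius_mm = min(18, 0.06 * extent[3]), suv = 12))  # bladder
    art <- if (runif(1) < artifact_prob)
      default_injection_artifact(grid_shape, voxel_spacing_mm) else NULL
    phantom_spec(grid_shape, voxel_spacing_mm, lesions = lesions,
                 organ_uptakes = organs, background_suv = background_suv,
                 noise_sd = noise_sd, artifact = art, seed = seed)
  })
}
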