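#' @useDynLib tmtvnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd t.test cor.test
#' @importFrom utils head
NULL

#' 3D image volume with geometry
#'
#' The basic container for a PET or CT scalar field: a 3D array plus voxel
#' spacing (mm), world origin (mm) and modality tag. Voxel values sit at
#' voxel centres; the world coordinate of (1-based) voxel `(i,j,k)` is
#' `origin + (c(i,j,k) - 1) * spacing`, with x/y the transaxial plane and z
#' the axial (cranio-caudal) direction.
#'
#' @param values 3D numeric array.
#' @param spacing Voxel spacing in mm, length 3, strictly positive.
#' @param origin World coordinate (mm) of the first voxel centre, length 3.
#' @param modality `"PET_SUV"` or `"CT_HU"`. PET values must be >= 0.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0),
                        modality = c("PET_SUV", "CT_HU")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (modality == "PET_SUV" && any(values < 0, na.rm = TRUE))
    stop("PET_SUV values must be non-negative")
  structure(list(values = values, spacing = spacing, origin = origin,
                 modality = modality),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s> %s voxels, spacing %s mm, origin (%s) mm\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  value range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary segmentation mask on a grid
#'
#' @param values 3D logical array.
#' @param spacing,origin Grid geometry as in [volume_grid()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' Voxel-wise tumor-probability map
#'
#' Holds probabilities in \[0,1\] on a grid: either the multi-threshold
#' consensus ground truth (TMTVprob, attaining only multiples of 1/k for k
#' contributing threshold masks) or the continuous output of the
#' segmentation network.
#'
#' @param values 3D numeric array with values in \[0,1\].
#' @param spacing,origin Grid geometry as in [volume_grid()].
#' @return An object of class `prob_mask`.
#' @export
prob_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(list(values = pmin(pmax(values, 0), 1), spacing = spacing,
                 origin = as.numeric(origin)),
            class = "prob_mask")
}

#' Set of labelled regions of interest
#'
#' A collection of manual-style ROIs over one grid. ROIs may overlap (loose
#' physician-drawn regions routinely do), so each is stored as its own
#' binary field under an integer id.
#'
#' @param rois Named list of 3D logical arrays; names are integer ids.
#' @param spacing,origin Grid geometry as in [volume_grid()].
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois, spacing, origin = c(0, 0, 0)) {
  if (length(rois)) {
    if (is.null(names(rois)) || anyNA(suppressWarnings(as.integer(names(rois)))))
      stop("`rois` must be a named list with integer-coercible names")
    d <- dim(rois[[1]])
    for (m in rois) {
      if (!identical(dim(m), d)) stop("all ROIs must share one grid shape")
    }
    rois <- lapply(rois, function(m) { storage.mode(m) <- "logical"; m })
  }
  structure(list(rois = rois, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s)", length(x$rois)))
  if (length(x$rois))
    cat(sprintf(", %s voxels each", paste(dim(x$rois[[1]]), collapse = "x")))
  cat("\n")
  invisible(x)
}

#' @rdname roi_set
#' @param x A `roi_set`.
#' @return `roi_ids()`: integer vector of ids.
#' @export
roi_ids <- function(x) {
  stopifnot(inherits(x, "roi_set"))
  as.integer(names(x$rois))
}

#' Collapse a roi_set to a single integer label array
#'
#' Overlapping voxels take the smallest id (overlaps are legal in a
#' `roi_set` but a label image cannot represent them).
#'
#' @param x A `roi_set`.
#' @return 3D integer array, 0 = background.
#' @export
as_label_array <- function(x) {
  stopifnot(inherits(x, "roi_set"))
  if (!length(x$rois)) stop("empty roi_set has no grid shape")
  lab <- array(0L, dim(x$rois[[1]]))
  for (id in rev(sort(roi_ids(x)))) {
    lab[x$rois[[as.character(id)]]] <- id
  }
  lab
}

# ---- geometry helpers ------------------------------------------------------

grid_shape <- function(x) dim(x$values)

#' Voxel volume in mL
#' @param x Any grid-bearing object (`volume_grid`, `binary_mask`, ...).
#' @return Single voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Mask volume in mL
#' @param x A `binary_mask`.
#' @return Voxel count times voxel volume, in mL.
#' @export
volume_ml <- function(x) {
  stopifnot(inherits(x, "binary_mask"))
  sum(x$values) * voxel_volume_ml(x)
}

grid_center_mm <- function(x) {
  d <- if (inherits(x, "roi_set")) dim(x$rois[[1]]) else dim(x$values)
  x$origin + (d - 1) / 2 * x$spacing
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "roi_set")) dim(a$rois[[1]]) else dim(a$values)
  db <- if (inherits(b, "roi_set")) dim(b$rois[[1]]) else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_unless_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

# ---- NIfTI serialization ---------------------------------------------------

grid_affine <- function(spacing, origin) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  aff
}

#' Write a volume, mask or probability map as NIfTI
#'
#' Geometry (spacing and origin) is stored in the qform with code 2
#' (aligned). Masks are written as 8-bit integers, probability maps and
#' volumes as floats.
#'
#' @param x A `volume_grid`, `binary_mask` or `prob_mask`.
#' @param path Output path, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  vals <- x$values
  if (inherits(x, "binary_mask")) {
    vals <- array(as.integer(vals), dim(vals))
    dt <- "uint8"
  } else {
    dt <- "double"
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  img <- RNifti::`qform<-`(img, structure(grid_affine(x$spacing, x$origin), code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

read_nifti_geometry <- function(img) {
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  # take origin from the affine translation; axis directions are assumed
  # axis-aligned (the package writes them that way)
  list(spacing = abs(as.numeric(spacing)), origin = as.numeric(aff[1:3, 4]))
}
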