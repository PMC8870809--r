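# Within-ROI segmentation operators and the consensus ground truth.
#
# Four clinically used rules delineate tumor inside a manual ROI: the
# relative 41% SUVmax threshold, the fixed SUV > 2.5 and SUV > 4.0 cutoffs,
# and Otsu's histogram threshold. Averaging their binary masks voxel-wise
# gives the TMTV probability map (TMTVprob, values in steps of 0.25) that
# the segmentation network is trained against. Boundary semantics: the
# fixed cutoffs are strict (SUV > c, as the rules are written); the
# relative rule uses >= so the SUVmax voxel itself always survives.

#' Threshold methodology descriptor
#'
#' @param type `"percent41"`, `"cutoff"` or `"otsu"`.
#' @param cutoff SUV cutoff, required when `type = "cutoff"` (clinically
#'   2.5 or 4.0).
#' @return An object of class `threshold_method`.
#' @export
threshold_method <- function(type = c("percent41", "cutoff", "otsu"), cutoff = NULL) {
  type <- match.arg(type)
  if (type == "cutoff") {
    if (is.null(cutoff) || cutoff <= 0) stop("`cutoff` must be a positive SUV")
  } else cutoff <- NULL
  structure(list(type = type, cutoff = cutoff), class = "threshold_method")
}

#' @rdname threshold_method
#' @export
method_percent41 <- function() threshold_method("percent41")

#' @rdname threshold_method
#' @export
method_cutoff <- function(cutoff) threshold_method("cutoff", cutoff)

#' @rdname threshold_method
#' @export
method_otsu <- function() threshold_method("otsu")

#' @export
format.threshold_method <- function(x, ...) {
  switch(x$type, percent41 = "41% SUVmax",
         cutoff = sprintf("SUV > %.1f", x$cutoff), otsu = "Otsu")
}

#' @export
print.threshold_method <- function(x, ...) {
  cat("<threshold_method>", format(x), "\n"); invisible(x)
}

roi_logical <- function(roi, pet) {
  m <- if (inherits(roi, "binary_mask")) roi$values else roi
  if (!identical(dim(m), dim(pet$values)))
    stop("ROI and PET are not on the same grid")
  m
}

as_mask <- function(vals, pet) binary_mask(vals, pet$spacing, pet$origin)

#' Fixed-cutoff segmentation within an ROI
#'
#' Keeps the ROI voxels with SUV strictly greater than `cutoff`.
#'
#' @param pet A PET [volume_grid()] in SUV.
#' @param roi ROI as a [binary_mask()] or logical array on the same grid.
#' @param cutoff Positive SUV cutoff (2.5 or 4.0 clinically).
#' @return A [binary_mask()] (possibly empty).
#' @export
cutoff_segment <- function(pet, roi, cutoff) {
  m <- roi_logical(roi, pet)
  if (!any(m)) stop("ROI is empty")
  if (cutoff < 0) stop("`cutoff` must be non-negative")
  as_mask(m & (pet$values > cutoff), pet)
}

#' Relative 41% SUVmax segmentation within an ROI
#'
#' Threshold t = 0.41 * max(SUV within ROI); keeps ROI voxels with
#' SUV >= t, so the SUVmax voxel itself is always kept. Scale-invariant:
#' multiplying the PET by any positive factor leaves the mask unchanged.
#'
#' @inheritParams cutoff_segment
#' @param fraction Relative threshold fraction; fixed at 0.41 clinically.
#' @return A non-empty [binary_mask()].
#' @export
percent41_segment <- function(pet, roi, fraction = 0.41) {
  m <- roi_logical(roi, pet)
  if (!any(m)) stop("ROI is empty")
  mx <- max(pet$values[m])
  if (mx <= 0) stop("degenerate ROI: SUVmax is 0, relative threshold undefined")
  as_mask(m & (pet$values >= fraction * mx), pet)
}

#' Otsu threshold of a value vector
#'
#' Histogram threshold maximizing the between-class variance over
#' `n_bins` equal-width bins spanning the value range. Candidate
#' thresholds are the interior bin edges; ties take the lowest threshold.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold value (classes are `<= t` and `> t`).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) stop("Otsu threshold undefined: all values identical")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  n <- length(values)
  w0 <- cumsum(counts)[-n_bins]
  s0 <- cumsum(counts * mids)[-n_bins]
  total <- sum(counts * mids)
  valid <- w0 > 0 & w0 < n
  mu0 <- s0 / w0
  mu1 <- (total - s0) / (n - w0)
  sigma_b <- ifelse(valid, w0 * (n - w0) * (mu0 - mu1)^2, -Inf)
  edges[which.max(sigma_b) + 1]
}

#' Otsu segmentation within an ROI
#'
#' Keeps ROI voxels strictly above the Otsu threshold of the within-ROI
#' SUV histogram.
#'
#' @inheritParams cutoff_segment
#' @param n_bins Number of histogram bins.
#' @return A [binary_mask()].
#' @export
otsu_segment <- function(pet, roi, n_bins = 256) {
  m <- roi_logical(roi, pet)
  if (!any(m)) stop("ROI is empty")
  vals <- pet$values[m]
  if (length(unique(vals)) < 2)
    stop("Otsu segmentation failed: ROI is single-valued")
  t <- otsu_threshold(vals, n_bins)
  as_mask(m & (pet$values > t), pet)
}

segment_roi <- function(pet, roi, method) {
  switch(method$type,
         percent41 = percent41_segment(pet, roi),
         cutoff = cutoff_segment(pet, roi, method$cutoff),
         otsu = otsu_segment(pet, roi))
}

#' The four ground-truth threshold methods
#'
#' 41% SUVmax, SUV > 2.5, SUV > 4.0 and Otsu — the set averaged into
#' TMTVprob.
#'
#' @return List of four [threshold_method()]s.
#' @export
ground_truth_methods <- function() {
  list(method_percent41(), method_cutoff(2.5), method_cutoff(4.0), method_otsu())
}

#' Average binary masks into a probability map
#'
#' Voxel value = (number of masks containing the voxel) / k. For the four
#' ground-truth methods the attained values are exactly
#' \{0, 0.25, 0.5, 0.75, 1\}.
#'
#' @param masks List of [binary_mask()]s on one grid.
#' @return A [prob_mask()].
#' @export
build_tmtv_prob <- function(masks) {
  if (!length(masks)) stop("need at least one mask")
  d <- dim(masks[[1]]$values)
  acc <- array(0, d)
  for (m in masks) {
    stopifnot(inherits(m, "binary_mask"))
    if (!identical(dim(m$values), d)) stop("masks are not on one grid")
    acc <- acc + m$values
  }
  prob_mask(acc / length(masks), masks[[1]]$spacing, masks[[1]]$origin)
}

#' Consensus ground truth (TMTVprob) for one case
#'
#' Applies each of the four threshold methods inside every manual ROI,
#' unions the per-ROI masks per method (so overlapping ROIs cannot push a
#' probability above 1), and averages the four per-method masks. Voxels
#' outside every ROI are 0. Errors from a per-ROI operator are re-raised
#' tagged with the ROI id.
#'
#' @param pet A PET [volume_grid()] in SUV.
#' @param rois A [roi_set()] of manual ROIs.
#' @param methods List of [threshold_method()]s;
#'   default [ground_truth_methods()].
#' @return A [prob_mask()] — the TMTVprob.
#' @export
ground_truth_for_case <- function(pet, rois, methods = ground_truth_methods()) {
  stopifnot(inherits(pet, "volume_grid"), inherits(rois, "roi_set"))
  d <- dim(pet$values)
  if (!length(rois$rois))
    return(prob_mask(array(0, d), pet$spacing, pet$origin))
  per_method <- lapply(methods, function(meth) {
    u <- array(FALSE, d)
    for (id in names(rois$rois)) {
      m <- tryCatch(segment_roi(pet, rois$rois[[id]], meth),
                    error = function(e)
                      stop(sprintf("ROI %s (%s): %s", id, format(meth),
                                   conditionMessage(e)), call. = FALSE))
      u <- u | m$values
    }
    binary_mask(u, pet$spacing, pet$origin)
  })
  build_tmtv_prob(per_method)
}
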