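# Post-processing: predicted probability map -> per-methodology TMTV.
#
# The raw tumor mask is the prediction binarized at probability > 0.5. The
# fixed-cutoff methodologies re-threshold that mask globally. The 41%
# SUVmax methodology is per-lesion: connected components are isolated
# (26-connectivity), components over 30 mL — likely coalescent tumor
# masses — are split into subparts by a marker-controlled watershed on the
# SUV field, and each surviving sub-component is thresholded at 41% of its
# own SUVmax.

#' Binarize a probability map
#'
#' @param p A [prob_mask()].
#' @param t Probability threshold; voxels strictly above `t` are kept.
#' @return A [binary_mask()].
#' @export
binarize_prediction <- function(p, t = 0.5) {
  stopifnot(inherits(p, "prob_mask"))
  binary_mask(p$values > t, p$spacing, p$origin)
}

new_component <- function(id, voxel_idx, dim, spacing, origin, pet_vals) {
  structure(list(id = id, voxel_idx = voxel_idx, dim = dim, spacing = spacing,
                 origin = origin,
                 volume_ml = length(voxel_idx) * prod(spacing) / 1000,
                 suvmax = if (length(voxel_idx)) max(pet_vals[voxel_idx]) else NA_real_),
            class = "lesion_component")
}

#' @export
print.lesion_component <- function(x, ...) {
  cat(sprintf("<lesion_component %d> %.2f mL, SUVmax %.2f\n",
              x$id, x$volume_ml, x$suvmax))
  invisible(x)
}

#' Component mask as a binary_mask
#' @param comp A `lesion_component`.
#' @return A [binary_mask()] with the component's voxels set.
#' @export
component_mask <- function(comp) {
  m <- array(FALSE, comp$dim)
  m[comp$voxel_idx] <- TRUE
  binary_mask(m, comp$spacing, comp$origin)
}

#' Connected components of a tumor mask
#'
#' Maximal connected voxel sets under 26-connectivity (face, edge and
#' corner neighbours), each annotated with its volume (mL) and SUVmax from
#' the PET. Components are returned in decreasing volume order and
#' re-numbered 1..n.
#'
#' @param mask A [binary_mask()].
#' @param pet The PET [volume_grid()] on the same grid.
#' @param connectivity 26 (default) or 6.
#' @return List of `lesion_component`s (empty for an empty mask).
#' @export
connected_components <- function(mask, pet, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"), inherits(pet, "volume_grid"))
  stop_unless_same_grid(mask, pet, "mask and PET")
  lab <- label_components_cpp(as.logical(mask$values), dim(mask$values),
                              connectivity)
  n <- attr(lab, "n")
  if (n == 0L) return(list())
  groups <- split(which(lab > 0L), lab[lab > 0L])
  comps <- lapply(groups, function(ix)
    new_component(0L, ix, dim(mask$values), mask$spacing, mask$origin,
                  pet$values))
  comps <- comps[order(vapply(comps, `[[`, 0, "volume_ml"), decreasing = TRUE)]
  for (i in seq_along(comps)) comps[[i]]$id <- i
  comps
}

#' Split a large component into watershed subparts
#'
#' Components at most `min_volume_ml` are returned unchanged. Larger
#' components — likely coalescent tumor masses — are partitioned by a
#' marker-controlled watershed on the SUV field restricted to the
#' component: markers are the regional maxima of the Gaussian-smoothed SUV
#' (sigma `smooth_sigma_vox` voxels), merged when closer than
#' `merge_dist_vox` voxels, and basins are flooded from high SUV downward.
#' The subparts partition the component exactly (their voxel sets are
#' disjoint with union equal to the component).
#'
#' @param comp A `lesion_component`.
#' @param pet The PET [volume_grid()].
#' @param min_volume_ml Volume gate in mL; clinical default 30.
#' @param smooth_sigma_vox Gaussian smoothing (voxels) before peak finding.
#' @param merge_dist_vox Maxima closer than this (voxels, Euclidean) merge
#'   into one marker.
#' @return List of `lesion_component`s.
#' @export
watershed_split <- function(comp, pet, min_volume_ml = 30,
                            smooth_sigma_vox = 1, merge_dist_vox = 2) {
  stopifnot(inherits(comp, "lesion_component"))
  if (comp$volume_ml <= min_volume_ml) return(list(comp))
  d <- comp$dim
  m <- array(FALSE, d); m[comp$voxel_idx] <- TRUE
  sm <- gaussian_smooth_cpp(as.numeric(pet$values), d, smooth_sigma_vox)
  dim(sm) <- d
  peaks <- which(regional_maxima_cpp(sm, m, d))
  if (length(peaks) <= 1L) return(list(comp))
  # merge nearby maxima (plateaus and near-duplicate peaks) by single linkage
  coord <- arrayInd(peaks, d)
  grp <- seq_along(peaks)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_along(peaks)) for (j in seq_len(i - 1L)) {
    if (sum((coord[i, ] - coord[j, ])^2) < merge_dist_vox^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) grp[ri] <- rj
    }
  }
  roots <- vapply(seq_along(peaks), find, 0L)
  marker_ids <- match(roots, unique(roots))
  if (max(marker_ids) == 1L) return(list(comp))
  markers <- array(0L, d)
  markers[peaks] <- marker_ids
  ws <- watershed_cpp(sm, m, markers, d)
  out <- lapply(seq_len(max(marker_ids)), function(g)
    new_component(g, which(ws == g), d, comp$spacing, comp$origin, pet$values))
  out <- out[vapply(out, function(x) length(x$voxel_idx) > 0L, TRUE)]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' TMTV result for one methodology
#'
#' @param method A [threshold_method()].
#' @param final_mask Final [binary_mask()].
#' @param components List of surviving `lesion_component`s.
#' @return An object of class `tmtv_result` with `tmtv_ml` equal to the
#'   final mask volume.
#' @export
tmtv_result <- function(method, final_mask, components) {
  structure(list(method = method, final_mask = final_mask,
                 tmtv_ml = volume_ml(final_mask), components = components),
            class = "tmtv_result")
}

#' @export
print.tmtv_result <- function(x, ...) {
  cat(sprintf("<tmtv_result %s> TMTV %.2f mL, %d ROI(s)\n",
              format(x$method), x$tmtv_ml, count_rois(x)))
  invisible(x)
}

#' Apply a TMTV methodology to a raw predicted mask
#'
#' For a fixed cutoff the SUV threshold is applied globally over the raw
#' mask (no clustering needed: the rule does not depend on lesion
#' identity). For the 41% SUVmax methodology the raw mask is first split
#' into connected components, components over `min_volume_ml` are
#' sub-segmented by [watershed_split()], and each sub-component is
#' thresholded at 41% of its own SUVmax. Sub-components with no surviving
#' voxel are dropped. An empty raw mask yields TMTV 0 with no components.
#'
#' @param raw Raw predicted [binary_mask()] (probability > 0.5).
#' @param pet The PET [volume_grid()] on the same grid.
#' @param method A [threshold_method()] (`percent41` or `cutoff`; `otsu`
#'   is available as a ground-truth operator but is not a validated
#'   post-processing methodology).
#' @param min_volume_ml Watershed volume gate (mL).
#' @param fraction Relative threshold fraction for `percent41`.
#' @return A `tmtv_result`.
#' @export
apply_methodology <- function(raw, pet, method, min_volume_ml = 30,
                              fraction = 0.41) {
  stopifnot(inherits(raw, "binary_mask"), inherits(method, "threshold_method"))
  stop_unless_same_grid(raw, pet, "raw mask and PET")
  empty <- binary_mask(array(FALSE, dim(raw$values)), raw$spacing, raw$origin)
  if (!any(raw$values)) return(tmtv_result(method, empty, list()))

  if (method$type == "cutoff") {
    final <- binary_mask(raw$values & (pet$values > method$cutoff),
                         raw$spacing, raw$origin)
    comps <- if (any(final$values)) connected_components(final, pet) else list()
    return(tmtv_result(method, final, comps))
  }
  if (method$type != "percent41")
    stop(sprintf("'%s' is not wired as a post-processing methodology",
                 method$type))

  comps <- connected_components(raw, pet)
  subs <- list()
  for (comp in comps)
    subs <- c(subs, watershed_split(comp, pet, min_volume_ml))
  final_arr <- array(FALSE, dim(raw$values))
  survivors <- list()
  for (s in subs) {
    keep <- s$voxel_idx[pet$values[s$voxel_idx] >= fraction * s$suvmax]
    if (!length(keep)) next
    final_arr[keep] <- TRUE
    survivors[[length(survivors) + 1L]] <-
      new_component(length(survivors) + 1L, keep, s$dim, s$spacing, s$origin,
                    pet$values)
  }
  tmtv_result(method, binary_mask(final_arr, raw$spacing, raw$origin), survivors)
}

#' Number of generated ROIs in a TMTV result
#'
#' Counts the (sub-)components with at least one surviving voxel — the
#' automated counterpart of the number of ROIs a physician draws.
#'
#' @param result A `tmtv_result`.
#' @return Integer count.
#' @export
count_rois <- function(result) {
  stopifnot(inherits(result, "tmtv_result"))
  sum(vapply(result$components, function(x) length(x$voxel_idx) > 0L, TRUE))
}

#' Write a TMTV result to disk
#'
#' Final mask as NIfTI plus a JSON report with the methodology, TMTV (mL),
#' ROI count and the per-component volumes and SUVmax.
#'
#' @param result A `tmtv_result`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return `dir`, invisibly.
#' @export
write_tmtv_result <- function(result, dir, prefix = "tmtv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti_volume(result$final_mask,
                     file.path(dir, paste0(prefix, "_mask.nii.gz")))
  rep <- list(method = format(result$method), tmtv_ml = result$tmtv_ml,
              n_rois = count_rois(result),
              per_component = lapply(result$components, function(x)
                list(id = x$id, volume_ml = x$volume_ml, suvmax = x$suvmax)))
  jsonlite::write_json(rep, file.path(dir, paste0(prefix, "_report.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
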