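# Training-side utilities: rigid+scale augmentation, the 60/20/20 dataset
# split, and the SGD training loop.

rotation_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Random rigid + scale augmentation of an aligned PET/CT/truth triplet
#'
#' Samples one transform — translation up to `translation_mm` per axis,
#' rotation about the axial (z) axis up to `rotation_deg`, and isotropic
#' scaling in `scale_range` — and applies it identically to all three
#' volumes about the field centre. PET and CT are interpolated
#' trilinearly with their modality backgrounds as fill (0 SUV, -1000 HU);
#' the truth probability map is continuous-valued, so it is also
#' interpolated linearly (not re-binarized) with fill 0. Reproducible by
#' seed.
#'
#' @param pet,ct [volume_grid()]s on one grid.
#' @param truth A [prob_mask()] on the same grid.
#' @param seed Integer seed.
#' @param translation_mm,rotation_deg,scale_range Transform ranges.
#' @return List with transformed `pet`, `ct`, `truth` and the sampled
#'   `params`.
#' @export
augment_case <- function(pet, ct, truth, seed, translation_mm = 16,
                         rotation_deg = 10, scale_range = c(0.9, 1.1)) {
  stop_unless_same_grid(pet, ct, "PET and CT")
  stop_unless_same_grid(pet, truth, "PET and truth")
  params <- with_preserved_rng(seed, list(
    translation = runif(3, -translation_mm, translation_mm),
    theta = runif(1, -rotation_deg, rotation_deg) * pi / 180,
    scale = runif(1, scale_range[1], scale_range[2])))
  out <- apply_rigid_scale(pet, ct, truth, params)
  c(out, list(params = params))
}

# Deterministic core of the augmentation: output world coordinate w maps to
# source coordinate c + R(-theta) * (w - c - t) / s, expressed in voxel
# index space for the resampler.
apply_rigid_scale <- function(pet, ct, truth, params) {
  sp <- pet$spacing
  d <- dim(pet$values)
  ctr_idx <- (d - 1) / 2                       # rotate/scale about the centre
  S <- diag(sp)
  Sinv <- diag(1 / sp)
  A <- Sinv %*% rotation_z(-params$theta) %*% S / params$scale
  b <- ctr_idx - A %*% (ctr_idx + params$translation / sp)
  warp <- function(arr, fill) {
    v <- resample_affine_cpp(as.numeric(arr), d, d, A, as.numeric(b), TRUE, fill)
    dim(v) <- d
    v
  }
  pet_v <- warp(pet$values, 0); pet_v[pet_v < 0] <- 0
  list(pet = volume_grid(pet_v, sp, pet$origin, "PET_SUV"),
       ct = volume_grid(warp(ct$values, -1000), sp, ct$origin, "CT_HU"),
       truth = prob_mask(pmin(pmax(warp(truth$values, 0), 0), 1), sp,
                         truth$origin))
}

#' Split cases into train / validation / test
#'
#' Reproducible shuffled split with the study fractions: 60% training,
#' 20% test, 20% validation (disjoint, exhaustive).
#'
#' @param case_ids Vector of case identifiers.
#' @param seed Integer seed.
#' @param fractions Named fractions summing to 1.
#' @return An object of class `dataset_split`: list with `train`, `val`,
#'   `test`, `seed`.
#' @export
split_dataset <- function(case_ids, seed,
                          fractions = c(train = 0.6, test = 0.2, val = 0.2)) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("`fractions` must sum to 1")
  n <- length(case_ids)
  perm <- with_preserved_rng(seed, sample(n))
  n_train <- round(fractions[["train"]] * n)
  n_test <- round(fractions[["test"]] * n)
  structure(list(train = case_ids[perm[seq_len(n_train)]],
                 test = case_ids[perm[n_train + seq_len(n_test)]],
                 val = case_ids[perm[-seq_len(n_train + n_test)]],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d val / %d test (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

case_tensor <- function(case) {
  input <- scale_intensities(case$ct, case$pet)
  list(x = array(c(input$ct, input$pet), c(dim(input$ct), 2L)),
       t = input_truth(case))
}

input_truth <- function(case) {
  tv <- case$truth
  if (inherits(tv, "prob_mask")) tv$values else tv
}

sgd_update <- function(params, vel, grads, lr, mom) {
  for (nm in names(grads)) {
    vel[[nm]] <- mom * vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

case_loss_grads <- function(model, tc) {
  fw <- vnet_forward(model, tc$x, train = TRUE)
  loss <- soft_dice_loss(fw$pred, tc$t)
  dpred <- soft_dice_grad(fw$pred, tc$t)
  list(loss = loss, grads = vnet_backward(model, fw$cache, dpred))
}

#' Train a V-NET on phantom cases
#'
#' SGD with momentum on the soft dice loss against the continuous TMTVprob
#' target. Each training case may contribute `cfg$augment_per_case`
#' additional augmented copies (generated once, before training, as in the
#' clinical setup). Per-epoch mean training loss and validation loss are
#' logged; the weights with the best validation loss are kept alongside
#' the final weights. A non-finite loss aborts with the epoch index.
#'
#' @param cases List of training cases; each a list with `pet`, `ct`
#'   ([volume_grid()]s on the network grid) and `truth` (a [prob_mask()]).
#' @param cfg A [vnet_config()].
#' @param val_cases Optional validation cases in the same format.
#' @param verbose Print a line per epoch.
#' @return List with `model` (final weights), `best_model` (best
#'   validation loss, or final if no validation set) and `history`
#'   (data.frame: epoch, train_loss, val_loss).
#' @export
train_vnet <- function(cases, cfg, val_cases = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "vnet_config"))
  if (length(cases) < 2) stop("need at least 2 training cases")
  model <- build_vnet(cfg)

  tensors <- lapply(cases, case_tensor)
  if (cfg$augment_per_case > 0) {
    for (i in seq_along(cases)) {
      for (a in seq_len(cfg$augment_per_case)) {
        aug <- augment_case(cases[[i]]$pet, cases[[i]]$ct,
                            as_prob(cases[[i]]$truth, cases[[i]]$pet),
                            seed = cfg$seed + 1000L * i + a)
        tensors[[length(tensors) + 1L]] <- case_tensor(aug)
      }
    }
  }
  val_tensors <- lapply(val_cases, case_tensor)

  vel <- lapply(model$params, function(p) p * 0)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- model$params

  order_seeds <- with_preserved_rng(cfg$seed,
                                    sample.int(.Machine$integer.max, cfg$epochs))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_preserved_rng(order_seeds[epoch], sample(length(tensors)))
    losses <- numeric(0)
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      i <- i + cfg$batch_size
      acc <- NULL
      for (bi in batch) {
        lg <- case_loss_grads(model, tensors[[bi]])
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        losses <- c(losses, lg$loss)
        acc <- if (is.null(acc)) lg$grads else
          Map(`+`, acc, lg$grads)
      }
      acc <- lapply(acc, function(gv) gv / length(batch))
      upd <- sgd_update(model$params, vel, acc, cfg$learning_rate, cfg$momentum)
      model$params <- upd$params
      vel <- upd$vel
    }
    val_loss <- if (length(val_tensors)) {
      mean(vapply(val_tensors, function(tc)
        soft_dice_loss(vnet_forward(model, tc$x)$pred, tc$t), 0))
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = val_loss))
    if (!is.na(val_loss) && val_loss < best_val) {
      best_val <- val_loss
      best_params <- model$params
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, mean(losses),
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
  }
  best_model <- model
  best_model$params <- if (is.finite(best_val)) best_params else model$params
  list(model = model, best_model = best_model, history = history)
}

as_prob <- function(truth, like) {
  if (inherits(truth, "prob_mask")) return(truth)
  if (inherits(truth, "binary_mask"))
    return(prob_mask(truth$values + 0, truth$spacing, truth$origin))
  prob_mask(truth, like$spacing, like$origin)
}

#' Build one phantom training case on the network grid
#'
#' Generates a randomized phantom directly on a (downscaled) network grid,
#' derives loose manual-style box ROIs and the four-threshold consensus
#' ground truth, and returns everything [train_vnet()] needs. The desk
#' default — 16 x 16 x 32 voxels at 8 mm — keeps a whole phantom body in a
#' field the suite can train on in minutes; lesion half-axes of 24-48 mm
#' keep each lesion several voxels wide at that spacing.
#'
#' @param seed Integer seed (drives the phantom spec and its noise).
#' @param grid_shape,voxel_spacing_mm Network grid geometry.
#' @param radii_range_mm Lesion half-axis range (mm).
#' @param n_lesions Range of the lesion count.
#' @param roi_margin_mm Margin of the manual-style box ROIs.
#' @param ... Further arguments to [random_phantom_spec()].
#' @return List with `pet`, `ct`, `truth` (TMTVprob [prob_mask()]),
#'   `truth_masks`, `rois`, `spec`.
#' @export
phantom_case <- function(seed, grid_shape = c(16, 16, 32),
                         voxel_spacing_mm = c(8, 8, 8),
                         radii_range_mm = c(24, 48), n_lesions = c(1, 3),
                         roi_margin_mm = 12, ...) {
  spec <- random_phantom_spec(seed, grid_shape = grid_shape,
                              voxel_spacing_mm = voxel_spacing_mm,
                              radii_range_mm = radii_range_mm,
                              n_lesions = n_lesions, ...)
  ph <- generate_phantom(spec)
  rois <- manual_roi_boxes(ph$truth_masks, roi_margin_mm)
  truth <- ground_truth_for_case(ph$pet, rois)
  list(pet = ph$pet, ct = ph$ct, truth = truth, truth_masks = ph$truth_masks,
       rois = rois, spec = spec)
}
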