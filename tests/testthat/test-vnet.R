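tiny_cfg <- function(...) {
  vnet_config(levels = 2, base_channels = 2, epochs = 2, batch_size = 2,
              seed = 9, augment_per_case = 0, enc_convs = c(1, 2), ...)
}

test_that("soft dice loss matches its closed form and bounds", {
  d <- c(5, 2, 1)
  m <- array(c(1, 0, 1, 1, 0, 0, 0, 1, 0, 0), d)
  expect_lt(soft_dice_loss(m, m), 1e-6)
  disj <- array(c(0, 1, 0, 0, 1, 1, 1, 0, 0, 0), d)
  expect_gt(soft_dice_loss(m, disj), 1 - 1e-5)
  # uniform 0.5 prediction vs binary truth on a 10-voxel example:
  # 1 - (2 * 0.5*4 + eps) / (5 + 4 + eps) = 1 - 4/9
  u <- array(0.5, d)
  expect_equal(soft_dice_loss(u, m), 1 - 4 / 9, tolerance = 1e-6)
  # symmetry and range on random prob fields
  set.seed(10)
  for (i in 1:10) {
    a <- array(runif(prod(d)), d); b <- array(runif(prod(d)), d)
    l <- soft_dice_loss(a, b)
    expect_equal(l, soft_dice_loss(b, a))
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(soft_dice_loss(m, array(1, c(2, 2, 2))), "shapes differ")
})

test_that("loss equals 1 - dice exactly on binary masks as eps -> 0", {
  set.seed(6)
  d <- c(6, 6, 4)
  for (i in 1:10) {
    a <- array(runif(prod(d)) < 0.4, d)
    b <- array(runif(prod(d)) < 0.4, d)
    if (!any(a) && !any(b)) next
    expect_equal(soft_dice_loss(a + 0, b + 0, eps = 0), 1 - dice(a, b),
                 tolerance = 1e-12)
  }
})

test_that("model respects the input/output shape contract", {
  model <- build_vnet(vnet_config(levels = 4, base_channels = 8, seed = 2))
  x <- array(runif(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  out <- tmtvnet:::vnet_forward(model, x)
  expect_identical(dim(out$pred), c(16L, 16L, 32L))
  expect_true(all(out$pred > 0 & out$pred < 1))      # sigmoid range
  # indivisible shapes are refused
  bad <- array(0, c(12, 12, 12, 2))
  expect_error(tmtvnet:::vnet_forward(model, bad), "divisible")
  expect_error(tmtvnet:::vnet_forward(model, array(0, c(16, 16, 32, 3))),
               "channels")
})

test_that("parameter count grows with base channels", {
  n8 <- n_params(build_vnet(vnet_config(base_channels = 8)))
  n12 <- n_params(build_vnet(vnet_config(base_channels = 12)))
  n16 <- n_params(build_vnet(vnet_config(base_channels = 16)))
  expect_lt(n8, n12); expect_lt(n12, n16)
})

test_that("backward pass agrees with finite differences", {
  cfg <- tiny_cfg()
  model <- build_vnet(cfg)
  set.seed(1)
  x <- array(runif(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  truth <- array(rbinom(128, 1, 0.3) + 0, c(4, 4, 8))
  fw <- tmtvnet:::vnet_forward(model, x, train = TRUE)
  g <- tmtvnet:::vnet_backward(model, fw$cache,
                               tmtvnet:::soft_dice_grad(fw$pred, truth))
  base <- soft_dice_loss(fw$pred, truth)
  eps <- 1e-6
  set.seed(2)
  for (nm in sample(names(g), 6)) {
    ix <- sample(length(model$params[[nm]]), 1)
    m2 <- model
    m2$params[[nm]][ix] <- m2$params[[nm]][ix] + eps
    num <- (soft_dice_loss(tmtvnet:::vnet_forward(m2, x)$pred, truth) - base) / eps
    expect_equal(g[[nm]][ix], num, tolerance = 1e-3,
                 label = sprintf("grad %s[%d]", nm, ix))
  }
})

test_that("augmentation is seed-reproducible and identity at zero ranges", {
  case <- phantom_case(31, grid_shape = c(8, 8, 16))
  a1 <- augment_case(case$pet, case$ct, case$truth, seed = 5)
  a2 <- augment_case(case$pet, case$ct, case$truth, seed = 5)
  expect_identical(a1$pet$values, a2$pet$values)
  expect_identical(a1$truth$values, a2$truth$values)
  a3 <- augment_case(case$pet, case$ct, case$truth, seed = 6)
  expect_false(identical(a1$pet$values, a3$pet$values))
  ident <- augment_case(case$pet, case$ct, case$truth, seed = 5,
                        translation_mm = 0, rotation_deg = 0,
                        scale_range = c(1, 1))
  expect_equal(ident$pet$values, case$pet$values, tolerance = 1e-9)
  expect_equal(ident$truth$values, case$truth$values, tolerance = 1e-9)
})

test_that("scaling changes mask volume by about the cube of the factor", {
  case <- phantom_case(42, grid_shape = c(16, 16, 32))
  base_vol <- sum(case$truth$values > 0.5)
  for (s in c(0.9, 1.1)) {
    aug <- tmtvnet:::apply_rigid_scale(case$pet, case$ct, case$truth,
                                       list(translation = c(0, 0, 0),
                                            theta = 0, scale = s))
    vol <- sum(aug$truth$values > 0.5)
    expect_equal(vol / base_vol, s^3, tolerance = 0.2)
  }
})

test_that("dataset split honours the 60/20/20 fractions", {
  sp <- split_dataset(1:10, seed = 3)
  expect_length(sp$train, 6); expect_length(sp$val, 2); expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:10)   # disjoint + exhaustive
  sp2 <- split_dataset(1:10, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(split_dataset(1:10, seed = 4)$train, sp$train))
  big <- split_dataset(sprintf("c%03d", 1:200), seed = 1)
  expect_length(big$train, 120); expect_length(big$test, 40)
})

test_that("a short training run learns and logs per-epoch history", {
  cases <- lapply(1:4, phantom_case, grid_shape = c(8, 8, 16),
                  voxel_spacing_mm = c(12, 12, 12),
                  radii_range_mm = c(30, 55))
  cfg <- vnet_config(levels = 2, base_channels = 4, epochs = 6,
                     batch_size = 2, seed = 5, augment_per_case = 1,
                     enc_convs = c(1, 2))
  fit <- train_vnet(cases, cfg, val_cases = cases[1])
  expect_equal(nrow(fit$history), 6)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_true(all(is.finite(fit$history$val_loss)))
  # reproducibility: same cases + cfg give identical history
  fit2 <- train_vnet(cases, cfg, val_cases = cases[1])
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
})

test_that("model checkpoints round-trip with their metadata sidecar", {
  model <- build_vnet(tiny_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_vnet(model, path)
  m2 <- load_vnet(path)
  expect_equal(m2$params, model$params)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$levels, 2)
  expect_equal(meta$n_params, n_params(model))
})
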