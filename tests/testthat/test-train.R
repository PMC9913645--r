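test_that("the step schedule divides by 10 at the milestones with a floor", {
  cfg <- rtn_train_config(epochs = 200)
  expect_equal(lr_at(10, cfg), 0.01)
  expect_equal(lr_at(49, cfg), 0.01)
  expect_equal(lr_at(50, cfg), 0.001)
  expect_equal(lr_at(120, cfg), 1e-4)
  expect_equal(lr_at(200, cfg), 1e-5)   # floor after three milestones
  lin <- rtn_train_config(epochs = 100, schedule = "linear")
  expect_equal(lr_at(1, lin), 0.01)
  expect_equal(lr_at(100, lin), 1e-5)
  expect_lt(lr_at(50, lin), 0.01)
})

test_that("training config validates its fields", {
  expect_error(rtn_train_config(lr0 = -1), "positive")
  expect_error(rtn_train_config(milestones = c(100, 50)), "increase")
  expect_error(rtn_train_config(imbalance = "focal"))
})

test_that("a zero-step run leaves parameters unchanged", {
  m <- tiny_model(seed = 20)
  x <- tiny_images(8, seed = 9)
  y <- rep(0:1, 4)
  cfg <- rtn_train_config(lr0 = 1e-30, lr_floor = 1e-31, epochs = 1,
                          batch_size = 8, seed = 1, imbalance = "none")
  tr <- rtn_train(m, x, y, cfg)
  for (nm in names(m$params))
    expect_equal(tr$model$params[[nm]], m$params[[nm]], tolerance = 1e-20)
})

test_that("training is deterministic given the seed", {
  x <- tiny_images(12, seed = 10)
  y <- rep(0:1, 6)
  cfg <- rtn_train_config(epochs = 2, batch_size = 6, seed = 3)
  tr1 <- rtn_train(tiny_model(seed = 21), x, y, cfg)
  tr2 <- rtn_train(tiny_model(seed = 21), x, y, cfg)
  expect_identical(tr1$history$train_loss, tr2$history$train_loss)
  expect_equal(tr1$model$params, tr2$model$params)
})

test_that("loss decreases over the first ten steps on a frozen batch", {
  ## one full-resolution batch trained repeatedly (batch size = n, so each
  ## epoch is exactly one SGD step at lr 0.01)
  for (seed in 1:3) {
    co <- generate_synthetic_cohort(n_patients = 32, images_per_patient = 1,
                                    prevalence = 0.5, effect_size = 3,
                                    survival_link = NULL, seed = seed)
    m <- rtn_build(rtn_model_config(n_blocks = 2L, d = 32L), seed = seed)
    tr <- rtn_train(m, co$images, co$meta$label,
                    rtn_train_config(epochs = 10, batch_size = 32,
                                     seed = seed, imbalance = "none"))
    expect_lt(tr$history$train_loss[10], tr$history$train_loss[1])
  }
})

test_that("every imbalance strategy runs and logs a complete history", {
  x <- tiny_images(12, seed = 11)
  y <- rep(c(0L, 1L), c(9, 3))
  for (st in c("none", "oversample", "reweight", "gradient_penalty")) {
    cfg <- rtn_train_config(epochs = 2, batch_size = 6, seed = 2,
                            imbalance = st)
    tr <- rtn_train(tiny_model(seed = 22), x, y, cfg,
                    test = list(images = tiny_images(4, seed = 12),
                                labels = c(0, 1, 0, 1)))
    expect_equal(nrow(tr$history), 2)
    expect_true(all(is.finite(tr$history$train_loss)))
    expect_true(all(is.finite(tr$history$test_loss)))
    expect_false(is.null(tr$best))
  }
})

test_that("augmented training keeps the label pipeline intact", {
  x <- tiny_images(8, seed = 13)
  y <- rep(0:1, 4)
  cfg <- rtn_train_config(epochs = 1, batch_size = 4, seed = 5,
                          imbalance = "none",
                          augment_cfg = augment_config(max_rotate = 10))
  tr <- rtn_train(tiny_model(seed = 23), x, y, cfg)
  expect_true(is.finite(tr$history$train_loss[1]))
})

test_that("a trained-state checkpoint round-trips through disk exactly", {
  x <- tiny_images(8, seed = 14)
  y <- rep(0:1, 4)
  tr <- rtn_train(tiny_model(seed = 24), x, y,
                  rtn_train_config(epochs = 1, batch_size = 8, seed = 6))
  path <- tempfile(fileext = ".rds")
  rtn_save(tr$model, path)
  m2 <- rtn_load(path)
  expect_identical(rtn_predict(tr$model, x), rtn_predict(m2, x))
  unlink(path)
})
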