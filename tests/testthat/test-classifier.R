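test_that("hyperparameters are validated", {
  expect_error(hyperparams(dropout = 1), class = "sliceleak_bad_hp")
  expect_error(hyperparams(learning_rate = 0), class = "sliceleak_bad_hp")
  expect_error(hyperparams("tinycnn", input_size = 20), class = "sliceleak_bad_hp")
  hp <- hyperparams()
  expect_equal(hp$dropout, 0.2)
  expect_equal(hp$batch_size, 256L)
  expect_equal(hp$learning_rate, 1e-5)
})

test_that("model construction is deterministic given the seed", {
  hp <- hyperparams("tinycnn", input_size = 16, seed = 7)
  m1 <- build_model(hp)
  m2 <- build_model(hp)
  expect_identical(model_checksum(m1), model_checksum(m2))
  m3 <- build_model(hyperparams("tinycnn", input_size = 16, seed = 8))
  expect_false(identical(model_checksum(m1), model_checksum(m3)))
})

test_that("both architectures end in a 2-logit binary head", {
  ns <- asNamespace("sliceleak")
  for (arch in c("tinycnn", "resnet18")) {
    hp <- hyperparams(arch, input_size = 32, seed = 1)
    m <- build_model(hp)
    x <- withr::with_seed(2, array(stats::runif(32 * 32 * 3 * 3), c(32, 32, 3, 3)))
    out <- ns$seq_forward(m$layers, x, train = FALSE)$out
    expect_equal(dim(out), c(2, 3))
    head_dense <- m$layers[[length(m$layers)]]
    expect_s3_class(head_dense, "nn_dense")
    expect_equal(head_dense$out_dim, 2L)
  }
})

test_that("pretrained = TRUE without a weights file is a labeled error", {
  hp <- hyperparams("tinycnn", pretrained = TRUE, input_size = 16)
  expect_error(build_model(hp), class = "sliceleak_no_weights")
})

test_that("zero dropout makes train and eval forward passes identical", {
  ns <- asNamespace("sliceleak")
  hp <- hyperparams("tinycnn", input_size = 16, dropout = 0, seed = 3)
  m <- build_model(hp)
  x <- withr::with_seed(4, array(stats::runif(16 * 16 * 3 * 2), c(16, 16, 3, 2)))
  a <- withr::with_seed(5, ns$seq_forward(m$layers, x, train = TRUE)$out)
  b <- ns$seq_forward(m$layers, x, train = FALSE)$out
  expect_identical(a, b)
})

test_that("epochs = 0 is a no-op with an empty history", {
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 0, seed = 1)
  m <- build_model(hp)
  d <- separable_images(10, size = 16)
  trained <- train_model(m, d$x, d$y, hp)
  expect_identical(model_checksum(trained), model_checksum(m))
  expect_length(trained$history, 0)
  expect_false(trained$trained)
})

test_that("training separates linearly separable classes", {
  # bound established by a prior calibration run at these exact settings
  d <- separable_images(30, size = 16, seed = 6)
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 8, batch_size = 16,
                    learning_rate = 1e-3, seed = 2)
  m <- train_model(build_model(hp), d$x, d$y, hp)
  expect_length(m$history, 8)
  expect_gte(m$history[[8]]$accuracy, 0.95)
  pred <- predict(m, d$x)
  expect_gte(mean(pred$label == d$y), 0.95)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("training is reproducible given the seed", {
  d <- separable_images(8, size = 16, seed = 7)
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 2, batch_size = 8,
                    learning_rate = 1e-3, seed = 9)
  m1 <- train_model(build_model(hp), d$x, d$y, hp)
  m2 <- train_model(build_model(hp), d$x, d$y, hp)
  expect_identical(model_checksum(m1), model_checksum(m2))
  expect_equal(m1$history, m2$history)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
})

test_that("single-class training sets and empty predictions are labeled errors", {
  d <- separable_images(4, size = 16)
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 1)
  expect_error(train_model(build_model(hp), d$x, rep(0L, 8), hp),
               class = "sliceleak_single_class")
  m <- build_model(hp)
  expect_error(predict(m, d$x), class = "sliceleak_untrained_model")
  expect_error(predict(m, d$x[, , , 0, drop = FALSE], allow_untrained = TRUE),
               class = "sliceleak_empty_input")
})

test_that("untrained model on balanced data scores at chance", {
  # structure-free inputs with arbitrary balanced labels: predictions are
  # label-independent by construction
  x <- withr::with_seed(8, array(stats::runif(16 * 16 * 3 * 200), c(16, 16, 3, 200)))
  y <- rep(c(0L, 1L), 100)
  hp <- hyperparams("tinycnn", input_size = 16, seed = 4)
  pred <- predict(build_model(hp), x, allow_untrained = TRUE)
  acc <- mean(pred$label == y)
  ci_half <- 1.96 * sqrt(0.25 / 200)
  expect_lt(abs(acc - 0.5), ci_half + 1e-9)
  # identical inputs get identical predictions
  dup <- x[, , , c(1, 1), drop = FALSE]
  pd <- predict(build_model(hp), dup, allow_untrained = TRUE)
  expect_identical(pd$score[1], pd$score[2])
})

test_that("label-shuffled training gives chance-level held-out accuracy", {
  d <- separable_images(20, size = 16, seed = 10)
  y_shuffled <- withr::with_seed(11, sample(d$y))
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 3, batch_size = 16,
                    learning_rate = 1e-3, seed = 12)
  m <- train_model(build_model(hp), d$x, y_shuffled, hp)
  fresh <- separable_images(50, size = 16, seed = 13)
  acc <- mean(predict(m, fresh$x)$label == withr::with_seed(14, sample(fresh$y)))
  ci_half <- 1.96 * sqrt(0.25 / 100)
  expect_lt(abs(acc - 0.5), ci_half + 1e-9)
})

test_that("batch size larger than the dataset clamps with a warning", {
  d <- separable_images(4, size = 16, seed = 15)
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 1, batch_size = 256,
                    learning_rate = 1e-3, seed = 5)
  expect_warning(train_model(build_model(hp), d$x, d$y, hp), "clamping")
})

test_that("model parameters round-trip through the JSON checkpoint", {
  d <- separable_images(6, size = 16, seed = 16)
  hp <- hyperparams("tinycnn", input_size = 16, epochs = 1, batch_size = 4,
                    learning_rate = 1e-3, seed = 6)
  m <- train_model(build_model(hp), d$x, d$y, hp)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model_weights(build_model(hp), path)
  expect_true(m2$trained)
  # text serialization is exact to the last decimal digit (~1 ulp)
  expect_equal(sliceleak:::model_param_vector(m2),
               sliceleak:::model_param_vector(m), tolerance = 1e-14)
  expect_equal(predict(m2, d$x), predict(m, d$x), tolerance = 1e-12)
})
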