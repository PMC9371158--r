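test_that("reference architectures match their published structure", {
  s1 <- build_architecture("CNN1", 17)
  expect_length(s1$blocks, 4)
  expect_equal(sum(vapply(s1$blocks, `[[`, integer(1), "n_conv_layers")), 8L)
  expect_true(all(vapply(s1$blocks, `[[`, integer(1), "kernel_size") == 8L))
  expect_true(all(vapply(s1$blocks, `[[`, integer(1), "n_filters") == 100L))
  expect_equal(vapply(s1$blocks, `[[`, logical(1), "followed_by_pool"),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(s1$dropout_rate, 0.5)

  s2 <- build_architecture("CNN2", 17)
  expect_length(s2$blocks, 3)
  expect_equal(sum(vapply(s2$blocks, `[[`, integer(1), "n_conv_layers")), 6L)
  expect_true(all(vapply(s2$blocks, `[[`, integer(1), "kernel_size") == 4L))
  expect_equal(vapply(s2$blocks, `[[`, logical(1), "followed_by_pool"),
               c(TRUE, TRUE, FALSE))

  # biometric heads take the subject count as softmax width
  s3 <- build_architecture("CNN1", 29)
  expect_equal(s3$n_classes, 29L)
  expect_error(build_architecture("CNN1", 1), "at least 2")
})

test_that("last_conv_length reproduces the printed resolutions", {
  expect_equal(last_conv_length(build_architecture("CNN1", 17), 151), 19L)
  expect_equal(last_conv_length(build_architecture("CNN2", 17), 151), 38L)
  expect_equal(last_conv_length(build_architecture("CNN1", 17), 160), 20L)
  nopool <- cnn_spec(list(conv_block(2, 8, 8, FALSE)), 2)
  expect_equal(last_conv_length(nopool, 151), 151L)
})

test_that("last_conv_length is monotone non-decreasing in input length", {
  for (name in c("CNN1", "CNN2")) {
    spec <- build_architecture(name, 5)
    lens <- vapply(8:200, function(L) last_conv_length(spec, L), integer(1))
    expect_true(all(diff(lens) >= 0))
  }
})

test_that("a separable two-class toy trains to high validation macro F1", {
  m <- toy_model()
  expect_gte(max(m$history$val_macro_f1), 0.95)
})

test_that("checkpointing keeps the earliest best-macro-F1 epoch", {
  m <- toy_model()
  f1 <- m$history$val_macro_f1
  expect_equal(m$checkpoint_epoch, which.max(f1))   # which.max = earliest tie
  expect_equal(nrow(m$history), 5L)
})

test_that("training is reproducible for a fixed seed", {
  ds <- toy_dataset(seed = 7, n_subjects = 2, wpp = 4)
  plan <- split_subject_dependent(ds, 0.3, seed = 42)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 3)
  m1 <- train_model(tiny_spec(2), ds, plan, cfg)
  m2 <- train_model(tiny_spec(2), ds, plan, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})

test_that("predictions are proper probability vectors with low-index ties", {
  m <- toy_model()
  ds <- toy_dataset(seed = 20, n_subjects = 2, wpp = 2)
  p <- predict(m, ds)
  expect_equal(dim(p$scores), c(n_windows(ds), 2L))
  expect_true(all(abs(rowSums(p$scores) - 1) < 1e-6))
  expect_true(all(p$scores >= 0))

  # exact tie resolves to the lowest class index
  tied <- m
  j <- length(tied$layers)
  tied$layers[[j]]$W[] <- 0
  tied$layers[[j]]$b[] <- 0
  pt <- predict(tied, get_window(ds, 1))
  expect_equal(pt$scores[1, ], c(0.5, 0.5))
  expect_equal(pt$class, 1L)
})

test_that("shape mismatches are rejected with the expected shape named", {
  m <- toy_model()
  expect_error(predict(m, matrix(0, 100, 3)), "151 x 3")
  expect_error(predict(m, array(0, dim = c(2, 151, 2))), "151 x 3")
})

test_that("a class absent from training triggers a recorded warning", {
  ds <- toy_dataset(seed = 7, n_subjects = 2, wpp = 4)
  slow <- which(ds$meta$activity == "slow")
  fast <- which(ds$meta$activity == "fast")
  plan <- harcam:::new_split_plan("SD", train = slow,
                                  val = c(fast[1:3], slow[1]))
  expect_warning(
    m <- train_model(tiny_spec(2), ds, plan,
                     train_config(epochs = 1, batch_size = 8, seed = 1)),
    "absent in training")
  expect_match(m$warnings, "fast")
})

test_that("training rejects an empty training set and class-count mismatch", {
  ds <- toy_dataset(seed = 7, n_subjects = 2, wpp = 4)
  empty <- harcam:::new_split_plan("SD", train = integer(0), val = 1:4)
  expect_error(train_model(tiny_spec(2), ds, empty, train_config(1, 8)),
               "empty")
  plan <- split_subject_dependent(ds, 0.3, 42)
  expect_error(train_model(tiny_spec(3), ds, plan, train_config(1, 8)),
               "classes")
})

test_that("backpropagated feature-map gradients match finite differences", {
  m <- toy_model()
  ds <- toy_dataset(seed = 21, n_subjects = 1, wpp = 1)
  w <- get_window(ds, 1)
  for (cls in 1:2) {
    ag <- activations_and_gradient(m, w, cls)
    Z <- last_conv_length(m$spec)
    expect_equal(dim(ag$feature_maps), c(Z, 8L))
    expect_equal(dim(ag$gradient), dim(ag$feature_maps))

    A <- ag$feature_maps
    eps <- 1e-3
    set.seed(cls)
    idx <- cbind(sample(nrow(A), 6), sample(ncol(A), 6, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      Ap <- A; Am <- A
      Ap[idx[r, 1], idx[r, 2]] <- A[idx[r, 1], idx[r, 2]] + eps
      Am[idx[r, 1], idx[r, 2]] <- A[idx[r, 1], idx[r, 2]] - eps
      fd <- (harcam:::forward_from_designated(m, Ap)[cls] -
               harcam:::forward_from_designated(m, Am)[cls]) / (2 * eps)
      an <- ag$gradient[idx[r, 1], idx[r, 2]]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("a zero-weight class head yields an identically zero gradient", {
  m <- toy_model()
  j <- length(m$layers)
  m$layers[[j]]$W[, 2] <- 0
  m$layers[[j]]$b[2] <- 0
  ds <- toy_dataset(seed = 22, n_subjects = 1, wpp = 1)
  ag <- activations_and_gradient(m, get_window(ds, 1), 2)
  expect_true(all(ag$gradient == 0))
})

test_that("post-softmax gradients follow the softmax chain rule", {
  m <- toy_model()
  ds <- toy_dataset(seed = 23, n_subjects = 1, wpp = 1)
  w <- get_window(ds, 1)
  p <- predict(m, w)$scores[1, ]
  pre <- activations_and_gradient(m, w, 1)
  pre2 <- activations_and_gradient(m, w, 2)
  post <- activations_and_gradient(m, w, 1, post_softmax = TRUE)
  # d p1 / dA = p1 (1 - p1) dy1/dA - p1 p2 dy2/dA
  expect_equal(post$gradient,
               p[1] * (1 - p[1]) * pre$gradient - p[1] * p[2] * pre2$gradient,
               tolerance = 1e-10)
})

test_that("models survive a save/load round trip", {
  m <- toy_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  ds <- toy_dataset(seed = 24, n_subjects = 1, wpp = 2)
  expect_equal(predict(back, ds)$scores, predict(m, ds)$scores,
               tolerance = 1e-12)
  expect_equal(back$checkpoint_epoch, m$checkpoint_epoch)
  expect_identical(back$class_labels, m$class_labels)
})
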