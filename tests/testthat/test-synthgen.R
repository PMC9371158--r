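test_that("cohorts and datasets are deterministic per seed", {
  cfg <- synth_config(n_subjects = 4, activities = toy_templates(),
                      windows_per_subject_activity = 3, dropout_pairs = NULL)
  expect_identical(build_cohort(cfg, 9), build_cohort(cfg, 9))
  d1 <- generate_dataset(cfg, 9)
  d2 <- generate_dataset(cfg, 9)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$meta, d2$meta)
  d3 <- generate_dataset(cfg, 10)
  expect_false(identical(d1$values, d3$values))
})

test_that("zero signature strength makes subjects generatively identical", {
  cfg <- synth_config(n_subjects = 5, activities = toy_templates(),
                      windows_per_subject_activity = 1,
                      signature_strength = 0, noise_sd = 0,
                      dropout_pairs = NULL)
  sigs <- build_cohort(cfg, 4)
  for (s in sigs[-1]) {
    expect_equal(s$axis_gain, sigs[[1]]$axis_gain)
    expect_equal(s$frequency_offset_hz, 0)
    expect_equal(s$orientation_rotation, diag(3))
  }
  ds <- generate_dataset(cfg, 4)
  w1 <- ds$values[ds$meta$subject == 1 & ds$meta$activity == "slow", , ]
  w2 <- ds$values[ds$meta$subject == 2 & ds$meta$activity == "slow", , ]
  expect_equal(w1, w2)
})

test_that("signature deviations scale linearly with strength", {
  gain_sd <- function(strength, seed) {
    cfg <- synth_config(n_subjects = 1000, activities = toy_templates(),
                        windows_per_subject_activity = 0,
                        signature_strength = strength, dropout_pairs = NULL)
    sigs <- build_cohort(cfg, seed)
    g <- t(vapply(sigs, `[[`, numeric(3), "axis_gain"))
    mean(apply(g, 2, sd))
  }
  ratio <- gain_sd(1.0, 21) / gain_sd(0.5, 21)
  expect_equal(ratio, 2, tolerance = 0.1)   # Monte-Carlo over 1000 subjects
})

test_that("rotations are orthonormal with determinant +1 and gains bounded", {
  cfg <- synth_config(n_subjects = 50, activities = toy_templates(),
                      windows_per_subject_activity = 0,
                      signature_strength = 1, dropout_pairs = NULL)
  for (s in build_cohort(cfg, 2)) {
    R <- s$orientation_rotation
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_true(all(s$axis_gain >= 0.5 & s$axis_gain <= 2))
  }
})

test_that("default-config windows have 151 samples per axis at 50 Hz", {
  cfg <- synth_config(n_subjects = 2,
                      windows_per_subject_activity = 1)
  ds <- generate_dataset(cfg, 1)
  expect_equal(dim(ds$values)[2], 151L)
  expect_equal(dim(ds$values)[3], 3L)
  expect_equal(ds$sample_rate_hz, 50)
  expect_equal(length(ds$activity_vocabulary), 17L)
})

test_that("the dominant event sits at the central timestep", {
  cfg <- synth_config(n_subjects = 1, activities = toy_templates(),
                      windows_per_subject_activity = 1,
                      signature_strength = 0, noise_sd = 0,
                      dropout_pairs = NULL)
  ds <- generate_dataset(cfg, 1)
  w <- get_window(ds, 1)
  vert <- w$values[, 3] - mean(w$values[, 3])  # remove gravity offset
  expect_equal(which.max(abs(vert)) - 1L, 75L) # 0-based center = floor(151/2)
})

test_that("gravity appears as a ~9.81 offset on the gravity axis", {
  cfg <- synth_config(n_subjects = 1, activities = toy_templates(),
                      windows_per_subject_activity = 1,
                      signature_strength = 0, noise_sd = 0,
                      dropout_pairs = NULL)
  ds <- generate_dataset(cfg, 1)
  expect_equal(mean(ds$values[1, , 3]), 9.81, tolerance = 0.2)
})

test_that("a 2 Hz periodic template peaks at 2 Hz in the amplitude spectrum", {
  tpl <- list(activity_template("two", "periodic", 2.0, 3, 0.5))
  cfg <- synth_config(n_subjects = 1, activities = tpl,
                      windows_per_subject_activity = 1,
                      signature_strength = 0, noise_sd = 0,
                      dropout_pairs = NULL)
  ds <- generate_dataset(cfg, 1)
  x <- ds$values[1, , 3]
  spec <- Mod(fft(x - mean(x)))[2:75]            # positive frequencies, no DC
  freqs <- (1:74) * 50 / 151
  expect_equal(freqs[which.max(spec)], 2, tolerance = 0.2)
})

test_that("dropout pairs and per-activity tables control window counts", {
  drop <- data.frame(subject = 2L, activity = "slow")
  cfg <- synth_config(n_subjects = 3, activities = toy_templates(),
                      windows_per_subject_activity = c(slow = 4, fast = 2),
                      dropout_pairs = drop)
  ds <- generate_dataset(cfg, 3)
  tab <- table(ds$meta$activity, ds$meta$subject)
  expect_equal(tab["slow", "2"], 0)
  expect_equal(tab["slow", "1"], 4)
  expect_equal(tab["fast", "3"], 2)
})

test_that("sustained steps have exactly the requested one-sample difference", {
  ds <- toy_dataset(seed = 6, n_subjects = 2, wpp = 4, noise_sd = 0.3)
  spec <- bias_injection_spec("slow", probability_per_window = 1,
                              jump_magnitude = 11, affected_axes = c(2L, 3L))
  res <- inject_discontinuities(ds, spec, 5)
  expect_true(nrow(res$plants) > 0)
  for (r in seq_len(nrow(res$plants))) {
    p <- res$plants[r, ]
    x <- res$dataset$values[p$window, , p$axis]
    expect_equal(x[p$timestep + 2] - x[p$timestep + 1], p$delta)
    expect_equal(abs(p$delta), 11)
    # the level shift persists: the rest of the suffix is unchanged in shape
    orig <- ds$values[p$window, , p$axis]
    expect_equal(diff(x[(p$timestep + 2):151]),
                 diff(orig[(p$timestep + 2):151]))
  }
  # non-target activity untouched
  fast <- which(ds$meta$activity == "fast")
  expect_identical(res$dataset$values[fast, , ], ds$values[fast, , ])
})

test_that("probability zero leaves the dataset unchanged", {
  ds <- toy_dataset(seed = 6, n_subjects = 2, wpp = 2)
  spec <- bias_injection_spec("slow", probability_per_window = 0)
  res <- inject_discontinuities(ds, spec, 5)
  expect_identical(res$dataset$values, ds$values)
  expect_equal(nrow(res$plants), 0L)
})

test_that("planted counts follow the binomial under fractional probability", {
  ds <- toy_dataset(seed = 8, n_subjects = 10, wpp = 40)  # 400 'slow' windows
  spec <- bias_injection_spec("slow", probability_per_window = 0.5,
                              affected_axes = 2L)
  res <- inject_discontinuities(ds, spec, 11)
  n_planted <- length(unique(res$plants$window))
  expect_true(abs(n_planted - 200) <= 3 * sqrt(400 * 0.25))
})

test_that("spike mode alters exactly one sample", {
  ds <- toy_dataset(seed = 6, n_subjects = 1, wpp = 2)
  spec <- bias_injection_spec("slow", mode = "single-sample-spike",
                              affected_axes = 2L)
  res <- inject_discontinuities(ds, spec, 2)
  p <- res$plants[1, ]
  x <- res$dataset$values[p$window, , 2]
  orig <- ds$values[p$window, , 2]
  changed <- which(x != orig)
  expect_equal(changed, p$timestep + 2)
  expect_equal(x[p$timestep + 2] - x[p$timestep + 1], p$delta)
})

test_that("subject-activity granularity reuses one position per pair", {
  ds <- toy_dataset(seed = 6, n_subjects = 3, wpp = 5)
  spec <- bias_injection_spec("slow", position_granularity = "subject-activity",
                              affected_axes = 2L)
  res <- inject_discontinuities(ds, spec, 7)
  by_subj <- split(res$plants$timestep,
                   ds$meta$subject[res$plants$window])
  for (ts in by_subj) expect_equal(length(unique(ts)), 1L)
  expect_gt(length(unique(unlist(by_subj))), 1L)  # positions differ by pair
})

test_that("injection validates its inputs", {
  ds <- toy_dataset(seed = 1, n_subjects = 1, wpp = 1)
  expect_error(
    inject_discontinuities(ds, bias_injection_spec("NotThere"), 1),
    "NotThere")
  expect_error(bias_injection_spec("slow", jump_magnitude = -1), "positive")
  expect_error(bias_injection_spec("slow", probability_per_window = 1.2),
               "\\[0, 1\\]")
})

test_that("nearest-centroid subject identification improves with signature strength", {
  acc_at <- function(strength) {
    accs <- numeric(0)
    for (seed in 1:2) {
      ds <- generate_dataset(
        synth_config(n_subjects = 5,
                     activities = toy_templates()[1],
                     windows_per_subject_activity = 6,
                     signature_strength = strength, noise_sd = 1.5,
                     dropout_pairs = NULL),
        seed)
      X <- ds$values
      dim(X) <- c(dim(X)[1], 151 * 3)
      subj <- ds$meta$subject
      train <- unlist(lapply(split(seq_along(subj), subj), head, 3))
      test <- setdiff(seq_along(subj), train)
      cent <- do.call(rbind, lapply(split(train, subj[train]), function(ii)
        colMeans(X[ii, , drop = FALSE])))
      pred <- apply(X[test, ], 1, function(x)
        which.min(colSums((t(cent) - x)^2)))
      accs <- c(accs, mean(pred == subj[test]))
    }
    mean(accs)
  }
  expect_gt(acc_at(0.8), acc_at(0.2))
})
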