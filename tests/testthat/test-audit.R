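test_that("importance extent is the super-threshold fraction", {
  ones <- structure(list(values = rep(1, 151)), class = "heatmap")
  zeros <- structure(list(values = rep(0, 151)), class = "heatmap")
  expect_equal(importance_extent(ones, 0.7), 1)
  expect_equal(importance_extent(zeros, 0.7), 0)
  expect_error(importance_extent(ones, 1.4), "\\[0, 1\\]")

  # a 19-position source map upsampled to 151: extent by brute enumeration
  src <- rep(0, 19); src[c(3, 11, 17)] <- 1
  up <- upsample_nearest(src, 151)
  hits <- sum((floor((0:150) * 19 / 151) + 1) %in% c(3, 11, 17))
  expect_equal(importance_extent(up, 0.7), hits / 151)
})

test_that("extent is monotone non-increasing in the threshold", {
  set.seed(12)
  v <- runif(151)
  taus <- seq(0, 1, by = 0.05)
  exts <- vapply(taus, function(t) importance_extent(v, t), numeric(1))
  expect_true(all(diff(exts) <= 0))
})

test_that("discontinuity detection finds implausible one-sample jumps", {
  # the printed example: a rise from -10 to 1.3 on y, a fall 2.8 -> -9.2 on z
  x <- matrix(0, 151, 3)
  x[, 2] <- c(rep(-10, 60), rep(1.3, 91))
  x[, 3] <- c(rep(2.8, 60), rep(-9.2, 91))
  w <- signal_window(x, "SittingDown", 1)
  ev <- detect_discontinuities(w, 10)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$timestep, c(59L, 59L))
  expect_equal(ev$delta, c(11.3, -12), tolerance = 1e-12)
  expect_equal(ev$elapsed, c(0.02, 0.02))

  const <- signal_window(matrix(5, 151, 3), "A", 1)
  expect_equal(nrow(detect_discontinuities(const, 10)), 0L)
})

test_that("smooth sinusoids at 50 Hz never trip the default threshold", {
  t <- (0:150) / 50
  x <- matrix(5 * sin(2 * pi * 2 * t), 151, 3)
  w <- signal_window(x, "Walking", 1)
  # max one-sample step of a 2 Hz, 5 m/s^2 sinusoid is ~1.26 m/s^2
  expect_lte(max(abs(diff(x[, 1]))), 5 * 2 * pi * 2 / 50)
  expect_equal(nrow(detect_discontinuities(w, 10)), 0L)
})

test_that("planted sustained steps are all recovered by the detector", {
  ds <- toy_dataset(seed = 16, n_subjects = 2, wpp = 4, noise_sd = 0.3)
  res <- inject_discontinuities(
    ds, bias_injection_spec("slow", jump_magnitude = 11,
                            affected_axes = c(2L, 3L)), 3)
  for (i in unique(res$plants$window)) {
    ev <- detect_discontinuities(get_window(res$dataset, i), 10)
    planted <- res$plants[res$plants$window == i, ]
    expect_true(all(planted$timestep %in% ev$timestep))
  }
})

test_that("co-localization scores and degenerate cases follow the contract", {
  v <- rep(0, 151); v[70:75] <- 1
  ev <- data.frame(timestep = 71L, axis = 2L, delta = 11, elapsed = 0.02)
  cl <- colocalization(v, ev, tau = 0.7, halo_w = 2L)
  expect_true(cl$defined)
  # halo = [t-2, t+3] = 69..74 (0-based) = exactly the super-threshold set
  expect_equal(cl$score, 1)
  expect_equal(cl$chance, 6 / 151)
  expect_equal(cl$enrichment, 151 / 6)

  none <- colocalization(v, ev[0, ], 0.7, 2L)
  expect_false(none$defined)
  flat <- colocalization(rep(0, 151), ev, 0.7, 2L)
  expect_false(flat$defined)
})

test_that("random masks score at chance under the null", {
  set.seed(31)
  ev <- data.frame(timestep = c(30L, 90L), axis = c(2L, 2L),
                   delta = c(11, -11), elapsed = 0.02)
  scores <- replicate(10000, {
    v <- rep(0, 151)
    v[sample.int(151, 12)] <- 1
    colocalization(v, ev, tau = 0.7, halo_w = 2L)$score
  })
  chance <- colocalization(c(1, rep(0, 150)), ev, 0.7, 2L)$chance
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - chance), 3 * se)
})

test_that("correlation reproduces the t-based noncorrelation p-value", {
  x <- 1:6
  expect_equal(correlate_performance(x, 2 * x + 1)$r, 1)

  set.seed(8)
  a <- rnorm(12); b <- 0.4 * a + rnorm(12)
  res <- correlate_performance(a, b)
  r <- cor(a, b)
  tstat <- r * sqrt((12 - 2) / (1 - r^2))
  expect_equal(res$r, r)
  expect_equal(res$p, 2 * pt(-abs(tstat), 10), tolerance = 1e-12)

  flat <- correlate_performance(rep(1, 5), rnorm(5))
  expect_false(flat$defined)
  expect_error(correlate_performance(1:2, 1:2), "at least 3")
})

test_that("a clean cohort is audited without bias flags", {
  for (seed in 1:2) {
    g <- gap_models(seed)
    rep <- run_audit(g$dataset, g$models, g$plans,
                     audit_config(seed = seed, windows_per_class = 4))
    expect_equal(nrow(rep$events), 0L)
    expect_length(rep$flagged, 0L)
    expect_true(all(rep$extents$extent >= 0 & rep$extents$extent <= 1))
    expect_setequal(rep$extent_by_tag$group, c("sd", "si"))
  }
})

test_that("audit reports serialize and reload losslessly", {
  g <- gap_models(1)
  rep <- run_audit(g$dataset, g$models, g$plans,
                   audit_config(seed = 1, windows_per_class = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_audit_report(rep, f)
  back <- read_audit_report(f)
  expect_equal(back$gaps$gap, rep$gaps$gap)
  expect_identical(back$flagged, rep$flagged)
  expect_equal(back$extent_by_tag$mean, rep$extent_by_tag$mean)
  expect_equal(back$config$tau, rep$config$tau)
})

test_that("run_audit demands both SD and SI models", {
  g <- gap_models(1)
  expect_error(run_audit(g$dataset, list(sd = g$models$sd),
                         list(sd = g$plans$sd), audit_config()),
               "missing model or plan")
})
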