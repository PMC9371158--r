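## Synthetic accelerometer cohorts: peak-centered 151 x 3 windows at 50 Hz,
## activity key events, per-subject movement signatures, class imbalance,
## missing subject-activity pairs, and injectable level-shift artifacts.

GRAVITY <- 9.81

#' Define an activity template
#'
#' Templates describe the class-level motion pattern: a periodic gait-like
#' oscillation, a postural transition, or an impulsive fall spike. The
#' dominant event is always placed at the window center (peak-triggered
#' windowing).
#'
#' @param name activity label.
#' @param kind one of `"periodic"`, `"transition"`, `"impulsive-fall"`.
#' @param base_frequency_hz fundamental frequency for periodic templates,
#'   must lie in (0.5, 5).
#' @param event_amplitude peak event acceleration, m/s^2.
#' @param event_width_s temporal width of the key event, seconds; must be
#'   shorter than the window.
#' @param orientation_change if `TRUE`, the gravity direction rotates during
#'   the window (falls, lying down).
#' @param window_duration_s window duration used to validate
#'   `event_width_s` (default 3).
#' @return an object of class `activity_template`.
#' @export
activity_template <- function(name,
                              kind = c("periodic", "transition", "impulsive-fall"),
                              base_frequency_hz = NULL,
                              event_amplitude = 3,
                              event_width_s = 0.5,
                              orientation_change = FALSE,
                              window_duration_s = 3) {
  kind <- match.arg(kind)
  if (kind == "periodic") {
    if (is.null(base_frequency_hz) ||
        base_frequency_hz <= 0.5 || base_frequency_hz >= 5) {
      stop("periodic templates need base_frequency_hz in (0.5, 5)", call. = FALSE)
    }
  }
  if (event_amplitude <= 0) stop("event_amplitude must be positive", call. = FALSE)
  if (event_width_s <= 0 || event_width_s >= window_duration_s) {
    stop("event_width_s must be positive and shorter than the window", call. = FALSE)
  }
  structure(list(name = as.character(name), kind = kind,
                 base_frequency_hz = base_frequency_hz,
                 event_amplitude = event_amplitude,
                 event_width_s = event_width_s,
                 orientation_change = isTRUE(orientation_change)),
            class = "activity_template")
}

#' The default 17-activity vocabulary (9 ADLs + 8 fall types)
#'
#' Mirrors the standard benchmark structure for peak-centered smartphone
#' accelerometer windows: gait-like periodic ADLs, postural transitions, and
#' impulsive falls with orientation change. Fall classes are deliberately
#' similar to each other (they differ only in spike amplitude/width), which
#' reproduces the well-known fall-vs-fall confusion structure.
#'
#' @return named list of [activity_template()] objects, length 17.
#' @export
default_activity_templates <- function() {
  tpl <- list(
    activity_template("StandingUpFS", "transition", event_amplitude = 2.0,
                      event_width_s = 0.8),
    activity_template("StandingUpFL", "transition", event_amplitude = 2.6,
                      event_width_s = 1.0, orientation_change = TRUE),
    activity_template("Walking", "periodic", 1.8, 2.5, 0.5),
    activity_template("Running", "periodic", 2.8, 6.0, 0.35),
    activity_template("GoingUpS", "periodic", 1.5, 2.8, 0.6),
    activity_template("Jumping", "periodic", 2.2, 5.0, 0.4),
    activity_template("GoingDownS", "periodic", 1.7, 3.2, 0.55),
    activity_template("LyingDownFS", "transition", event_amplitude = 2.2,
                      event_width_s = 1.1, orientation_change = TRUE),
    activity_template("SittingDown", "transition", event_amplitude = 2.4,
                      event_width_s = 0.9),
    activity_template("FallingForw", "impulsive-fall", event_amplitude = 18,
                      event_width_s = 0.30, orientation_change = TRUE),
    activity_template("FallingRight", "impulsive-fall", event_amplitude = 17,
                      event_width_s = 0.28, orientation_change = TRUE),
    activity_template("FallingBack", "impulsive-fall", event_amplitude = 19,
                      event_width_s = 0.32, orientation_change = TRUE),
    activity_template("HittingObstacle", "impulsive-fall", event_amplitude = 22,
                      event_width_s = 0.22, orientation_change = FALSE),
    activity_template("FallingWithPS", "impulsive-fall", event_amplitude = 14,
                      event_width_s = 0.40, orientation_change = TRUE),
    activity_template("FallingBackSC", "impulsive-fall", event_amplitude = 15,
                      event_width_s = 0.36, orientation_change = FALSE),
    activity_template("Syncope", "impulsive-fall", event_amplitude = 16,
                      event_width_s = 0.45, orientation_change = TRUE),
    activity_template("FallingLeft", "impulsive-fall", event_amplitude = 17.5,
                      event_width_s = 0.26, orientation_change = TRUE)
  )
  names(tpl) <- vapply(tpl, `[[`, character(1), "name")
  tpl
}

## Per-activity window allocation mirroring the benchmark's class imbalance
## (total sample count per class divided by the subjects performing it).
default_windows_per_activity <- function() {
  c(StandingUpFS = 6, StandingUpFL = 8, Walking = 60, Running = 66,
    GoingUpS = 31, Jumping = 25, GoingDownS = 44, LyingDownFS = 10,
    SittingDown = 7, FallingForw = 18, FallingRight = 17, FallingBack = 18,
    HittingObstacle = 22, FallingWithPS = 16, FallingBackSC = 14,
    Syncope = 17, FallingLeft = 18)
}

## Missing subject-activity pairs: some transition classes were not performed
## by all 30 subjects. The highest subject ids are dropped (deterministic).
default_dropout_pairs <- function(n_subjects = 30L) {
  missing <- c(StandingUpFS = 6L, StandingUpFL = 2L, Walking = 1L,
               LyingDownFS = 1L, SittingDown = 2L)
  out <- do.call(rbind, lapply(names(missing), function(a) {
    k <- missing[[a]]
    data.frame(subject = seq.int(n_subjects, by = -1L, length.out = min(k, n_subjects)),
               activity = a, stringsAsFactors = FALSE)
  }))
  out[out$subject >= 1L, , drop = FALSE]
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the benchmark's study conditions: 30 subjects, the
#' 17-activity vocabulary with its class imbalance and missing
#' subject-activity pairs, 151-sample windows (3 s at 50 Hz, inclusive
#' endpoints), gravity retained on a rotated axis, and per-subject movement
#' signatures whose deviation from the population mean scales linearly with
#' `signature_strength`.
#'
#' @param n_subjects number of subjects (default 30).
#' @param activities list of [activity_template()] (default the 17-class set).
#' @param windows_per_subject_activity scalar count, a named per-activity
#'   vector, or a data frame with columns `subject`, `activity`, `n`.
#' @param signature_strength in `[0, 1]`; 0 makes all subjects generatively
#'   identical (default 0.8).
#' @param noise_sd additive white noise, m/s^2 (default 0.4).
#' @param gravity_axis body axis carrying gravity (default 3).
#' @param n_timesteps window length in samples (default 151).
#' @param sample_rate_hz sampling rate (default 50).
#' @param dropout_pairs data frame (`subject`, `activity`) of pairs that
#'   produce no windows; default mirrors the benchmark's missing pairs.
#' @param center_jitter_s uniform jitter of the key-event position, seconds
#'   (default 0: event exactly at the middle timestep).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 30L,
                         activities = default_activity_templates(),
                         windows_per_subject_activity = default_windows_per_activity(),
                         signature_strength = 0.8,
                         noise_sd = 0.4,
                         gravity_axis = 3L,
                         n_timesteps = 151L,
                         sample_rate_hz = 50,
                         dropout_pairs = default_dropout_pairs(n_subjects),
                         center_jitter_s = 0) {
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (length(activities) == 0) stop("activity list must be non-empty", call. = FALSE)
  if (signature_strength < 0 || signature_strength > 1) {
    stop("signature_strength must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!gravity_axis %in% 1:3) stop("gravity_axis must be 1, 2 or 3", call. = FALSE)
  if (is.null(names(activities))) {
    names(activities) <- vapply(activities, `[[`, character(1), "name")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), activities = activities,
    windows_per_subject_activity = windows_per_subject_activity,
    signature_strength = signature_strength, noise_sd = noise_sd,
    gravity_axis = as.integer(gravity_axis),
    n_timesteps = as.integer(n_timesteps),
    sample_rate_hz = as.numeric(sample_rate_hz),
    dropout_pairs = dropout_pairs,
    center_jitter_s = center_jitter_s
  ), class = "synth_config")
}

## Rodrigues rotation matrix about unit axis u by angle theta.
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Draw one subject's signature from the current RNG stream.
## Draw order per subject (documented, fixed): frequency offset (1 normal),
## axis gains (3 uniform), harmonic deviations (2 normal),
## smoothing factor (1 uniform), rotation axis (3 normal), angle (1 uniform).
draw_signature <- function(subject, s) {
  freq_off <- s * stats::rnorm(1, 0, 0.2)
  gain <- 1 + s * stats::runif(3, -0.5, 0.5)          # stays in [0.5, 1.5]
  harm <- s * stats::rnorm(2, 0, 0.15)
  smooth_w <- 0.05 * (1 + s * stats::runif(1, -0.8, 0.8))
  axis <- stats::rnorm(3)
  if (all(axis == 0)) axis <- c(0, 0, 1)
  angle <- s * stats::runif(1, 0, 25 * pi / 180)
  structure(list(
    subject = as.integer(subject),
    frequency_offset_hz = freq_off,
    axis_gain = gain,
    harmonic_weights = c(0.30, 0.12) + harm,
    smoothing_width_s = smooth_w,
    orientation_rotation = rotation_matrix(axis, angle)
  ), class = "subject_signature")
}

#' Draw the per-subject movement signatures of a cohort
#'
#' Signatures are the generative stand-in for the personal information a
#' biometric-identification network exploits: a gait-frequency offset,
#' per-axis gains, harmonic content, smoothing, and a device-orientation
#' rotation. All deviations from the population mean scale linearly with
#' `signature_strength`; at strength 0 every subject is identical.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; output is fully determined by `(config, seed)`.
#' @return list of `subject_signature` objects, one per subject.
#' @export
build_cohort <- function(config, seed) {
  with_preserved_rng({
    set.seed(as.integer(seed))
    lapply(seq_len(config$n_subjects), draw_signature,
           s = config$signature_strength)
  })
}

## Evaluate a saved RNG-state block, restoring .Random.seed afterwards so
## package randomness never perturbs the caller's stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

gaussian_smooth <- function(M, width_s, fs) {
  sigma <- width_s * fs
  if (sigma < 0.3) return(M)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(M)
  idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)   # replicate edges
  apply(M, 2, function(col) {
    as.numeric(stats::filter(col[idx], k, sides = 2))[(r + 1):(r + n)]
  })
}

## Neutral per-pair style (used when styles are disabled).
neutral_style <- function() {
  list(amp = 1, h = c(0, 0), hphase = c(0, 0), phase_ap = 0, phase_ml = 0,
       envw = 1)
}

## Draw one (subject, activity) performance style from the current RNG
## stream. Styles encode how a particular person performs a particular
## activity -- the consistent idiosyncrasy a subject-dependent model can
## memorize but a subject-independent one never sees. Deviations scale
## linearly with signature_strength. Draw order (fixed): amplitude factor,
## two harmonic amplitude jitters, two harmonic phase offsets, two
## secondary-axis phase offsets, envelope-width factor.
draw_style <- function(s) {
  list(amp = 1 + s * stats::runif(1, -0.5, 0.5),
       h = s * stats::runif(2, c(-0.35, -0.25), c(0.35, 0.25)),
       hphase = s * stats::runif(2, -pi, pi),
       phase_ap = s * stats::runif(1, -1.8, 1.8),
       phase_ml = s * stats::runif(1, -1.8, 1.8),
       envw = 1 + s * stats::runif(1, -0.4, 0.4))
}

## Body-frame motion for one window (timesteps x 3), before gains/rotation.
## Axis layout in the body frame: 1 = mediolateral, 2 = anteroposterior,
## 3 (or config$gravity_axis) = vertical.
template_motion <- function(tpl, sig, tc, style = neutral_style()) {
  A <- tpl$event_amplitude * style$amp
  env <- exp(-tc^2 / (2 * style$envw^2))
  M <- matrix(0, length(tc), 3)
  if (tpl$kind == "periodic") {
    f <- max(0.2, tpl$base_frequency_hz + sig$frequency_offset_hz)
    h <- sig$harmonic_weights + style$h
    vert <- A * (cos(2 * pi * f * tc) +
                   h[1] * cos(4 * pi * f * tc + style$hphase[1]) +
                   h[2] * cos(6 * pi * f * tc + style$hphase[2])) * env
    ap <- 0.5 * A * cos(2 * pi * f * tc + 0.8 + style$phase_ap) * env
    ml <- 0.3 * A * sin(2 * pi * f * tc + 0.4 + style$phase_ml) * env
    M <- cbind(ml, ap, vert)
  } else if (tpl$kind == "transition") {
    sgm <- stats::plogis(tc / 0.15)
    bump <- A * exp(-tc^2 / (2 * (tpl$event_width_s / 4)^2))
    ap <- 0.5 * A * 4 * sgm * (1 - sgm)
    ml <- 0.15 * A * sin(2 * pi * 1.2 * tc + style$phase_ml) * env
    M <- cbind(ml, ap, bump)
  } else { # impulsive-fall
    sigma <- tpl$event_width_s / 4 * style$envw
    spike <- A * exp(-tc^2 / (2 * sigma^2))
    ap <- 0.4 * A * exp(-(tc - 0.08)^2 / (2 * sigma^2))
    ml <- 0.2 * A * exp(-(tc + 0.05)^2 / (2 * sigma^2))
    M <- cbind(ml, ap, spike)
  }
  M
}

## Gravity contribution (timesteps x 3) in the body frame, including the
## orientation flip of falls/lying transitions and the free-fall dip that
## precedes an impact.
gravity_track <- function(tpl, tc, gravity_axis) {
  n <- length(tc)
  e0 <- numeric(3); e0[gravity_axis] <- 1
  D <- matrix(rep(e0, each = n), n, 3)
  if (tpl$orientation_change) {
    e1 <- numeric(3); e1[(gravity_axis %% 3) + 1L] <- 1
    sgm <- stats::plogis(tc / 0.25)
    D <- (1 - sgm) %o% e0 + sgm %o% e1
    D <- D / sqrt(rowSums(D^2))
  }
  gmag <- rep(GRAVITY, n)
  if (tpl$kind == "impulsive-fall") {
    gmag <- GRAVITY * (1 - 0.7 * exp(-(tc + 0.4)^2 / (2 * 0.15^2)))
  }
  D * gmag
}

synth_window_values <- function(tpl, sig, config, style = neutral_style()) {
  fs <- config$sample_rate_hz
  n <- config$n_timesteps
  t_center <- (n - 1) / 2 / fs
  jitter <- if (config$center_jitter_s > 0)
    stats::runif(1, -config$center_jitter_s, config$center_jitter_s) else 0
  tc <- (seq_len(n) - 1) / fs - t_center - jitter

  M <- template_motion(tpl, sig, tc, style)
  ## reorder body axes so the vertical channel sits on gravity_axis
  ord <- c(1L, 2L, 3L)
  if (config$gravity_axis != 3L) {
    ord[c(config$gravity_axis, 3L)] <- ord[c(3L, config$gravity_axis)]
  }
  M <- M[, order(ord), drop = FALSE]
  M <- sweep(M, 2, sig$axis_gain, `*`)
  M <- gaussian_smooth(M, sig$smoothing_width_s, fs)
  X <- (M + gravity_track(tpl, tc, config$gravity_axis)) %*%
    t(sig$orientation_rotation)
  if (config$noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X))
  }
  X
}

resolve_count <- function(wpsa, subject, activity) {
  if (is.data.frame(wpsa)) {
    hit <- wpsa$subject == subject & wpsa$activity == activity
    return(if (any(hit)) as.integer(wpsa$n[which(hit)[1]]) else 0L)
  }
  if (!is.null(names(wpsa))) {
    return(if (activity %in% names(wpsa)) as.integer(wpsa[[activity]]) else 0L)
  }
  as.integer(wpsa[1])
}

is_dropped <- function(dropout, subject, activity) {
  if (is.null(dropout) || nrow(dropout) == 0L) return(FALSE)
  any(dropout$subject == subject & dropout$activity == activity)
}

#' Generate a labelled synthetic cohort dataset
#'
#' Windows are peak-centered: the key event of each activity sits at the
#' middle timestep (index `floor(n_timesteps / 2)`, 0-based) unless jitter is
#' configured. Gravity (about 9.81 m/s^2) is retained on the rotated gravity
#' axis since the modelling pipeline consumes raw, unfiltered windows.
#' Beyond the per-subject signature, every `(subject, activity)` pair gets a
#' consistent performance style (amplitude, harmonic content, secondary-axis
#' phases, event-envelope width) shared by all of that pair's windows: the
#' generative stand-in for "how this person performs this activity", which a
#' subject-dependent model can memorize but a subject-independent one never
#' observes. Style deviations also scale linearly with
#' `signature_strength`. Deterministic for a fixed `(config, seed)`; draw
#' order is signatures first, then per-pair styles, then windows, grouped by
#' activity (vocabulary order) and subject (roster order).
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return a [har_dataset()].
#' @export
generate_dataset <- function(config, seed) {
  if (length(config$activities) == 0) {
    stop("activity list must be non-empty", call. = FALSE)
  }
  with_preserved_rng({
    set.seed(as.integer(seed))
    sigs <- lapply(seq_len(config$n_subjects), draw_signature,
                   s = config$signature_strength)
    vocab <- names(config$activities)
    styles <- list()
    for (act in vocab) {
      for (subj in seq_len(config$n_subjects)) {
        styles[[paste(act, subj)]] <- draw_style(config$signature_strength)
      }
    }
    chunks <- list(); meta <- list()
    for (act in vocab) {
      tpl <- config$activities[[act]]
      for (subj in seq_len(config$n_subjects)) {
        if (is_dropped(config$dropout_pairs, subj, act)) next
        k <- resolve_count(config$windows_per_subject_activity, subj, act)
        if (k <= 0L) next
        for (w in seq_len(k)) {
          chunks[[length(chunks) + 1L]] <-
            synth_window_values(tpl, sigs[[subj]], config,
                                styles[[paste(act, subj)]])
          meta[[length(meta) + 1L]] <- data.frame(
            activity = act, subject = subj,
            trial = ((w - 1L) %% 6L) + 1L, stringsAsFactors = FALSE)
        }
      }
    }
    n <- length(chunks)
    values <- array(0, dim = c(n, config$n_timesteps, 3L))
    for (i in seq_len(n)) values[i, , ] <- chunks[[i]]
    har_dataset(values, do.call(rbind, meta),
                activity_vocabulary = vocab,
                subject_roster = seq_len(config$n_subjects),
                sample_rate_hz = config$sample_rate_hz)
  })
}

#' Specification of injectable discontinuity artifacts
#'
#' Describes physically implausible one-sample level shifts such as those
#' produced by merging segments of different trials during windowing: the
#' signal jumps by `jump_magnitude` between two consecutive samples and, in
#' `"sustained-step"` mode, stays at the shifted level until the window end.
#'
#' @param target_activities labels receiving artifacts.
#' @param probability_per_window probability each target-class window gets
#'   one artifact.
#' @param jump_magnitude size of the one-sample difference, m/s^2.
#' @param affected_axes axis indices modified (all at the same timestep).
#' @param mode `"sustained-step"` (default, a level shift persisting to the
#'   window end) or `"single-sample-spike"`.
#' @param position_granularity `"window"` draws an independent uniform
#'   position for every window; `"subject-activity"` draws one uniform
#'   position per (subject, activity) pair and reuses it for all of that
#'   pair's windows, emulating recording-level faults (e.g. merged trial
#'   segments) whose traces recur across the overlapping windows cut from
#'   the same recording.
#' @return an object of class `bias_injection_spec`.
#' @export
bias_injection_spec <- function(target_activities,
                                probability_per_window = 1,
                                jump_magnitude = 11,
                                affected_axes = c(2L, 3L),
                                mode = c("sustained-step", "single-sample-spike"),
                                position_granularity = c("window", "subject-activity")) {
  mode <- match.arg(mode)
  position_granularity <- match.arg(position_granularity)
  if (jump_magnitude <= 0) stop("jump_magnitude must be positive", call. = FALSE)
  if (probability_per_window < 0 || probability_per_window > 1) {
    stop("probability_per_window must lie in [0, 1]", call. = FALSE)
  }
  structure(list(target_activities = as.character(target_activities),
                 probability_per_window = probability_per_window,
                 jump_magnitude = jump_magnitude,
                 affected_axes = as.integer(affected_axes),
                 mode = mode,
                 position_granularity = position_granularity),
            class = "bias_injection_spec")
}

#' Plant discontinuity artifacts in a dataset
#'
#' Returns a modified copy plus the ground-truth plant locations. The jump
#' position is uniform over interior timesteps; the one-sample difference at
#' the planted timestep equals exactly `+- jump_magnitude` on each affected
#' axis (the suffix is re-based relative to the preceding sample, emulating a
#' segment from a different trial being appended at a foreign level).
#' Non-target activities are never modified. Deterministic per seed.
#'
#' @param dataset a `har_dataset`.
#' @param spec a [bias_injection_spec()].
#' @param seed integer seed.
#' @return list with elements `dataset` (modified copy) and `plants`
#'   (data frame: `window`, `timestep` (0-based jump position), `axis`,
#'   `delta` (signed step size)).
#' @export
inject_discontinuities <- function(dataset, spec, seed) {
  missing_act <- setdiff(spec$target_activities, dataset$activity_vocabulary)
  if (length(missing_act)) {
    stop("target activities absent from vocabulary: ",
         paste(missing_act, collapse = ", "), call. = FALSE)
  }
  n <- n_windows(dataset)
  N <- dataset$n_timesteps
  plants <- list()
  with_preserved_rng({
    set.seed(as.integer(seed))
    pair_pos <- NULL
    if (spec$position_granularity == "subject-activity") {
      pair_pos <- list()
      for (act in spec$target_activities) {
        for (subj in dataset$subject_roster) {
          pair_pos[[paste(act, subj)]] <- sample(seq.int(1L, N - 3L), 1L)
        }
      }
    }
    for (i in seq_len(n)) {
      if (!(dataset$meta$activity[i] %in% spec$target_activities)) next
      if (spec$probability_per_window < 1 &&
          stats::runif(1) >= spec$probability_per_window) next
      if (spec$probability_per_window == 0) next
      t0 <- if (!is.null(pair_pos)) {
        pair_pos[[paste(dataset$meta$activity[i], dataset$meta$subject[i])]]
      } else sample(seq.int(1L, N - 3L), 1L)      # 0-based interior timestep
      tR <- t0 + 1L                                # 1-based index of sample t0
      for (a in spec$affected_axes) {
        ## Jump toward the opposite side of the axis's range, as a segment
        ## recorded in a different device orientation would: the landing
        ## level stays physically plausible and only the one-sample edge is
        ## anomalous (e.g. a rise from about -10 to about +1).
        sgn <- if (dataset$values[i, tR, a] > 0) -1 else 1
        delta <- sgn * spec$jump_magnitude
        x <- dataset$values[i, , a]
        if (spec$mode == "sustained-step") {
          offset <- (x[tR] + delta) - x[tR + 1L]
          x[(tR + 1L):N] <- x[(tR + 1L):N] + offset
        } else {
          x[tR + 1L] <- x[tR] + delta
        }
        dataset$values[i, , a] <- x
        plants[[length(plants) + 1L]] <- data.frame(
          window = i, timestep = t0, axis = a, delta = delta)
      }
    }
  })
  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(window = integer(), timestep = integer(),
               axis = integer(), delta = numeric())
  list(dataset = dataset, plants = plants)
}
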