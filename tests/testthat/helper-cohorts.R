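# Shared fixtures: small synthetic cohorts and compact networks. Trained
# models are memoised in `.model_cache` so property tests can reuse them
# instead of re-training.

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, force(expr), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

# Two well-separated periodic classes; linearly separable by construction.
toy_templates <- function() {
  list(activity_template("slow", "periodic", 1.0, 3, 0.5),
       activity_template("fast", "periodic", 3.0, 3, 0.5))
}

toy_dataset <- function(seed = 7, n_subjects = 4, wpp = 10, noise_sd = 0.2,
                        strength = 0) {
  generate_dataset(
    synth_config(n_subjects = n_subjects, activities = toy_templates(),
                 windows_per_subject_activity = wpp,
                 signature_strength = strength, noise_sd = noise_sd,
                 dropout_pairs = NULL),
    seed)
}

tiny_spec <- function(n_classes, n_filters = 8) {
  cnn_spec(list(conv_block(2, n_filters, 8, TRUE),
                conv_block(2, n_filters, 8, FALSE)),
           n_classes = n_classes, dropout_rate = 0.25)
}

# A trained two-class toy model, shared across gradient/saliency tests.
toy_model <- function() {
  cached("toy_model", {
    ds <- toy_dataset()
    plan <- split_subject_dependent(ds, 0.3, seed = 42)
    train_model(tiny_spec(2), ds, plan,
                train_config(epochs = 5, batch_size = 16, seed = 1))
  })
}

# Gap cohort: 2 distinct classes plus 4 classes sharing one quiet template,
# whose identity is carried by per-(subject, activity) performance styles.
# Subject-dependent models can memorize the styles; subject-independent
# models never observe the held-out subjects' styles.
gap_templates <- function() {
  list(
    activity_template("Walking",  "periodic", 0.8, 3.0, 0.5),
    activity_template("Running",  "periodic", 3.2, 3.0, 0.35),
    activity_template("StandingUpFS", "periodic", 2.0, 1.2, 0.6),
    activity_template("StandingUpFL", "periodic", 2.0, 1.2, 0.6),
    activity_template("SittingDown",  "periodic", 2.0, 1.2, 0.6),
    activity_template("LyingDownFS",  "periodic", 2.0, 1.2, 0.6))
}

gap_cohort <- function(seed, strength = 0.8) {
  generate_dataset(
    synth_config(n_subjects = 6, activities = gap_templates(),
                 windows_per_subject_activity = 8,
                 signature_strength = strength, noise_sd = 0.2,
                 dropout_pairs = NULL),
    seed)
}

gap_spec <- function() {
  cnn_spec(list(conv_block(2, 16, 8, TRUE), conv_block(2, 16, 8, FALSE)),
           n_classes = 6, dropout_rate = 0.2)
}

# SD and SI models on the clean gap cohort (reused by the audit null test
# and the SD-vs-SI acceptance check).
gap_models <- function(seed) {
  cached(paste0("gap_models_", seed), {
    ds <- gap_cohort(seed)
    sd_plan <- split_subject_dependent(ds, 0.3, seed = 42)
    si_plan <- split_subject_independent(ds, 1:2)
    cfg <- train_config(epochs = 15, batch_size = 64, seed = 1,
                        standardize = TRUE)
    list(dataset = ds,
         plans = list(sd = sd_plan, si = si_plan),
         models = list(sd = train_model(gap_spec(), ds, sd_plan, cfg),
                       si = train_model(gap_spec(), ds, si_plan, cfg)))
  })
}

# Audit cohort for the bias-localization study: 4 distinct periodic classes
# plus 4 quiet classes sharing one template (rare-class analogues); the
# audit plants sustained-step artifacts in the quiet quartet.
audit_templates <- function() {
  list(
    activity_template("Walking",  "periodic", 0.8, 3.0, 0.5),
    activity_template("GoingUpS", "periodic", 1.3, 3.0, 0.6),
    activity_template("Running",  "periodic", 3.2, 3.0, 0.35),
    activity_template("Jumping",  "periodic", 4.2, 3.0, 0.4),
    activity_template("StandingUpFS", "periodic", 2.0, 1.2, 0.6),
    activity_template("StandingUpFL", "periodic", 2.0, 1.2, 0.6),
    activity_template("SittingDown",  "periodic", 2.0, 1.2, 0.6),
    activity_template("LyingDownFS",  "periodic", 2.0, 1.2, 0.6))
}

audit_target_classes <- function() {
  c("StandingUpFS", "StandingUpFL", "SittingDown", "LyingDownFS")
}

audit_cohort <- function(seed) {
  wins <- c(Walking = 12, GoingUpS = 12, Running = 12, Jumping = 12,
            StandingUpFS = 20, StandingUpFL = 20, SittingDown = 20,
            LyingDownFS = 20)
  generate_dataset(
    synth_config(n_subjects = 8, activities = audit_templates(),
                 windows_per_subject_activity = wins,
                 signature_strength = 0.8, noise_sd = 0.2,
                 dropout_pairs = NULL),
    seed)
}

audit_spec <- function() {
  cnn_spec(list(conv_block(2, 24, 8, TRUE), conv_block(2, 24, 8, FALSE)),
           n_classes = 8, dropout_rate = 0.2)
}

# Full audit pipeline for one seed: inject, split, train SD + SI, audit.
audit_run <- function(seed) {
  cached(paste0("audit_run_", seed), {
    ds <- audit_cohort(seed)
    inj <- inject_discontinuities(
      ds,
      bias_injection_spec(audit_target_classes(),
                          probability_per_window = 0.8,
                          jump_magnitude = 11, affected_axes = c(2L, 3L)),
      seed + 100)
    ds2 <- inj$dataset
    plans <- list(sd = split_subject_dependent(ds2, 0.3, seed = 42),
                  si = split_subject_independent(ds2, 1:2))
    cfg <- train_config(epochs = 40, batch_size = 64, seed = 1,
                        standardize = TRUE)
    models <- list(sd = train_model(audit_spec(), ds2, plans$sd, cfg),
                   si = train_model(audit_spec(), ds2, plans$si, cfg))
    report <- run_audit(ds2, models, plans, audit_config(seed = seed))
    list(dataset = ds2, plants = inj$plants, plans = plans,
         models = models, report = report)
  })
}
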