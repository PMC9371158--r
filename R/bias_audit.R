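## Audit procedures built on the saliency maps: importance extent across
## validation strategies, discontinuity detection with heatmap
## co-localization, HAR-vs-BUI performance correlation, and per-class
## SD-SI gap flags.

#' Fraction of a window the model considers important
#'
#' Formalizes "how much of the signal the model looks at" as the fraction of
#' timesteps whose heatmap value meets the threshold.
#'
#' @param heatmap a `heatmap` or numeric vector in `[0, 1]`.
#' @param tau threshold in `[0, 1]` (default 0.7).
#' @return real in `[0, 1]`.
#' @export
importance_extent <- function(heatmap, tau = 0.7) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  v <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  mean(v >= tau)
}

#' Detect abrupt one-sample discontinuities in a window
#'
#' Flags every `(timestep, axis)` whose one-sample difference exceeds
#' `jump_threshold` in magnitude. At 50 Hz such a jump corresponds to a
#' physically implausible level change within 0.02 s. The default threshold
#' of 10 m/s^2 sits above the steepest one-sample change smooth human motion
#' produces at this rate, while typical windowing artifacts (level shifts of
#' about 11-12 m/s^2) exceed it.
#'
#' @param window a `signal_window` or `timesteps x axes` matrix.
#' @param jump_threshold minimum jump magnitude, m/s^2 (default 10).
#' @param sample_rate_hz sampling rate; taken from the window when available.
#' @return data frame of events: `timestep` (0-based index `t` of the jump
#'   between samples `t` and `t+1`), `axis`, `delta` (signed difference),
#'   `elapsed` (seconds between the two samples).
#' @export
detect_discontinuities <- function(window, jump_threshold = 10,
                                   sample_rate_hz = NULL) {
  if (inherits(window, "signal_window")) {
    if (is.null(sample_rate_hz)) sample_rate_hz <- window$sample_rate_hz
    values <- window$values
  } else {
    values <- as.matrix(window)
    if (is.null(sample_rate_hz)) sample_rate_hz <- 50
  }
  out <- list()
  for (a in seq_len(ncol(values))) {
    d <- diff(values[, a])
    hit <- which(abs(d) > jump_threshold)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        timestep = hit - 1L, axis = a, delta = d[hit],
        elapsed = 1 / sample_rate_hz)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(timestep = integer(), axis = integer(), delta = numeric(),
               elapsed = numeric())
}

#' Co-localization of heatmap importance with discontinuity events
#'
#' Builds a halo of `[t - w, t + w + 1]` timesteps around each event (the
#' two samples forming the jump plus `w` on each side, clipped to the
#' window) and measures which share of the super-threshold heatmap timesteps
#' falls inside it. `chance` is the halo's coverage fraction, so
#' `enrichment = score / chance` is 1 in expectation for unlocalized
#' importance. Undefined (flagged, not thrown) when there are no events or
#' no super-threshold timesteps.
#'
#' @param heatmap a `heatmap` or numeric vector in `[0, 1]`.
#' @param events event data frame from [detect_discontinuities()].
#' @param tau heatmap threshold (default 0.7).
#' @param halo_w halo half-width in timesteps (default 2).
#' @return list of class `colocalization_result`: `defined`, `score`,
#'   `chance`, `enrichment`, `n_events`.
#' @export
colocalization <- function(heatmap, events, tau = 0.7, halo_w = 2L) {
  v <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  N <- length(v)
  super <- which(v >= tau) - 1L                    # 0-based
  undefined <- structure(list(defined = FALSE, score = NA_real_,
                              chance = NA_real_, enrichment = NA_real_,
                              n_events = nrow(events)),
                         class = "colocalization_result")
  if (nrow(events) == 0 || length(super) == 0) return(undefined)
  halo <- unique(unlist(lapply(events$timestep, function(t)
    max(0L, t - halo_w):min(N - 1L, t + halo_w + 1L))))
  score <- mean(super %in% halo)
  chance <- length(halo) / N
  structure(list(defined = TRUE, score = score, chance = chance,
                 enrichment = score / chance, n_events = nrow(events)),
            class = "colocalization_result")
}

#' Pearson correlation with noncorrelation p-value
#'
#' Sample Pearson coefficient between paired per-activity scores, with the
#' two-sided p-value of the noncorrelation test based on
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (as computed by [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors (`n >= 3`), paired by activity.
#' @return list of class `correlation_result`: `r`, `p`, `n`, `defined`.
#' @export
correlate_performance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired scores", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$defined) cat(sprintf("Pearson r = %.3f, p = %.4f (n = %d)\n",
                             x$r, x$p, x$n))
  else cat("correlation undefined (zero variance)\n")
  invisible(x)
}

#' Audit configuration
#'
#' @param tau heatmap threshold for extent and co-localization (default 0.7).
#' @param halo_w event halo half-width, timesteps (default 2).
#' @param jump_threshold discontinuity threshold, m/s^2 (default 10).
#' @param gap_threshold SD-SI per-class recall gap above which a class with
#'   physical evidence is flagged (default 0.20).
#' @param windows_per_class validation windows sampled per class for heatmap
#'   analyses (default 10).
#' @param corr_metric `"macro_f1"` or `"accuracy"` pairing for the HAR-BUI
#'   correlation.
#' @param seed seed for the window sampling.
#' @return an `audit_config` list.
#' @export
audit_config <- function(tau = 0.7, halo_w = 2L, jump_threshold = 10,
                         gap_threshold = 0.20, windows_per_class = 10L,
                         corr_metric = c("macro_f1", "accuracy"), seed = 1L) {
  structure(list(tau = tau, halo_w = as.integer(halo_w),
                 jump_threshold = jump_threshold,
                 gap_threshold = gap_threshold,
                 windows_per_class = as.integer(windows_per_class),
                 corr_metric = match.arg(corr_metric),
                 seed = as.integer(seed)),
            class = "audit_config")
}

sample_val_windows <- function(dataset, plan, per_class) {
  idx <- plan$val_indices
  cls <- dataset$meta$activity[idx]
  unlist(lapply(split(idx, cls), function(ii) {
    if (length(ii) <= per_class) ii else ii[sample.int(length(ii), per_class)]
  }), use.names = FALSE)
}

extent_for_model <- function(model, dataset, idx, tau) {
  do.call(rbind, lapply(idx, function(i) {
    hm <- explain(model, get_window(dataset, i))
    data.frame(window = i, class = dataset$meta$activity[i],
               extent = importance_extent(hm, tau))
  }))
}

#' Run the full bias audit
#'
#' Combines the audit procedures over a set of trained models:
#' importance-extent summaries per model tag, a discontinuity scan with
#' heatmap co-localization of the subject-dependent model, per-class SD-SI
#' recall gaps, the per-activity HAR-vs-BUI performance correlation (when
#' BUI models are supplied), and bias flags for classes where a large gap
#' coincides with physical discontinuity evidence.
#'
#' @param dataset a `har_dataset`.
#' @param models named list with elements `sd` and `si` (trained `har_cnn`)
#'   and optionally `bui` (named list of per-activity `har_cnn`).
#' @param plans named list with the matching `sd`, `si` and optional `bui`
#'   split plans.
#' @param config an [audit_config()].
#' @return an object of class `audit_report`.
#' @export
run_audit <- function(dataset, models, plans, config = audit_config()) {
  for (tag in c("sd", "si")) {
    if (is.null(models[[tag]]) || is.null(plans[[tag]])) {
      stop("missing model or plan for required tag: ", tag, call. = FALSE)
    }
  }
  with_preserved_rng({
    set.seed(config$seed)

    ## --- importance extents per model tag -------------------------------
    idx_sd <- sample_val_windows(dataset, plans$sd, config$windows_per_class)
    idx_si <- sample_val_windows(dataset, plans$si, config$windows_per_class)
    extents <- rbind(
      cbind(tag = "sd", extent_for_model(models$sd, dataset, idx_sd, config$tau)),
      cbind(tag = "si", extent_for_model(models$si, dataset, idx_si, config$tau))
    )
    if (!is.null(models$bui)) {
      for (act in names(models$bui)) {
        idx_b <- sample_val_windows(dataset, plans$bui[[act]],
                                    config$windows_per_class)
        extents <- rbind(extents,
          cbind(tag = paste0("bui:", act),
                extent_for_model(models$bui[[act]], dataset, idx_b, config$tau)))
      }
    }
    extents$group <- sub(":.*", "", extents$tag)
    extent_by_tag <- do.call(rbind, lapply(split(extents, extents$group),
      function(d) data.frame(group = d$group[1], mean = mean(d$extent),
                             sd = stats::sd(d$extent), n = nrow(d))))

    ## --- discontinuity scan over the whole dataset ----------------------
    events <- list()
    for (i in seq_len(n_windows(dataset))) {
      ev <- detect_discontinuities(get_window(dataset, i),
                                   config$jump_threshold)
      if (nrow(ev)) {
        ev$window <- i
        ev$class <- dataset$meta$activity[i]
        events[[length(events) + 1L]] <- ev
      }
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(timestep = integer(), axis = integer(), delta = numeric(),
                 elapsed = numeric(), window = integer(), class = character())

    ## --- co-localization of the SD model's saliency with events --------
    coloc <- list()
    for (i in intersect(idx_sd, unique(events$window))) {
      hm <- explain(models$sd, get_window(dataset, i))
      cl <- colocalization(hm, events[events$window == i, , drop = FALSE],
                           tau = config$tau, halo_w = config$halo_w)
      if (cl$defined) {
        coloc[[length(coloc) + 1L]] <- data.frame(
          window = i, class = dataset$meta$activity[i],
          score = cl$score, chance = cl$chance, enrichment = cl$enrichment)
      }
    }
    coloc <- if (length(coloc)) do.call(rbind, coloc) else
      data.frame(window = integer(), class = character(), score = numeric(),
                 chance = numeric(), enrichment = numeric())

    ## --- per-class SD-SI recall gaps ------------------------------------
    rep_sd <- evaluate_model(models$sd, dataset, plans$sd)
    rep_si <- evaluate_model(models$si, dataset, plans$si)
    pc_sd <- rep_sd$per_class; pc_si <- rep_si$per_class
    gaps <- data.frame(
      class = pc_sd$class,
      recall_sd = pc_sd$recall,
      recall_si = pc_si$recall[match(pc_sd$class, pc_si$class)])
    gaps$gap <- gaps$recall_sd - gaps$recall_si

    ## --- HAR-BUI correlation --------------------------------------------
    correlation <- NULL
    bui_scores <- NULL
    if (!is.null(models$bui) && length(models$bui) >= 3) {
      acts <- names(models$bui)
      bui_val <- vapply(acts, function(act) {
        r <- evaluate_model(models$bui[[act]], dataset, plans$bui[[act]])
        if (config$corr_metric == "accuracy") r$accuracy else r$macro$f1
      }, numeric(1))
      har_val <- if (config$corr_metric == "accuracy") {
        pc_sd$recall[match(acts, pc_sd$class)]
      } else {
        pc_sd$f1[match(acts, pc_sd$class)]
      }
      bui_scores <- data.frame(class = acts, har_sd = har_val, bui = bui_val)
      correlation <- correlate_performance(har_val, bui_val)
    }

    ## --- flags: large gap AND physical evidence -------------------------
    ev_classes <- unique(events$class)
    flagged <- gaps$class[!is.na(gaps$gap) &
                            gaps$gap > config$gap_threshold &
                            gaps$class %in% ev_classes]

    structure(list(
      extents = extents, extent_by_tag = extent_by_tag,
      events = events, colocalization = coloc,
      gaps = gaps, correlation = correlation, bui_scores = bui_scores,
      flagged = as.character(flagged), config = config,
      metrics = list(sd = rep_sd, si = rep_si)
    ), class = "audit_report")
  })
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  cat("mean importance extent by strategy:\n")
  print(x$extent_by_tag, row.names = FALSE)
  cat(sprintf("%d discontinuity event(s) in %d window(s)\n",
              nrow(x$events), length(unique(x$events$window))))
  if (nrow(x$colocalization)) {
    cat(sprintf("mean co-localization enrichment: %.2f x chance\n",
                mean(x$colocalization$enrichment)))
  }
  if (!is.null(x$correlation)) print(x$correlation)
  cat("flagged classes:",
      if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Serialize an audit report to JSON
#' @param report an `audit_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(report, path) {
  obj <- list(
    extents = report$extents, extent_by_tag = report$extent_by_tag,
    events = report$events, colocalization = report$colocalization,
    gaps = report$gaps,
    correlation = if (!is.null(report$correlation))
      report$correlation[c("r", "p", "n", "defined")],
    bui_scores = report$bui_scores,
    flagged = report$flagged,
    config = unclass(report$config)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read an audit report written by [write_audit_report()]
#' @param path JSON file.
#' @return an `audit_report` (without the model evaluation objects).
#' @export
read_audit_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$flagged <- as.character(obj$flagged)
  if (!is.null(obj$correlation)) {
    obj$correlation <- structure(as.list(obj$correlation),
                                 class = "correlation_result")
  }
  obj$config <- structure(as.list(obj$config), class = "audit_config")
  structure(obj, class = "audit_report")
}
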