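## 1D grad-CAM: time-only gradient pooling, no-ReLU weighted combination,
## min-max normalization to [0, 1], nearest-neighbour upsampling to the
## input length, and threshold masks.

#' Importance weights by global average pooling of the gradient
#'
#' `alpha_k = (1/Z) * sum_i gradient[i, k]`, where `Z` is the number of
#' temporal positions of the designated layer. Pooling runs over time only
#' (the one-dimensional reading of the original two-dimensional rule).
#'
#' @param gradient `positions x maps` matrix of class-score gradients.
#' @return numeric vector of length `n_maps`.
#' @export
importance_weights <- function(gradient) {
  gradient <- as.matrix(gradient)
  if (length(gradient) == 0) stop("gradient matrix is empty", call. = FALSE)
  colMeans(gradient)
}

#' Weighted combination of feature maps
#'
#' `out_i = sum_k alpha_k * A[i, k]`. Negative values are preserved by
#' default; the original formulation's ReLU is available behind a flag.
#'
#' @param weights numeric vector (one weight per map).
#' @param maps `positions x maps` feature-map matrix.
#' @param relu apply ReLU to the combination (default `FALSE`).
#' @return numeric vector of length `positions`.
#' @export
combine_maps <- function(weights, maps, relu = FALSE) {
  maps <- as.matrix(maps)
  if (length(weights) != ncol(maps)) {
    stop(sprintf("got %d weights for %d maps", length(weights), ncol(maps)),
         call. = FALSE)
  }
  out <- drop(maps %*% weights)
  if (relu) out <- pmax(out, 0)
  out
}

#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)`. A constant input (max equals min) normalizes
#' to all zeros so that "no signal" reads as "no importance".
#'
#' @param raw numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_heatmap <- function(raw) {
  if (length(raw) == 0) stop("cannot normalize an empty vector", call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(0, length(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Nearest-neighbour upsampling
#'
#' Piecewise-constant stretch: `out[j] = values[floor(j * L / N)]` for
#' 0-based `j`, so the output contains only values present in the input and
#' shows the blocky banding characteristic of nearest-neighbour
#' interpolation.
#'
#' @param values numeric vector of length `L`.
#' @param target_length output length `N`.
#' @return numeric vector of length `N`.
#' @export
upsample_nearest <- function(values, target_length) {
  L <- length(values)
  N <- as.integer(target_length)
  if (L < 1 || N < 1) stop("lengths must be at least 1", call. = FALSE)
  j <- seq_len(N) - 1L
  values[floor(j * L / N) + 1L]
}

#' Grad-CAM heatmap for one window
#'
#' Composes the four stages: backpropagated gradients at the last
#' convolutional layer, global average pooling over time, no-ReLU weighted
#' combination of the feature maps, min-max normalization to `[0, 1]`, and
#' nearest-neighbour upsampling to the input length. Normalizing before
#' upsampling is equivalent to the reverse order here because
#' nearest-neighbour interpolation introduces no new values.
#'
#' @param model a trained `har_cnn`.
#' @param window a `signal_window` or `timesteps x axes` matrix.
#' @param class_index 1-based target class; defaults to the model's
#'   prediction for the window.
#' @param relu apply ReLU to the map combination (default `FALSE`).
#' @param post_softmax differentiate the softmax output instead of the
#'   pre-softmax score.
#' @return an object of class `heatmap`: list with `values` (length equal to
#'   the input window, in `[0, 1]`), `class_index`, `source_resolution`.
#' @export
explain <- function(model, window, class_index = NULL, relu = FALSE,
                    post_softmax = FALSE) {
  if (is.null(class_index)) {
    class_index <- predict(model, window)$class[1]
  }
  ag <- activations_and_gradient(model, window, class_index,
                                 post_softmax = post_softmax)
  raw <- combine_maps(importance_weights(ag$gradient), ag$feature_maps,
                      relu = relu)
  values <- upsample_nearest(normalize_heatmap(raw), model$spec$input_length)
  structure(list(values = values, class_index = as.integer(class_index),
                 source_resolution = nrow(ag$feature_maps)),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> length %d (source resolution %d), class %d\n",
              length(x$values), x$source_resolution, x$class_index))
  invisible(x)
}

#' Threshold a heatmap into a boolean importance mask
#'
#' `mask[i]` is `TRUE` where the heatmap value is at least `tau` (inclusive
#' boundary). The default threshold 0.7 matches the convention used when
#' reading "regions of greater importance" off the heatmaps.
#'
#' @param heatmap a `heatmap` or numeric vector in `[0, 1]`.
#' @param tau threshold in `[0, 1]` (default 0.7).
#' @return logical vector of the heatmap's length.
#' @export
threshold_mask <- function(heatmap, tau = 0.7) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  v <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  v >= tau
}

mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Plot a window with its heatmap overlay
#'
#' Draws the axes of the window with the heatmap as background shading;
#' when `tau` is given only super-threshold regions are shaded, one band per
#' maximal run of the mask. The piecewise-constant banding of the
#' nearest-neighbour upsampling is visible as constant-colour blocks.
#'
#' @param window a `signal_window`.
#' @param heatmap a `heatmap` of the same length.
#' @param tau optional threshold; `NULL` shades by continuous importance.
#' @param path output file (`.png` or `.svg`).
#' @return `path`, invisibly.
#' @export
render_overlay <- function(window, heatmap, tau = NULL, path = "overlay.png") {
  v <- heatmap$values
  if (length(v) != nrow(window$values)) {
    stop(sprintf("heatmap length %d does not match window length %d",
                 length(v), nrow(window$values)), call. = FALSE)
  }
  n <- nrow(window$values)
  tt <- (seq_len(n) - 1) / window$sample_rate_hz
  df <- data.frame(
    time = rep(tt, ncol(window$values)),
    value = as.vector(window$values),
    axis = factor(rep(paste0("axis ", seq_len(ncol(window$values))),
                      each = n))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (is.null(tau)) {
    shade <- data.frame(xmin = tt - 0.5 / window$sample_rate_hz,
                        xmax = tt + 0.5 / window$sample_rate_hz,
                        importance = v)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, alpha = .data$importance),
      fill = "firebrick", inherit.aes = FALSE) +
      ggplot2::scale_alpha_identity()
  } else {
    runs <- mask_runs(threshold_mask(heatmap, tau))
    if (nrow(runs) > 0) {
      shade <- data.frame(xmin = tt[runs$start] - 0.5 / window$sample_rate_hz,
                          xmax = tt[runs$end] + 0.5 / window$sample_rate_hz)
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        fill = "firebrick", alpha = 0.35, inherit.aes = FALSE)
    }
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = expression(acceleration ~ (m/s^2)),
                  title = sprintf("grad-CAM, class %d (resolution %d)",
                                  heatmap$class_index,
                                  heatmap$source_resolution)) +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 120)
  invisible(path)
}

#' Export a heatmap as TSV (timestep, value)
#' @param heatmap a `heatmap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path) {
  utils::write.table(
    data.frame(timestep = seq_along(heatmap$values) - 1L,
               value = heatmap$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
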