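#' Fluorescence image stack container
#'
#' A stack of grayscale frames (camera counts) with a frame interval and a
#' count of pre-stimulus baseline frames.
#'
#' @param frames `h x w x t` array of non-negative intensities.
#' @param frame_dt Frame interval in seconds.
#' @param pre_frames Number of leading baseline frames (>= 1).
#' @return An `image_stack` list.
#' @export
image_stack <- function(frames, frame_dt, pre_frames) {
  if (length(dim(frames)) != 3) stop("`frames` must be h x w x t", call. = FALSE)
  if (frame_dt <= 0 || pre_frames < 1) {
    stop("`frame_dt` must be > 0 and `pre_frames` >= 1", call. = FALSE)
  }
  structure(list(frames = frames, frame_dt = frame_dt,
                 pre_frames = as.integer(pre_frames)),
            class = "image_stack")
}

#' Read / write a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @export
read_stack_tiff <- function(path, frame_dt, pre_frames) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- simplify2array(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  }))
  image_stack(frames, frame_dt, pre_frames)
}

#' @rdname read_stack_tiff
#' @param stack An `image_stack`.
#' @param scale Divisor mapping counts into the TIFF [0, 1] range.
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack$frames)) {
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k) {
    pmin(pmax(stack$frames[, , k] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Delta-F image of a response window
#'
#' Pixelwise mean over the response frames minus the pixelwise mean over
#' the baseline (pre-stimulus) frames. Response and baseline windows must
#' not overlap.
#'
#' @param stack An [image_stack()].
#' @param response_frames Integer frame indices of the response window.
#' @param baseline_frames Frame indices of the baseline; defaults to the
#'   stack's `pre_frames` leading frames.
#' @return A numeric `h x w` matrix (counts).
#' @export
delta_f_image <- function(stack, response_frames,
                          baseline_frames = seq_len(stack$pre_frames)) {
  stopifnot(inherits(stack, "image_stack"))
  n_t <- dim(stack$frames)[3]
  if (any(response_frames < 1 | response_frames > n_t) ||
      any(baseline_frames < 1 | baseline_frames > n_t)) {
    stop("frame windows must lie within the stack", call. = FALSE)
  }
  if (length(intersect(response_frames, baseline_frames))) {
    stop("response window must not overlap the baseline window", call. = FALSE)
  }
  resp <- apply(stack$frames[, , response_frames, drop = FALSE], c(1, 2), mean)
  base <- apply(stack$frames[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  resp - base
}

#' Histogram-based ROI segmentation of a delta-F image
#'
#' Semi-automatic segmentation of the responding terminal: the delta-F
#' image is liberally blurred (Gaussian, `sigma_px` = 3 by default), a
#' global threshold is taken from the image histogram (Otsu's criterion by
#' default, or a percentile), the connected component containing
#' `seed_point` (or the largest, if no seed is given) is kept, and holes
#' are filled. The result is an outer bound for the terminal's extent.
#'
#' @param dF A numeric matrix from [delta_f_image()].
#' @param sigma_px Gaussian blur sigma in pixels.
#' @param seed_point Optional `(row, col)` inside the wanted component.
#' @param method `"otsu"` or `"percentile"`.
#' @param percentile Threshold quantile for `method = "percentile"`.
#' @return A `roi_mask`: list with `mask` (logical matrix, `NULL` if the
#'   foreground is empty), `area` (px), `ok`, and `provenance`.
#' @export
segment_roi <- function(dF, sigma_px = 3, seed_point = NULL,
                        method = c("otsu", "percentile"), percentile = 0.99) {
  method <- match.arg(method)
  if (nrow(dF) < 16 || ncol(dF) < 16) {
    stop("delta-F image must be at least 16 x 16 px", call. = FALSE)
  }
  blurred <- EBImage::gblur(dF, sigma = sigma_px)
  rng <- range(blurred)
  if (diff(rng) <= 0) {
    return(structure(list(mask = NULL, area = 0L, ok = FALSE,
                          provenance = list(filter_sigma = sigma_px,
                                            threshold = NA_real_,
                                            seed_point = seed_point,
                                            method = method)),
                     class = "roi_mask"))
  }
  norm <- (blurred - rng[1]) / diff(rng)
  thr_norm <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    stats::quantile(norm, percentile)
  }
  fg <- norm > thr_norm
  if (!any(fg)) {
    return(structure(list(mask = NULL, area = 0L, ok = FALSE,
                          provenance = list(filter_sigma = sigma_px,
                                            threshold = rng[1] + thr_norm * diff(rng),
                                            seed_point = seed_point,
                                            method = method)),
                     class = "roi_mask"))
  }
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- as.matrix(EBImage::imageData(labels))
  pick <- if (!is.null(seed_point) && lab[seed_point[1], seed_point[2]] > 0) {
    lab[seed_point[1], seed_point[2]]
  } else {
    tab <- tabulate(lab[lab > 0])
    which.max(tab)
  }
  comp <- lab == pick
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  mask <- as.matrix(EBImage::imageData(filled)) > 0
  structure(list(mask = mask, area = sum(mask), ok = TRUE,
                 provenance = list(filter_sigma = sigma_px,
                                   threshold = rng[1] + thr_norm * diff(rng),
                                   seed_point = seed_point, method = method)),
            class = "roi_mask")
}

#' Extract the ROI delta-F/F time course from a stack
#'
#' Per frame, the mean intensity over the mask; F0 is the mean of that
#' trace over the pre-stimulus frames; the returned trace is (F - F0)/F0.
#'
#' @param stack An [image_stack()].
#' @param mask A logical matrix or a `roi_mask` from [segment_roi()].
#' @return A `glu_ts` in delta-F/F units (`dt` = frame interval).
#' @export
extract_trace <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"))
  if (inherits(mask, "roi_mask")) {
    if (!isTRUE(mask$ok)) stop("ROI mask is flagged empty", call. = FALSE)
    mask <- mask$mask
  }
  d <- dim(stack$frames)
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stop("`mask` must be a logical matrix matching the frame size", call. = FALSE)
  }
  idx <- which(mask)
  f <- vapply(seq_len(d[3]), function(k) mean(stack$frames[, , k][idx]),
              numeric(1))
  f0 <- mean(f[seq_len(stack$pre_frames)])
  if (f0 <= 0) stop("baseline fluorescence F0 must be positive", call. = FALSE)
  glu_ts((f - f0) / f0, dt = stack$frame_dt, t0 = 0, units = "dff",
         label = "ROI dF/F")
}

#' Per-pulse area under the delta-F/F curve
#'
#' For each stimulus of a train, integrates delta-F/F over
#' `[stimulus_i, stimulus_{i+1})` after subtracting the exponential
#' continuation of all preceding responses (the tail at the window start
#' decays with the reporter time constant, so partial overlap of
#' consecutive responses is corrected in closed form). The final window
#' spans one mean inter-stimulus interval.
#'
#' @param dff A delta-F/F `glu_ts`.
#' @param protocol A [stim_protocol()] with ISI >= 2 frames.
#' @param tau Reporter decay constant (s); estimated from the post-train
#'   decay via [estimate_tau()] when `NULL`.
#' @param normalize Divide all AUCs by the first-pulse AUC.
#' @param tail_correct Apply the overlap correction (default TRUE).
#' @param method Integration rule: `"trapezoid"` (default) or `"sum"`
#'   (frame value times frame interval; exact for exposure-averaged data).
#' @return A tibble with one row per stimulus: `stimulus`, `auc` (units:
#'   delta-F/F times seconds, or dimensionless if normalized).
#' @export
per_pulse_auc <- function(dff, protocol, tau = NULL, normalize = FALSE,
                          tail_correct = TRUE,
                          method = c("trapezoid", "sum")) {
  stopifnot_ts(dff)
  stopifnot(inherits(protocol, "stim_protocol"))
  method <- match.arg(method)
  dt <- dff$dt
  isis <- diff(protocol$times)
  isi <- if (length(isis)) mean(isis) else 10 * dt
  if (isi < 2 * dt - 1e-12) {
    stop("inter-stimulus interval under 2 frames; use the deconvolution path",
         call. = FALSE)
  }
  if (is.null(tau)) {
    tau <- estimate_tau(
      dff, c(protocol$times[protocol$n] + 2 * dt,
             dff$t0 + (length(dff$values) - 1) * dt))$tau
  }
  v <- dff$values
  n <- length(v)
  frame_start <- dff$t0 + (seq_len(n) - 1) * dt
  bounds <- c(protocol$times, protocol$times[protocol$n] + isi)
  auc <- numeric(protocol$n)
  for (i in seq_len(protocol$n)) {
    win <- which(frame_start >= bounds[i] - 1e-12 &
                   frame_start < bounds[i + 1] - 1e-12)
    if (!length(win)) next
    seg <- v[win]
    if (tail_correct) {
      k_pre <- win[1] - 1L
      if (k_pre >= 1) {
        seg <- seg - v[k_pre] * exp(-(seq_along(win)) * dt / tau)
      }
    }
    auc[i] <- if (method == "trapezoid") trapz_sum(seg, dt) else sum(seg) * dt
  }
  if (normalize) {
    if (auc[1] == 0) stop("first-pulse AUC is zero; cannot normalize", call. = FALSE)
    auc <- auc / auc[1]
  }
  tibble::tibble(stimulus = seq_len(protocol$n), auc = auc)
}
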