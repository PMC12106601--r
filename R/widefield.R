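#' Construct a wide-field pixel movie
#'
#' @param frames numeric 3-D array `ny x nx x time` of fluorescence frames.
#' @param epochs tibble with one row per trial: `trial`, `condition`
#'   (id into `conditions`), `first_frame`, `onset_frame`, `last_frame`.
#'   Baseline frames are `first_frame .. onset_frame - 1`.
#' @param conditions condition table with at least `condition` and
#'   `modality` columns (see [stimulus_grid()]); must contain a blank
#'   condition.
#' @param fs frame rate in Hz (default 50).
#' @return object of class `xmodal_movie` (list: `frames`, `epochs`,
#'   `conditions`, `fs`).
#' @export
pixel_movie <- function(frames, epochs, conditions, fs = 50) {
  stopifnot(length(dim(frames)) == 3)
  epochs <- as_tibble(epochs)
  need <- c("trial", "condition", "first_frame", "onset_frame", "last_frame")
  stopifnot(all(need %in% names(epochs)))
  conditions <- as_tibble(conditions)
  blank_ids <- conditions$condition[conditions$modality == "blank"]
  if (!any(epochs$condition %in% blank_ids)) {
    stop("movie must contain at least one blank-condition trial")
  }
  if (max(epochs$last_frame) > dim(frames)[3] || min(epochs$first_frame) < 1) {
    stop("epoch frame ranges outside the movie")
  }
  structure(list(frames = frames, epochs = epochs, conditions = conditions,
                 fs = fs),
            class = "xmodal_movie")
}

#' Preprocess a wide-field movie
#'
#' Pixelwise zero-phase notch filtering (second-order Butterworth band-stop
#' centered at `f0` with width `fw`, applied forward and backward) followed
#' by discrete-wavelet-transform detrending ([dwt_detrend()], `levels`-level
#' decomposition with zeroed approximation coefficients) to remove
#' illumination artifacts and slow drifts.
#'
#' @param movie an [pixel_movie()] object with at least `2^levels` frames.
#' @param f0 notch center frequency in Hz (default 12).
#' @param fw notch width in Hz (default 6).
#' @param levels DWT decomposition depth (default 6).
#' @return the movie with filtered frames.
#' @export
preprocess_movie <- function(movie, f0 = 12, fw = 6, levels = 6) {
  d <- dim(movie$frames)
  if (d[3] < 2^levels) stop("too few frames for the DWT decomposition")
  ny <- d[1]; nx <- d[2]
  band <- c(f0 - fw / 2, f0 + fw / 2) / (movie$fs / 2)
  bf <- signal::butter(2, band, type = "stop")
  out <- movie$frames
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      tr <- movie$frames[i, j, ]
      tr <- as.numeric(signal::filtfilt(bf, tr))
      out[i, j, ] <- dwt_detrend(tr, levels = levels)
    }
  }
  movie$frames <- out
  movie
}

trial_baseline_frames <- function(ep) {
  if (ep$onset_frame <= ep$first_frame) integer(0)
  else ep$first_frame:(ep$onset_frame - 1)
}

#' Blank-referenced z-scoring with high-baseline trial rejection
#'
#' Two-pass procedure: frames are z-scored per pixel against the ensemble
#' of frames belonging to blank-stimulus trials; trials whose baseline
#' activity (z-score averaged over pixels and baseline frames jointly) is
#' at or above `threshold` are discarded; z-scoring and per-trial baseline
#' subtraction are then recomputed from the remaining trials.  With
#' `reference = "global"` a single mean/sd over all pixels is used instead
#' of per-pixel statistics.
#'
#' @param movie an [pixel_movie()] object (typically after
#'   [preprocess_movie()]).
#' @param threshold baseline z-score rejection threshold (default 0.5; use
#'   `Inf` for a single-pass result without rejection).
#' @param reference `"pixel"` (default) or `"global"`.
#' @param baseline_subtract subtract each trial's own baseline mean per
#'   pixel (default `TRUE`).
#' @return object of class `xmodal_wf`: list with `z` (z-scored,
#'   baseline-subtracted frames), `epochs` (with `kept` and
#'   `baseline_mean` columns), `conditions`, `fs`.
#' @export
zscore_and_reject <- function(movie, threshold = 0.5,
                              reference = c("pixel", "global"),
                              baseline_subtract = TRUE) {
  reference <- match.arg(reference)
  eps <- movie$epochs
  blank_ids <- movie$conditions$condition[movie$conditions$modality == "blank"]

  zpass <- function(kept) {
    bl_trials <- eps$condition %in% blank_ids & kept
    if (!any(bl_trials)) stop("all blank trials rejected")
    bl_frames <- unlist(lapply(which(bl_trials), function(k) {
      eps$first_frame[k]:eps$last_frame[k]
    }))
    ref <- movie$frames[, , bl_frames, drop = FALSE]
    if (reference == "pixel") {
      mu <- apply(ref, c(1, 2), mean)
      sg <- apply(ref, c(1, 2), sd)
    } else {
      mu <- matrix(mean(ref), dim(ref)[1], dim(ref)[2])
      sg <- matrix(sd(ref), dim(ref)[1], dim(ref)[2])
    }
    sg[sg == 0] <- 1
    z <- sweep(movie$frames, c(1, 2), mu, "-")
    sweep(z, c(1, 2), sg, "/")
  }

  kept <- rep(TRUE, nrow(eps))
  z1 <- zpass(kept)
  base_mean <- vapply(seq_len(nrow(eps)), function(k) {
    bf <- trial_baseline_frames(eps[k, ])
    if (length(bf) == 0) return(0)
    mean(z1[, , bf])
  }, 0.0)
  kept <- base_mean < threshold
  if (!any(kept)) stop("all trials rejected")
  z2 <- zpass(kept)
  if (baseline_subtract) {
    for (k in seq_len(nrow(eps))) {
      bf <- trial_baseline_frames(eps[k, ])
      if (length(bf) == 0) next
      bl <- apply(z2[, , bf, drop = FALSE], c(1, 2), mean)
      fr <- eps$first_frame[k]:eps$last_frame[k]
      z2[, , fr] <- sweep(z2[, , fr, drop = FALSE], c(1, 2), bl, "-")
    }
  }
  eps$kept <- kept
  eps$baseline_mean <- base_mean
  structure(list(z = z2, epochs = eps, conditions = movie$conditions,
                 fs = movie$fs),
            class = "xmodal_wf")
}

norm01 <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

# mean over a post-onset window (seconds) of the median across kept trials
# of the given conditions
condition_response_map <- function(wf, condition_ids, window) {
  eps <- wf$epochs[wf$epochs$kept & wf$epochs$condition %in% condition_ids, ]
  if (nrow(eps) == 0) stop("no kept trials for the requested conditions")
  per_cond <- lapply(unique(eps$condition), function(cc) {
    e <- eps[eps$condition == cc, ]
    resp <- lapply(seq_len(nrow(e)), function(k) {
      fr <- e$onset_frame[k] + seq(round(window[1] * wf$fs),
                                   round(window[2] * wf$fs))
      fr <- fr[fr <= e$last_frame[k]]
      if (length(fr) == 0) stop("response window outside trial epoch")
      apply(wf$z[, , fr, drop = FALSE], c(1, 2), mean)
    })
    arr <- simplify2array(resp)
    apply(arr, c(1, 2), median)
  })
  Reduce(`+`, per_cond) / length(per_cond)
}

#' Vertical-position (retinotopy / somatotopy) difference map
#'
#' Average "top" and "bottom" response maps (visual: all conditions,
#' unimodal or multimodal, with the visual stimulus in grid positions 7-8
#' versus 3-4; tactile: B2 versus C2 whisker conditions), each
#' independently normalized to `[0, 1]`, then subtracted (top - bottom),
#' so the map is bounded in `[-1, 1]`.
#'
#' @param wf an [zscore_and_reject()] result.
#' @param modality `"visual"` (retinotopy) or `"tactile"` (somatotopy).
#' @param window averaging window in seconds after stimulus onset; defaults
#'   to 0.30-0.34 s for visual and 0.16-0.20 s for tactile maps.
#' @return `ny x nx` matrix in `[-1, 1]`.
#' @export
vertical_position_map <- function(wf, modality = c("visual", "tactile"),
                                  window = NULL) {
  modality <- match.arg(modality)
  g <- wf$conditions
  if (is.null(window)) {
    window <- if (modality == "visual") c(0.30, 0.34) else c(0.16, 0.20)
  }
  if (modality == "visual") {
    top <- g$condition[g$vis_pos %in% c(7, 8)]
    bottom <- g$condition[g$vis_pos %in% c(3, 4)]
  } else {
    top <- g$condition[g$whisker == "B2"]
    bottom <- g$condition[g$whisker == "C2"]
  }
  m_top <- condition_response_map(wf, top, window)
  m_bot <- condition_response_map(wf, bottom, window)
  norm01(m_top) - norm01(m_bot)
}

#' Modality preference map
#'
#' Pixelwise difference between the maximum response across unimodal
#' visual conditions and across unimodal tactile conditions, each maximum
#' map normalized to `[0, 1]` before subtraction (positive = visual-
#' preferring).
#'
#' @param wf an [zscore_and_reject()] result.
#' @param window averaging window in seconds after onset.
#' @return `ny x nx` matrix in `[-1, 1]`.
#' @export
modality_preference_map <- function(wf, window = c(0.16, 0.34)) {
  g <- wf$conditions
  max_map <- function(ids) {
    maps <- lapply(ids, function(cc) condition_response_map(wf, cc, window))
    Reduce(pmax, maps)
  }
  vis <- max_map(g$condition[g$modality == "visual"])
  tac <- max_map(g$condition[g$modality == "tactile"])
  norm01(vis) - norm01(tac)
}

#' Multisensory enhancement map
#'
#' Pixelwise difference between the measured multisensory response (maximum
#' across visuo-tactile conditions) and the predicted response (maximum
#' unisensory response between visual and tactile), each normalized to
#' `[0, 1]`; positive values indicate multisensory enhancement.
#'
#' @param wf an [zscore_and_reject()] result.
#' @param window averaging window in seconds after onset (default
#'   0.36-0.40 s).
#' @return `ny x nx` matrix in `[-1, 1]`.
#' @export
multisensory_enhancement_map <- function(wf, window = c(0.36, 0.40)) {
  g <- wf$conditions
  max_map <- function(ids) {
    maps <- lapply(ids, function(cc) condition_response_map(wf, cc, window))
    Reduce(pmax, maps)
  }
  vis <- max_map(g$condition[g$modality == "visual"])
  tac <- max_map(g$condition[g$modality == "tactile"])
  multi <- max_map(g$condition[g$modality == "multisensory"])
  predicted <- pmax(vis, tac)
  norm01(multi) - norm01(predicted)
}

#' Spatial coherence between two topographic maps
#'
#' Convolutionally (patch `patch` x `patch`, stride `stride`) computes the
#' Pearson correlation of matching patches of the two maps (each first
#' normalized to `[0, 1]`), scaled by the average peak-to-peak range of the
#' two patches so that locations with very low response magnitude
#' contribute little.  Values are placed at the patch center; margins and
#' constant patches are `NA`.
#'
#' @param mapA,mapB equal-size matrices.
#' @param patch patch side in pixels (default 8).
#' @param stride step between patch origins (default 1).
#' @return matrix of the same size with coherence values in `[-1, 1]`.
#' @export
spatial_coherence_map <- function(mapA, mapB, patch = 8, stride = 1) {
  stopifnot(all(dim(mapA) == dim(mapB)), min(dim(mapA)) >= patch)
  a <- norm01(mapA); b <- norm01(mapB)
  ny <- nrow(a); nx <- ncol(a)
  out <- matrix(NA_real_, ny, nx)
  ctr <- floor(patch / 2)
  for (i in seq(1, ny - patch + 1, by = stride)) {
    for (j in seq(1, nx - patch + 1, by = stride)) {
      pa <- a[i:(i + patch - 1), j:(j + patch - 1)]
      pb <- b[i:(i + patch - 1), j:(j + patch - 1)]
      if (sd(pa) == 0 || sd(pb) == 0) next
      rho <- cor(as.numeric(pa), as.numeric(pb))
      scale <- mean(c(diff(range(pa)), diff(range(pb))))
      out[i + ctr, j + ctr] <- rho * scale
    }
  }
  out
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_vec <- function(v) { # edge-replicated 1-D convolution
    n <- length(v)
    vp <- v[pmin(n, pmax(1, (1 - half):(n + half)))]
    vapply(seq_len(n), function(t) sum(vp[t:(t + 2 * half)] * k), 0.0)
  }
  m2 <- apply(m, 2, smooth_vec)
  t(apply(m2, 1, smooth_vec))
}

map_gradient <- function(m, scale = 4) {
  ny <- nrow(m); nx <- ncol(m)
  gx <- gy <- matrix(0, ny, nx)
  for (j in seq_len(nx)) {
    jp <- min(nx, j + scale); jm <- max(1, j - scale)
    gx[, j] <- (m[, jp] - m[, jm]) / (jp - jm)
  }
  for (i in seq_len(ny)) {
    ip <- min(ny, i + scale); im <- max(1, i - scale)
    gy[i, ] <- (m[ip, ] - m[im, ]) / (ip - im)
  }
  list(gx = gx, gy = gy)
}

#' Dominant gradient orientation of a topographic map
#'
#' Estimates the orientation of an embedded topographic gradient: the
#' spatial gradient is computed at a scale of `scale` pixels and Gaussian-
#' smoothed, and the squared-magnitude-weighted axial (mod-180) mean of
#' the gradient direction is returned.  A border of `trim` pixels is
#' excluded from the average because edge-clamped finite differences bias
#' the direction there.
#'
#' @param map a matrix.
#' @param scale finite-difference half-spacing in pixels (default 4).
#' @param smooth_sigma Gaussian smoothing sd of the gradient components in
#'   pixels (default 2).
#' @param trim border width excluded from the average (defaults to
#'   `scale + ceiling(smooth_sigma)`).
#' @return orientation in degrees in `[0, 180)`, measured from the +row
#'   axis towards the +column axis.
#' @export
map_orientation <- function(map, scale = 4, smooth_sigma = 2,
                            trim = scale + ceiling(smooth_sigma)) {
  ny <- nrow(map); nx <- ncol(map)
  stopifnot(ny > 2 * trim, nx > 2 * trim)
  g <- map_gradient(map, scale)
  gx <- gaussian_smooth(g$gx, smooth_sigma)
  gy <- gaussian_smooth(g$gy, smooth_sigma)
  keep <- matrix(FALSE, ny, nx)
  keep[(1 + trim):(ny - trim), (1 + trim):(nx - trim)] <- TRUE
  w <- (gx^2 + gy^2) * keep
  if (all(w == 0)) stop("map has no gradient in the interior")
  phi <- atan2(gx, gy)
  ang <- 0.5 * atan2(sum(w * sin(2 * phi)), sum(w * cos(2 * phi)))
  (ang * 180 / pi) %% 180
}

#' Mean angular mismatch between two map gradient fields
#'
#' Computes the spatial gradient of each map at a scale of `scale` pixels,
#' Gaussian-smooths the gradient components, and returns the average
#' angular difference (degrees, in `[0, 180]`) between the two gradient
#' fields over the region of interest.  Pixels where either gradient
#' vanishes are skipped.
#'
#' @param mapA,mapB equal-size matrices.
#' @param roi optional logical matrix selecting pixels (default all).
#' @param scale finite-difference half-spacing in pixels (default 4).
#' @param smooth_sigma Gaussian smoothing sd of the gradient components in
#'   pixels (default 2).
#' @return mean angular difference in degrees.
#' @export
gradient_angle_mismatch <- function(mapA, mapB, roi = NULL, scale = 4,
                                    smooth_sigma = 2) {
  stopifnot(all(dim(mapA) == dim(mapB)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mapA), ncol(mapA))
  if (!any(roi)) stop("empty region of interest")
  ga <- map_gradient(mapA, scale)
  gb <- map_gradient(mapB, scale)
  ga$gx <- gaussian_smooth(ga$gx, smooth_sigma)
  ga$gy <- gaussian_smooth(ga$gy, smooth_sigma)
  gb$gx <- gaussian_smooth(gb$gx, smooth_sigma)
  gb$gy <- gaussian_smooth(gb$gy, smooth_sigma)
  na <- sqrt(ga$gx^2 + ga$gy^2)
  nb <- sqrt(gb$gx^2 + gb$gy^2)
  ok <- roi & na > 0 & nb > 0
  if (!any(ok)) stop("no usable gradient vectors in the ROI")
  cosang <- (ga$gx * gb$gx + ga$gy * gb$gy)[ok] / (na[ok] * nb[ok])
  mean(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
}

#' Raster plot of a topographic map
#'
#' @param map matrix.
#' @param name legend title.
#' @return a ggplot object.
#' @export
plot_map <- function(map, name = "value") {
  df <- expand.grid(y = seq_len(nrow(map)), x = seq_len(ncol(map)))
  df$value <- as.numeric(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = name) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
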