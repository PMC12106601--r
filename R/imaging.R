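#' The 54-condition visuo-tactile sparse-noise stimulus grid
#'
#' Three whisker conditions (none, C2 = bottom, B2 = top) x nine visual
#' positions (1-8 plus 9 = blank screen) x two visuo-tactile delays
#' (synchronous, or tactile delayed by 0.15 s) = 54 conditions.  For
#' decoding, visual positions 5-8 form the "top" category and 1-4 the
#' "bottom" category.
#'
#' @param delays delay levels to include (default both).
#' @return tibble with columns `condition`, `whisker`, `vis_pos`, `delay`,
#'   `modality` (`"blank"`, `"visual"`, `"tactile"`, `"multisensory"`),
#'   `visual_category`, `tactile_category`.
#' @export
stimulus_grid <- function(delays = c("sync", "delayed")) {
  g <- expand.grid(delay = delays, vis_pos = 1:9,
                   whisker = c("none", "C2", "B2"),
                   stringsAsFactors = FALSE)[, 3:1]
  g <- as_tibble(g)
  g$condition <- seq_len(nrow(g))
  g$modality <- dplyr::case_when(
    g$whisker == "none" & g$vis_pos == 9 ~ "blank",
    g$whisker == "none" ~ "visual",
    g$vis_pos == 9 ~ "tactile",
    TRUE ~ "multisensory"
  )
  g$visual_category <- dplyr::case_when(
    g$vis_pos >= 5 & g$vis_pos <= 8 ~ "top",
    g$vis_pos <= 4 ~ "bottom",
    TRUE ~ NA_character_
  )
  g$tactile_category <- dplyr::case_when(
    g$whisker == "B2" ~ "top",
    g$whisker == "C2" ~ "bottom",
    TRUE ~ NA_character_
  )
  g[, c("condition", "whisker", "vis_pos", "delay", "modality",
        "visual_category", "tactile_category")]
}

#' Construct a trial tensor of z-scored fluorescence
#'
#' @param data numeric 4-D array `neuron x condition x trial x bin` of
#'   baseline-z-scored fluorescence.
#' @param conditions condition table matching the second dimension (default
#'   [stimulus_grid()]).
#' @param times bin times in seconds relative to stimulus onset; default a
#'   30 Hz axis with 0.2 s of baseline.
#' @param coords optional tibble of per-neuron map coordinates (`x`, `y`).
#' @return object of class `xmodal_tensor` (the array, with `conditions`,
#'   `times` and `coords` attributes).
#' @export
trial_tensor <- function(data, conditions = stimulus_grid(), times = NULL,
                         coords = NULL) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[2] != nrow(conditions)) {
    stop("condition dimension does not match the condition table")
  }
  if (is.null(times)) {
    fs <- 30
    times <- (seq_len(dim(data)[4]) - 1) / fs - 0.2
  }
  stopifnot(length(times) == dim(data)[4])
  structure(data, conditions = conditions, times = times, coords = coords,
            class = "xmodal_tensor")
}

tensor_conditions <- function(tensor) attr(tensor, "conditions")
tensor_times <- function(tensor) attr(tensor, "times")

#' Bin indices of the response window
#'
#' @param tensor an [trial_tensor()] object.
#' @param window window in seconds after stimulus onset (default the
#'   0.2-0.733 s response window).
#' @return integer vector of bin indices.
#' @export
response_window_bins <- function(tensor, window = c(0.2, 0.733)) {
  t <- tensor_times(tensor)
  which(t >= window[1] & t <= window[2])
}

#' Analysis parameters for the sparse-noise single-neuron pipeline
#'
#' @param ... named overrides of: `neuropil_alpha` (0.7), `surprise_strict`
#'   (8), `surprise_lenient` (2), `cv_th` (4), `consecutive_bins` (4),
#'   `window` (c(0.2, 0.733) s), `boot_outer` (2000), `boot_inner` (25),
#'   `mi_epsilon` (1e-6), `folds` (4), `resamplings` (40), `pool_sizes`
#'   (1:50).
#' @return named list of class `xmodal_analysis_params`.
#' @export
analysis_params <- function(...) {
  p <- list(
    neuropil_alpha = 0.7,
    surprise_strict = 8, surprise_lenient = 2, cv_th = 4,
    consecutive_bins = 4,
    window = c(0.2, 0.733),
    boot_outer = 2000, boot_inner = 25,
    mi_epsilon = 1e-6,
    folds = 4, resamplings = 40, pool_sizes = 1:50
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) stop("unknown parameter(s): ",
                                paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$surprise_strict > p$surprise_lenient)
  structure(p, class = "xmodal_analysis_params")
}

#' Neuropil correction of a somatic fluorescence trace
#'
#' `F(t) = F_soma(t) - alpha * F_surround(t)`.
#'
#' @param f_soma,f_surround equal-length numeric vectors.
#' @param alpha neuropil coefficient (default 0.7).
#' @return corrected trace.
#' @export
neuropil_correct <- function(f_soma, f_surround, alpha = 0.7) {
  if (length(f_soma) != length(f_surround)) {
    stop("soma and surround traces must have equal length")
  }
  f_soma - alpha * f_surround
}

# surprise/CV arrays [neuron, condition, bin] from a trial tensor
surprise_arrays <- function(tensor) {
  d <- dim(tensor)
  n_trials <- d[3]
  if (n_trials < 3) stop("at least 3 trials are required")
  m <- apply(tensor, c(1, 2, 4), mean)
  s <- apply(tensor, c(1, 2, 4), sd)
  # one-sample two-sided z test of the across-trial mean against 0; traces
  # are baseline-z-scored so the null SE is 1/sqrt(n)
  z <- m * sqrt(n_trials)
  logp <- log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  surprise <- -logp / log(10)
  cv <- s / abs(m)
  list(mean = m, sd = s, surprise = surprise, cv = cv)
}

#' Per-bin response surprise and variability
#'
#' For every neuron, condition and time bin: the response surprise
#' `-log10(p)` of a one-sample two-sided z-test of the across-trial mean
#' against zero (the baseline z-scoring fixes the null SE at `1/sqrt(n)`),
#' and the across-trial coefficient of variation `sd / |mean|`.
#'
#' @param tensor an [trial_tensor()] with at least 3 trials.
#' @param conditions optional condition ids to restrict to.
#' @return tibble: `neuron`, `condition`, `bin`, `time`, `mean`, `surprise`,
#'   `cv`.
#' @export
response_surprise <- function(tensor, conditions = NULL) {
  arr <- surprise_arrays(tensor)
  d <- dim(arr$mean)
  conds <- if (is.null(conditions)) seq_len(d[2]) else conditions
  times <- tensor_times(tensor)
  out <- expand.grid(neuron = seq_len(d[1]), condition = conds,
                     bin = seq_len(d[3]))
  out <- as_tibble(out)
  idx <- cbind(out$neuron, out$condition, out$bin)
  out$time <- times[out$bin]
  out$mean <- arr$mean[idx]
  out$surprise <- arr$surprise[idx]
  out$cv <- arr$cv[idx]
  out
}

has_consecutive <- function(flags, k) {
  if (!any(flags)) return(FALSE)
  r <- rle(flags)
  any(r$values & r$lengths >= k)
}

#' Functional classification of neurons
#'
#' A neuron is included ("reliably responsive") if in some stimulus
#' condition its surprise exceeds the stringent threshold while CV stays
#' below `cv_th` for at least `consecutive_bins` consecutive post-onset
#' bins.  Included neurons are then tested per condition with the lenient
#' threshold (any single bin) and classified from the responsivity pattern:
#' responsive only in visual conditions = "visual", only tactile =
#' "tactile", both = "visuo-tactile", only in joint visuo-tactile
#' conditions = "gated".  Neurons failing the inclusion gate are
#' "unresponsive".  The blank condition is never used for responsivity.
#'
#' @param tensor an [trial_tensor()] object.
#' @param params an [analysis_params()] object.
#' @return tibble: `neuron`, `class`, `included`, `visual_responsive`,
#'   `tactile_responsive`, `joint_responsive`.
#' @export
classify_cells <- function(tensor, params = analysis_params()) {
  arr <- surprise_arrays(tensor)
  grid <- tensor_conditions(tensor)
  post <- which(tensor_times(tensor) > 0)
  stim_conds <- grid$condition[grid$modality != "blank"]
  n_neuron <- dim(tensor)[1]

  per_neuron <- function(i) {
    strict_ok <- vapply(stim_conds, function(cc) {
      ok <- arr$surprise[i, cc, post] >= params$surprise_strict &
        arr$cv[i, cc, post] < params$cv_th
      ok[is.na(ok)] <- FALSE
      has_consecutive(ok, params$consecutive_bins)
    }, TRUE)
    included <- any(strict_ok)
    lenient <- vapply(seq_len(nrow(grid)), function(cc) {
      ok <- arr$surprise[i, cc, post] >= params$surprise_lenient &
        arr$cv[i, cc, post] < params$cv_th
      any(ok, na.rm = TRUE)
    }, TRUE)
    vis <- any(lenient[grid$modality == "visual"])
    tac <- any(lenient[grid$modality == "tactile"])
    joint <- any(lenient[grid$modality == "multisensory"])
    cls <- if (!included) "unresponsive"
      else if (vis && tac) "visuo-tactile"
      else if (vis) "visual"
      else if (tac) "tactile"
      else if (joint) "gated"
      else "unresponsive"
    tibble(neuron = i, class = cls, included = included,
           visual_responsive = vis, tactile_responsive = tac,
           joint_responsive = joint)
  }
  dplyr::bind_rows(lapply(seq_len(n_neuron), per_neuron))
}

#' Max-model prediction of a multisensory response
#'
#' For a multisensory condition, the predicted response is the trial-wise,
#' bin-wise maximum of the responses to the corresponding unimodal visual
#' and tactile conditions (same visual position / same whisker, same
#' delay), subsequently averaged across trials.
#'
#' @param tensor an [trial_tensor()] object.
#' @param condition a multisensory condition id.
#' @return list of class `xmodal_maxmodel`: `condition`,
#'   `visual_condition`, `tactile_condition`, `pred` (`neuron x trial x
#'   bin` array of per-trial predictions), `pred_mean`, `measured`
#'   (`neuron x trial x bin`), `measured_mean` (`neuron x bin`).
#' @export
predict_max_model <- function(tensor, condition) {
  grid <- tensor_conditions(tensor)
  row <- grid[grid$condition == condition, ]
  if (nrow(row) != 1 || row$modality != "multisensory") {
    stop("condition must be a multisensory condition of the grid")
  }
  vis_cond <- grid$condition[grid$whisker == "none" &
                               grid$vis_pos == row$vis_pos &
                               grid$delay == row$delay]
  tac_cond <- grid$condition[grid$whisker == row$whisker &
                               grid$vis_pos == 9 & grid$delay == row$delay]
  if (length(vis_cond) != 1 || length(tac_cond) != 1) {
    stop("unpaired condition: matching unimodal conditions not found")
  }
  v <- tensor[, vis_cond, , , drop = FALSE]
  t_ <- tensor[, tac_cond, , , drop = FALSE]
  pred <- pmax(v, t_)
  dim(pred) <- dim(pred)[c(1, 3, 4)]
  meas <- tensor[, condition, , , drop = FALSE]
  dim(meas) <- dim(meas)[c(1, 3, 4)]
  structure(list(
    condition = condition, visual_condition = vis_cond,
    tactile_condition = tac_cond,
    pred = pred, pred_mean = apply(pred, c(1, 3), mean),
    measured = meas, measured_mean = apply(meas, c(1, 3), mean)
  ), class = "xmodal_maxmodel")
}

#' Multisensory modulation index
#'
#' Normalized difference between measured and max-model-predicted
#' responses, `MI = (measured - predicted) / (|measured| + |predicted| +
#' epsilon)`; positive values indicate multisensory enhancement, negative
#' suppression.
#'
#' @param measured,predicted numeric vectors/arrays of equal shape
#'   (typically trial-averaged traces per bin).
#' @param epsilon regularizer of the denominator (default 1e-6).
#' @return MI with the shape of the inputs, in `[-1, 1]`.
#' @export
multisensory_modulation_index <- function(measured, predicted,
                                          epsilon = 1e-6) {
  if (length(measured) != length(predicted)) stop("shape mismatch")
  (measured - predicted) / (abs(measured) + abs(predicted) + epsilon)
}

#' Bootstrap-t significance of multisensory modulation
#'
#' Tests, per time bin, whether the multisensory modulation index differs
#' from zero, using a bootstrap-t procedure over trials: `reps[1]` outer
#' resamples each studentized by `reps[2]` inner resamples.  The observed
#' statistic is studentized by the sd of the outer bootstrap replicates.
#'
#' @param measured_trials,predicted_trials `trial x bin` matrices of the
#'   measured multisensory and max-model-predicted responses.
#' @param reps `c(outer, inner)` resampling counts (default `c(2000, 25)`;
#'   smaller values give a fast smoke mode).
#' @param epsilon MI regularizer.
#' @return numeric vector of two-sided p-values, one per bin.
#' @export
mi_significance <- function(measured_trials, predicted_trials,
                            reps = c(2000, 25), epsilon = 1e-6) {
  stopifnot(ncol(measured_trials) == ncol(predicted_trials))
  n_m <- nrow(measured_trials)
  n_p <- nrow(predicted_trials)
  if (min(n_m, n_p) < 5) stop("at least 5 trials are required")
  B <- reps[1]; Bi <- reps[2]
  mi_of <- function(m, p) {
    multisensory_modulation_index(colMeans(m), colMeans(p), epsilon)
  }
  theta_hat <- mi_of(measured_trials, predicted_trials)
  nb <- length(theta_hat)
  t_star <- matrix(NA_real_, B, nb)
  theta_star <- matrix(NA_real_, B, nb)
  for (b in seq_len(B)) {
    im <- sample.int(n_m, n_m, replace = TRUE)
    ip <- sample.int(n_p, n_p, replace = TRUE)
    m_b <- measured_trials[im, , drop = FALSE]
    p_b <- predicted_trials[ip, , drop = FALSE]
    th_b <- mi_of(m_b, p_b)
    inner <- matrix(NA_real_, Bi, nb)
    for (j in seq_len(Bi)) {
      inner[j, ] <- mi_of(m_b[sample.int(n_m, n_m, TRUE), , drop = FALSE],
                          p_b[sample.int(n_p, n_p, TRUE), , drop = FALSE])
    }
    se_b <- apply(inner, 2, sd)
    theta_star[b, ] <- th_b
    t_star[b, ] <- (th_b - theta_hat) / se_b
  }
  se0 <- apply(theta_star, 2, sd)
  t0 <- theta_hat / se0
  vapply(seq_len(nb), function(k) {
    ts <- t_star[, k]
    ts <- ts[is.finite(ts)]
    if (length(ts) == 0 || !is.finite(t0[k])) return(NA_real_)
    (1 + sum(abs(ts) >= abs(t0[k]))) / (length(ts) + 1)
  }, 0.0)
}

#' Summarize multisensory modulation of one neuron (MI range)
#'
#' Integrates the MI trace over the response window for every valid
#' multisensory condition and returns the min-max range of these integrals.
#' A condition is valid when the neuron is responsive (lenient threshold)
#' to at least one of its unisensory constituents and the modulation is
#' significant (bootstrap-t `p < 0.05`) at one or more bins.
#'
#' @param tensor an [trial_tensor()] object.
#' @param neuron neuron index.
#' @param params an [analysis_params()] object; `boot_outer`/`boot_inner`
#'   control the bootstrap cost.
#' @return list: `mi_range` (scalar; 0 when no condition is valid),
#'   `per_condition` tibble (`condition`, `mi_integral`, `significant`,
#'   `constituent_responsive`, `valid`).
#' @export
mi_range <- function(tensor, neuron, params = analysis_params()) {
  grid <- tensor_conditions(tensor)
  arr <- surprise_arrays(tensor)
  post <- which(tensor_times(tensor) > 0)
  win <- response_window_bins(tensor, params$window)
  lenient_ok <- function(cc) {
    any(arr$surprise[neuron, cc, post] >= params$surprise_lenient &
          arr$cv[neuron, cc, post] < params$cv_th, na.rm = TRUE)
  }
  ms <- grid$condition[grid$modality == "multisensory"]
  rows <- lapply(ms, function(cc) {
    mm <- predict_max_model(tensor, cc)
    resp <- lenient_ok(mm$visual_condition) || lenient_ok(mm$tactile_condition)
    mi <- multisensory_modulation_index(mm$measured_mean[neuron, ],
                                        mm$pred_mean[neuron, ],
                                        params$mi_epsilon)
    p <- mi_significance(mm$measured[neuron, , ], mm$pred[neuron, , ],
                         reps = c(params$boot_outer, params$boot_inner),
                         epsilon = params$mi_epsilon)
    tibble(condition = cc,
           mi_integral = sum(mi[win]) / length(win),
           significant = any(p < 0.05, na.rm = TRUE),
           constituent_responsive = resp,
           valid = resp && any(p < 0.05, na.rm = TRUE))
  })
  per <- dplyr::bind_rows(rows)
  valid <- per$mi_integral[per$valid]
  list(mi_range = if (length(valid) == 0) 0 else max(valid) - min(valid),
       per_condition = per)
}

#' Position preference index
#'
#' Center of mass of the (rectified) average responses along the stimulus
#' position axis, mapped linearly to `[-1, +1]`: +1 for responses
#' concentrated at the top extreme (visual position 8 / whisker B2), -1 at
#' the bottom extreme (position 1 / whisker C2).
#'
#' @param responses average responses: length 8 over visual positions 1-8,
#'   or length 2 over whiskers `(C2, B2)`.
#' @param modality `"visual"` or `"tactile"`.
#' @return scalar index in `[-1, 1]`.
#' @export
position_preference_index <- function(responses,
                                      modality = c("visual", "tactile")) {
  modality <- match.arg(modality)
  n_expected <- if (modality == "visual") 8 else 2
  if (length(responses) != n_expected) {
    stop("expected ", n_expected, " ", modality, " responses")
  }
  r <- pmax(0, responses)
  if (sum(r) == 0) stop("all responses are zero after rectification")
  x <- seq(-1, 1, length.out = length(r))
  sum(r * x) / sum(r)
}

#' Positional tuning selectivity
#'
#' Visual: a four-parameter Gaussian `a * exp(-(x - mu)^2 / (2 sigma^2)) +
#' b` is least-squares fitted to the 8-position average response profile and
#' selectivity is `min(1, sigma_ref / sigma)` where `sigma_ref` is the sigma
#' of a one-position-wide (FWHM = 1 position) Gaussian, so a one-position
#' response maps to 1 and a flat profile to ~0.  Tactile: the absolute value
#' of the two-point position preference index.
#'
#' @param responses average responses (length 8 visual, length 2 tactile
#'   `(C2, B2)`).
#' @param modality `"visual"` or `"tactile"`.
#' @return index in `[0, 1]`, or `NA` if the Gaussian fit fails.
#' @export
tuning_selectivity <- function(responses,
                               modality = c("visual", "tactile")) {
  modality <- match.arg(modality)
  if (modality == "tactile") {
    if (length(responses) != 2) stop("expected 2 tactile responses")
    return(abs(position_preference_index(responses, "tactile")))
  }
  if (length(responses) != 8) stop("expected 8 visual responses")
  fit <- fit_gaussian_profile(responses)
  if (is.null(fit)) return(NA_real_)
  sigma_ref <- 1 / (2 * sqrt(2 * log(2))) # FWHM = 1 position
  min(1, sigma_ref / fit["sigma"])
}

#' Gaussian fit of a positional response profile
#'
#' @param responses numeric vector over positions `1..length(responses)`.
#' @return named vector `c(a, mu, sigma, b)` or `NULL` on failure.
#' @export
fit_gaussian_profile <- function(responses) {
  x <- seq_along(responses)
  y <- responses
  start <- list(a = max(y) - min(y), mu = x[which.max(y)], sigma = 1.5,
                b = min(y))
  if (start$a <= 0) start$a <- 1e-3
  # nls.lm rather than nlsLM: the latter refuses solutions whose Jacobian
  # is singular (e.g. a one-bin spike, where the Gaussian underflows away
  # from the peak), even though the least-squares fit itself is exact
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = c(0, min(x) - 2, 0.05, -Inf),
      upper = c(Inf, max(x) + 2, 100, Inf),
      fn = function(p) y - (p$a * exp(-(x - p$mu)^2 / (2 * p$sigma^2)) + p$b),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info == 0) return(NULL)
  cf <- unlist(fit$par)
  names(cf) <- c("a", "mu", "sigma", "b")
  if (!all(is.finite(cf))) return(NULL)
  c(a = unname(cf["a"]), mu = unname(cf["mu"]),
    sigma = abs(unname(cf["sigma"])), b = unname(cf["b"]))
}

#' Cluster visuo-tactile neurons into processing streams
#'
#' Two-centroid k-means on neuron map coordinates, with the two clusters
#' labeled by proximity of their centroids to caller-provided anchor
#' points (e.g. known dorsal- and ventral-stream locations).
#'
#' @param coords tibble/data frame with `x`, `y` (one row per neuron).
#' @param anchors named list with `dorsal` and `ventral`, each `c(x, y)`.
#' @param nstart random restarts for k-means.
#' @return tibble: `x`, `y`, `stream` (`"dorsal"`/`"ventral"`).
#' @export
cluster_streams <- function(coords, anchors, nstart = 20) {
  m <- as.matrix(coords[, c("x", "y")])
  if (nrow(m) < 2) stop("need at least 2 neurons")
  if (nrow(unique(m)) < 2) stop("degenerate coordinates: all points equal")
  km <- kmeans(m, centers = 2, nstart = nstart)
  d_dorsal <- colSums((t(km$centers) - anchors$dorsal)^2)
  dorsal_cluster <- which.min(d_dorsal)
  # guard against both centroids nearer one anchor: assign by relative dist
  d_ventral <- colSums((t(km$centers) - anchors$ventral)^2)
  if (which.min(d_ventral) == dorsal_cluster) {
    dorsal_cluster <- which.max(d_ventral - d_dorsal)
  }
  out <- as_tibble(coords)
  out$stream <- ifelse(km$cluster == dorsal_cluster, "dorsal", "ventral")
  out
}
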