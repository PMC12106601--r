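# deterministic movie helper: hand-placed condition patterns, no noise
toy_movie <- function(patterns, n_trials = 3, n_baseline = 4,
                      n_response = 6, noise_sd = 0, seed = 1) {
  set.seed(seed)
  grid <- stimulus_grid(delays = "sync")
  n_cond <- nrow(grid)
  ny <- nrow(patterns[[1]]); nx <- ncol(patterns[[1]])
  fpt <- n_baseline + n_response
  n_tr <- n_cond * n_trials
  frames <- array(rnorm(ny * nx * n_tr * fpt, sd = noise_sd),
                  c(ny, nx, n_tr * fpt))
  epochs <- tibble::tibble(
    trial = seq_len(n_tr),
    condition = rep(seq_len(n_cond), each = n_trials),
    first_frame = (seq_len(n_tr) - 1) * fpt + 1
  )
  epochs$onset_frame <- epochs$first_frame + n_baseline
  epochs$last_frame <- epochs$first_frame + fpt - 1
  for (k in seq_len(n_tr)) {
    pat <- patterns[[epochs$condition[k]]]
    for (f in seq_len(n_response)) {
      frames[, , epochs$onset_frame[k] + f - 1] <-
        frames[, , epochs$onset_frame[k] + f - 1] + pat
    }
  }
  pixel_movie(frames, epochs, grid, fs = 50)
}

test_that("DWT steps invert exactly and detrending kills slow drift", {
  set.seed(1)
  x <- rnorm(256)
  s <- xmodal:::dwt_step(x)
  expect_equal(xmodal:::idwt_step(s$a, s$d), x, tolerance = 1e-12)
  # full analysis/synthesis round trip with approximation kept
  a <- x
  det <- list()
  for (l in 1:6) {
    s <- xmodal:::dwt_step(a)
    det[[l]] <- s$d
    a <- s$a
  }
  for (l in 6:1) a <- xmodal:::idwt_step(a, det[[l]])
  expect_equal(a, x, tolerance = 1e-12)
  # constant signals are removed entirely
  expect_equal(dwt_detrend(rep(3.7, 256)), rep(0, 256), tolerance = 1e-10)
  # slow drift removed, fast structure preserved
  t_ax <- seq_len(512) / 50
  fast <- sin(2 * pi * 5 * t_ax)
  slow <- 4 * sin(2 * pi * 0.05 * t_ax)
  out <- dwt_detrend(fast + slow)
  expect_lt(sd(out - fast), 0.35 * sd(slow))
  # non-power-of-two lengths are padded and cropped
  expect_length(dwt_detrend(rnorm(300)), 300)
  expect_error(dwt_detrend(rnorm(10)), "at least")
})

test_that("preprocessing removes the 12 Hz artifact and slow drift", {
  spec <- map_spec(ny = 8, nx = 8, n_trials = 2, amp = 0, noise_sd = 0.2,
                   drift_amp = 3, artifact_amp = 3)
  mv <- gen_widefield_movie(spec, seed = 2)
  out <- preprocess_movie(mv)
  band_power <- function(tr) {
    sp <- Mod(fft(tr - mean(tr)))^2
    fr <- (seq_along(tr) - 1) / length(tr) * 50
    c(artifact = sum(sp[fr > 11 & fr < 13]),
      slow = sum(sp[fr > 0 & fr < 0.2]))
  }
  before <- band_power(mv$frames[4, 4, ])
  after <- band_power(out$frames[4, 4, ])
  expect_lt(after["artifact"], 0.01 * before["artifact"])
  expect_lt(after["slow"], 0.01 * before["slow"])
  short <- mv
  short$frames <- mv$frames[, , 1:32, drop = FALSE]
  expect_error(preprocess_movie(short), "too few frames")
})

test_that("pixel_movie validates epochs and blank presence", {
  grid <- stimulus_grid(delays = "sync")
  frames <- array(0, c(2, 2, 10))
  eps <- tibble::tibble(trial = 1, condition = 3, first_frame = 1,
                        onset_frame = 3, last_frame = 10)
  expect_error(pixel_movie(frames, eps, grid), "blank")
  blank_id <- grid$condition[grid$modality == "blank"][1]
  eps$condition <- blank_id
  expect_s3_class(pixel_movie(frames, eps, grid), "xmodal_movie")
  eps$last_frame <- 99
  expect_error(pixel_movie(frames, eps, grid), "outside")
})

test_that("z-scoring references blank trials and subtracts baselines", {
  grid <- stimulus_grid(delays = "sync")
  pats <- lapply(grid$condition, function(cc) {
    if (grid$modality[cc] == "blank") matrix(0, 6, 6) else matrix(2, 6, 6)
  })
  mv <- toy_movie(pats, noise_sd = 0.5, seed = 3)
  wf <- zscore_and_reject(mv, threshold = Inf)
  expect_s3_class(wf, "xmodal_wf")
  expect_true(all(wf$epochs$kept))
  # blank trials are ~standard normal after referencing
  blank_ids <- grid$condition[grid$modality == "blank"]
  bl_fr <- unlist(lapply(which(wf$epochs$condition %in% blank_ids),
                         function(k) {
    wf$epochs$first_frame[k]:wf$epochs$last_frame[k]
  }))
  expect_lt(abs(mean(wf$z[, , bl_fr])), 0.2)
  expect_lt(abs(sd(wf$z[, , bl_fr]) - 1), 0.2)
  # per-trial baseline means are exactly zero after subtraction
  k <- 5
  bfr <- wf$epochs$first_frame[k]:(wf$epochs$onset_frame[k] - 1)
  bl <- apply(wf$z[, , bfr], c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-10)
  # stimulus trials carry a clear evoked z response
  k2 <- which(!(wf$epochs$condition %in% blank_ids))[1]
  rfr <- wf$epochs$onset_frame[k2]:wf$epochs$last_frame[k2]
  expect_gt(mean(wf$z[, , rfr]), 1)
})

test_that("global reference mode uses one mean and sd", {
  grid <- stimulus_grid(delays = "sync")
  pats <- lapply(grid$condition, function(cc) matrix(0, 4, 4))
  mv <- toy_movie(pats, noise_sd = 1, seed = 4)
  wf <- zscore_and_reject(mv, threshold = Inf, reference = "global",
                          baseline_subtract = FALSE)
  expect_lt(abs(sd(wf$z) - 1), 0.05)
})

test_that("identical top and bottom responses give a zero position map", {
  grid <- stimulus_grid(delays = "sync")
  same <- matrix(seq_len(36) / 36, 6, 6)
  pats <- lapply(grid$condition, function(cc) {
    if (grid$modality[cc] == "blank") matrix(0, 6, 6) else same
  })
  mv <- toy_movie(pats, noise_sd = 0)
  wf <- zscore_and_reject(mv, threshold = Inf)
  vm <- vertical_position_map(wf, "visual", window = c(0.02, 0.1))
  expect_equal(max(abs(vm)), 0, tolerance = 1e-9)
  tm <- vertical_position_map(wf, "tactile", window = c(0.02, 0.1))
  expect_equal(max(abs(tm)), 0, tolerance = 1e-9)
})

test_that("position maps are bounded and flip sign when roles swap", {
  grid <- stimulus_grid(delays = "sync")
  up <- outer(seq_len(6) / 6, rep(1, 6))
  down <- up[6:1, ]
  mk <- function(top_pat, bottom_pat) {
    pats <- lapply(grid$condition, function(cc) {
      if (!is.na(grid$visual_category[cc]) &&
          grid$visual_category[cc] == "top") top_pat
      else if (!is.na(grid$visual_category[cc])) bottom_pat
      else matrix(0, 6, 6)
    })
    zscore_and_reject(toy_movie(pats, noise_sd = 0), threshold = Inf)
  }
  m1 <- vertical_position_map(mk(up, down), "visual", window = c(0.02, 0.1))
  m2 <- vertical_position_map(mk(down, up), "visual", window = c(0.02, 0.1))
  expect_true(all(m1 >= -1 & m1 <= 1))
  expect_equal(m1, -m2, tolerance = 1e-9)
  # monotone along the programmed (row) axis
  expect_true(all(diff(m1[, 3]) > 0))
})

test_that("coherence: +range on identical maps, exact flip, ~0 independent", {
  set.seed(6)
  base <- outer(seq_len(20), seq_len(20), function(i, j) i + 0.3 * j)
  m <- base / max(base) + matrix(rnorm(400, sd = 0.02), 20, 20)
  same <- spatial_coherence_map(m, m)
  inner <- same[!is.na(same)]
  expect_true(all(inner > 0))
  # self-coherence equals the patch peak-to-peak range (correlation 1)
  a <- xmodal:::norm01(m)
  expect_equal(same[4 + 4, 4 + 4], diff(range(a[4:11, 4:11])),
               tolerance = 1e-9)
  flipped <- spatial_coherence_map(m, -m)
  expect_equal(flipped, -same, tolerance = 1e-9)
  indep <- matrix(rnorm(400), 20, 20)
  ic <- spatial_coherence_map(m, indep)
  expect_lt(abs(mean(ic, na.rm = TRUE)), 0.1)
  expect_error(spatial_coherence_map(m, matrix(0, 5, 5)), "dim")
})

test_that("gradient mismatch: identity 0, rotated ramps 90 +- 2", {
  ramp <- function(angle) {
    a <- angle * pi / 180
    outer(seq_len(30), rep(1, 30)) * cos(a) +
      outer(rep(1, 30), seq_len(30)) * sin(a)
  }
  m <- ramp(35)
  expect_equal(gradient_angle_mismatch(m, m), 0, tolerance = 1e-9)
  expect_equal(gradient_angle_mismatch(m, ramp(125)), 90, tolerance = 2)
  expect_equal(gradient_angle_mismatch(ramp(0), ramp(45)), 45, tolerance = 2)
  expect_error(gradient_angle_mismatch(m, ramp(0)[1:5, 1:5]), "dim")
  roi <- matrix(FALSE, 30, 30)
  expect_error(gradient_angle_mismatch(m, m, roi = roi), "empty")
})

test_that("map_orientation recovers ramp angles to a fraction of a degree", {
  ramp <- function(angle, n = 40) {
    a <- angle * pi / 180
    outer(seq_len(n), rep(1, n)) * cos(a) +
      outer(rep(1, n), seq_len(n)) * sin(a)
  }
  for (ang in c(0, 10, 45, 90, 137.5)) {
    expect_equal(map_orientation(ramp(ang)), ang %% 180, tolerance = 0.5)
  }
  # axial: a ramp and its negation share one orientation
  expect_equal(map_orientation(-ramp(30)), 30, tolerance = 0.5)
  expect_error(map_orientation(ramp(0, n = 10)), "trim")
  expect_error(map_orientation(matrix(1, 40, 40)), "no gradient")
})

test_that("gaussian smoothing preserves constants and means", {
  m <- matrix(rnorm(400), 20, 20)
  expect_identical(xmodal:::gaussian_smooth(m, 0), m)
  c_m <- matrix(2.5, 10, 10)
  expect_equal(xmodal:::gaussian_smooth(c_m, 1.5), c_m, tolerance = 1e-12)
  sm <- xmodal:::gaussian_smooth(m, 2)
  expect_lt(sd(sm), sd(m))
})

test_that("enhancement map: zero when max-consistent, positive at overlap", {
  # the map compares normalized response patterns, so only spatial
  # deviations from the unisensory maximum are visible (a uniform gain is
  # removed by the [0, 1] normalization, by design)
  ny <- 20
  gauss2 <- function(cy, cx) {
    outer(seq_len(ny), seq_len(ny), function(i, j) {
      exp(-((i - cy)^2 + (j - cx)^2) / (2 * 2.5^2))
    })
  }
  vis_pat <- gauss2(10, 7)
  tac_pat <- gauss2(10, 13)
  grid <- stimulus_grid(delays = "sync")
  mk <- function(ms_pattern) {
    patterns <- lapply(seq_len(nrow(grid)), function(cc) {
      switch(grid$modality[cc],
             blank = matrix(0, ny, ny),
             visual = vis_pat,
             tactile = tac_pat,
             multisensory = ms_pattern)
    })
    wf <- zscore_and_reject(toy_movie(patterns, noise_sd = 0.05, seed = 11),
                            threshold = Inf)
    multisensory_enhancement_map(wf, window = c(0, 0.1))
  }
  # multisensory response equal to the unisensory maximum -> flat map
  em_max <- mk(pmax(vis_pat, tac_pat))
  expect_lt(max(abs(em_max)), 0.1)
  # additive responses -> positive where the two inputs overlap
  em_add <- mk(vis_pat + tac_pat)
  expect_gt(em_add[10, 10], 0.2)
  expect_gt(em_add[10, 10], max(abs(em_max)) + 0.1)
})

test_that("modality preference map separates the two gradients", {
  spec <- map_spec(ny = 30, nx = 30, n_trials = 3, amp = 6, noise_sd = 0.3,
                   offset_deg = 90)
  mv <- gen_widefield_movie(spec, seed = 8)
  gt <- attr(mv, "ground_truth")
  wf <- zscore_and_reject(mv, threshold = Inf)
  pm <- modality_preference_map(wf, window = c(0.1, 0.4))
  expect_true(all(pm >= -1 & pm <= 1))
  # perpendicular gradients: far along the visual axis only visual bumps
  # respond, far along the tactile axis only tactile bumps do
  vis_only <- abs(gt$vis_map) > 0.7 & abs(gt$tact_map) < 0.3
  tact_only <- abs(gt$tact_map) > 0.6 & abs(gt$vis_map) < 0.3
  expect_gt(mean(pm[vis_only]), mean(pm[tact_only]) + 0.2)
  p <- plot_map(pm)
  expect_s3_class(p, "ggplot")
})
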