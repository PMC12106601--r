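#' Lick-policy specification for synthetic Go/No-go sessions
#'
#' @param p_go,p_nogo,p_catch lick probability on go / no-go / catch
#'   trials.
#' @param breakpoint optional trial index after which the animal
#'   disengages: lick probabilities decay exponentially from there.
#' @param decay_tau disengagement decay constant in trials (default 30).
#' @param proportions trial-type proportions `c(go, nogo, catch)`; the
#'   training defaults are 30% go, 50% no-go, 20% catch.
#' @return list of class `xmodal_policy`.
#' @export
lick_policy <- function(p_go, p_nogo, p_catch, breakpoint = NULL,
                        decay_tau = 30,
                        proportions = c(go = 0.3, nogo = 0.5, catch = 0.2)) {
  stopifnot(all(c(p_go, p_nogo, p_catch) >= 0),
            all(c(p_go, p_nogo, p_catch) <= 1),
            abs(sum(proportions) - 1) < 1e-9)
  structure(list(p = c(go = p_go, "no-go" = p_nogo, catch = p_catch),
                 breakpoint = breakpoint, decay_tau = decay_tau,
                 proportions = proportions),
            class = "xmodal_policy")
}

#' Generate a synthetic Go/No-go session log
#'
#' Trial types are drawn i.i.d. at the policy's proportions and licks are
#' Bernoulli with the per-type probabilities (decayed after the
#' disengagement breakpoint, if any).  Deterministic per seed.
#'
#' @param policy an [lick_policy()] object.
#' @param n_trials number of trials.
#' @param seed random seed.
#' @return session-log tibble: `trial_index`, `type`, `lick`, plus the
#'   policy as attribute `ground_truth`.
#' @export
gen_session <- function(policy, n_trials, seed = 1) {
  set.seed(seed)
  types <- sample(c("go", "no-go", "catch"), n_trials, replace = TRUE,
                  prob = policy$proportions)
  p <- unname(policy$p[types])
  if (!is.null(policy$breakpoint)) {
    over <- pmax(0, seq_len(n_trials) - policy$breakpoint)
    p <- p * exp(-over / policy$decay_tau)
  }
  out <- tibble(trial_index = seq_len(n_trials), type = types,
                lick = runif(n_trials) < p)
  attr(out, "ground_truth") <- policy
  out
}

#' Specification of one synthetic neuron
#'
#' @param class `"visual"`, `"tactile"`, `"visuo-tactile"` or `"gated"`.
#' @param pref_vis preferred visual position (1-8).
#' @param pref_whisker preferred whisker (`"B2"` top or `"C2"` bottom).
#' @param amp_vis,amp_tact unimodal response amplitudes in z units
#'   (forced to 0 for classes without that modality; gated neurons have
#'   zero unimodal amplitude and respond with `amp_vis` in joint
#'   conditions).
#' @param vis_sigma visual tuning width in grid positions.
#' @param latency,width temporal response peak latency and Gaussian width
#'   in seconds.
#' @param ms_mode multisensory combination: `"max"`, `"enhanced"`,
#'   `"suppressed"`.
#' @param ms_effect fractional enhancement/suppression relative to the
#'   max-model prediction.
#' @param noise_sd additive Gaussian trial noise in z units (also the
#'   baseline sd, so traces are z-scored by construction).
#' @return one-row tibble.
#' @export
neuron_spec <- function(class = "visuo-tactile", pref_vis = 6,
                        pref_whisker = "B2", amp_vis = 3, amp_tact = 3,
                        vis_sigma = 1, latency = 0.3, width = 0.12,
                        ms_mode = "max", ms_effect = 0.5, noise_sd = 1) {
  stopifnot(class %in% c("visual", "tactile", "visuo-tactile", "gated"),
            pref_whisker %in% c("B2", "C2"),
            ms_mode %in% c("max", "enhanced", "suppressed"),
            noise_sd > 0)
  if (class == "visual") amp_tact <- 0
  if (class == "tactile") amp_vis <- 0
  tibble(class = class, pref_vis = pref_vis, pref_whisker = pref_whisker,
         amp_vis = amp_vis, amp_tact = amp_tact, vis_sigma = vis_sigma,
         latency = latency, width = width, ms_mode = ms_mode,
         ms_effect = ms_effect, noise_sd = noise_sd)
}

#' Generate a synthetic sparse-noise trial tensor
#'
#' Builds the 54-condition visuo-tactile trial tensor for a set of
#' programmed neurons: Gaussian positional tuning, Gaussian temporal
#' kernels (the tactile kernel shifted by 0.15 s in delayed conditions),
#' multisensory combination by bin-wise max of the unimodal mean traces
#' (optionally scaled up or down for enhanced/suppressed neurons), gated
#' neurons responding only in joint conditions, plus unit-variance
#' Gaussian noise so traces are baseline-z-scored by construction.
#'
#' @param specs tibble of [neuron_spec()] rows.
#' @param n_trials trials per condition.
#' @param seed random seed.
#' @param fs frame rate (default 30 Hz).
#' @param t_pre,t_post baseline and post-onset durations in seconds.
#' @param grid condition table (default the full [stimulus_grid()]).
#' @return an [trial_tensor()] with the specs stored as attribute
#'   `ground_truth`.
#' @export
gen_trial_tensor <- function(specs, n_trials = 10, seed = 1, fs = 30,
                             t_pre = 0.2, t_post = 1.0,
                             grid = stimulus_grid()) {
  stopifnot(nrow(specs) >= 1)
  set.seed(seed)
  times <- seq(-t_pre, t_post, by = 1 / fs)
  n_bin <- length(times)
  n_neuron <- nrow(specs)
  n_cond <- nrow(grid)
  mu <- array(0, c(n_neuron, n_cond, n_bin))

  kern <- function(latency, width) {
    k <- exp(-(times - latency)^2 / (2 * width^2))
    k[times <= 0] <- 0
    k
  }
  for (i in seq_len(n_neuron)) {
    s <- specs[i, ]
    kv <- kern(s$latency, s$width)
    for (cc in seq_len(n_cond)) {
      g <- grid[cc, ]
      kt <- kern(s$latency + if (g$delay == "delayed") 0.15 else 0, s$width)
      vis_tune <- if (g$vis_pos == 9) 0 else
        exp(-(g$vis_pos - s$pref_vis)^2 / (2 * s$vis_sigma^2))
      tact_tune <- if (g$whisker == "none") 0 else
        if (g$whisker == s$pref_whisker) 1 else 0.1
      v_trace <- s$amp_vis * vis_tune * kv
      t_trace <- s$amp_tact * tact_tune * kt
      mu[i, cc, ] <- switch(
        s$class,
        "visual" = v_trace,
        "tactile" = t_trace,
        "visuo-tactile" = {
          if (g$modality == "multisensory") {
            base <- pmax(v_trace, t_trace)
            fac <- switch(s$ms_mode, max = 1, enhanced = 1 + s$ms_effect,
                          suppressed = 1 - s$ms_effect)
            base * fac
          } else pmax(v_trace, t_trace)
        },
        "gated" = {
          if (g$modality == "multisensory") {
            s$amp_vis * vis_tune * tact_tune * kv
          } else numeric(n_bin)
        }
      )
    }
  }
  data <- array(rnorm(n_neuron * n_cond * n_trials * n_bin),
                c(n_neuron, n_cond, n_trials, n_bin))
  data <- sweep(data, 1, specs$noise_sd, "*")
  data <- data + aperm(array(rep(mu, n_trials),
                             c(n_neuron, n_cond, n_bin, n_trials)),
                       c(1, 2, 4, 3))
  out <- trial_tensor(data, conditions = grid, times = times)
  attr(out, "ground_truth") <- specs
  attr(out, "mu") <- mu
  out
}

#' Specification of a synthetic wide-field movie
#'
#' @param ny,nx frame size in pixels.
#' @param fs frame rate (Hz).
#' @param n_trials trials per condition.
#' @param n_baseline,n_response baseline and response frames per trial.
#' @param amp evoked bump amplitude.
#' @param noise_sd pixel noise sd.
#' @param grad_angle visual vertical-space gradient direction in degrees
#'   (0 = along the +row axis).
#' @param offset_deg angular offset of the tactile gradient relative to
#'   the visual one.
#' @param bump_sigma spatial bump sd as a fraction of the smaller frame
#'   side.
#' @param enhancement fractional multisensory enhancement over the
#'   max-unisensory prediction.
#' @param drift_amp amplitude of a slow sinusoidal drift.
#' @param artifact_amp amplitude of a 12 Hz illumination artifact.
#' @return list of class `xmodal_mapspec`.
#' @export
map_spec <- function(ny = 40, nx = 40, fs = 50, n_trials = 6,
                     n_baseline = 10, n_response = 25, amp = 5,
                     noise_sd = 1, grad_angle = 0, offset_deg = 0,
                     bump_sigma = 0.12, enhancement = 0, drift_amp = 0,
                     artifact_amp = 0) {
  stopifnot(offset_deg >= 0, offset_deg <= 180)
  structure(as.list(environment()), class = "xmodal_mapspec")
}

#' Generate a synthetic wide-field movie with programmed topography
#'
#' Condition-evoked Gaussian activity bumps are placed along a linear
#' topographic gradient per modality (the tactile gradient rotated by the
#' programmed angular offset); multisensory conditions evoke the pixelwise
#' maximum of the two unisensory bumps, optionally scaled up by
#' `enhancement`.  Optional slow drift and a 12 Hz artifact support
#' preprocessing tests.  The sparse-noise grid with synchronous delay is
#' used (27 conditions including unimodal, multisensory and blank).
#'
#' @param spec an [map_spec()] object.
#' @param seed random seed.
#' @return an [pixel_movie()]; attribute `ground_truth` holds the ideal
#'   linear gradient maps (`vis_map`, `tact_map`), bump centers, and the
#'   programmed offset.
#' @export
gen_widefield_movie <- function(spec, seed = 1) {
  set.seed(seed)
  grid <- stimulus_grid(delays = "sync")
  n_cond <- nrow(grid)
  frames_per_trial <- spec$n_baseline + spec$n_response
  n_trial_total <- n_cond * spec$n_trials
  n_frames <- n_trial_total * frames_per_trial
  ny <- spec$ny; nx <- spec$nx
  ctr <- c((ny + 1) / 2, (nx + 1) / 2)
  L <- 0.6 * min(ny, nx)
  sig <- spec$bump_sigma * min(ny, nx)

  dir_of <- function(angle_deg) {
    a <- angle_deg * pi / 180
    c(cos(a), sin(a)) # (row, col) direction
  }
  u_vis <- dir_of(spec$grad_angle)
  u_tact <- dir_of(spec$grad_angle + spec$offset_deg)

  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  bump_at <- function(center) {
    exp(-((rows - center[1])^2 + (cols - center[2])^2) / (2 * sig^2))
  }
  vis_center <- function(pos) {
    v <- (pos - 4.5) / 3.5
    ctr + v * (L / 2) * u_vis
  }
  tact_center <- function(whisker) {
    v <- if (whisker == "B2") 0.75 else -0.75
    ctr + v * (L / 2) * u_tact
  }

  cond_pattern <- vector("list", n_cond)
  for (cc in seq_len(n_cond)) {
    g <- grid[cc, ]
    vis <- if (g$vis_pos < 9) bump_at(vis_center(g$vis_pos)) else 0 * rows
    tac <- if (g$whisker != "none") bump_at(tact_center(g$whisker))
           else 0 * rows
    pat <- if (g$modality == "multisensory") {
      pmax(vis, tac) * (1 + spec$enhancement)
    } else pmax(vis, tac)
    cond_pattern[[cc]] <- spec$amp * pat
  }

  # temporal kernel over response frames, peaked mid-window
  tk <- exp(-(seq_len(spec$n_response) - spec$n_response / 2)^2 /
              (2 * (spec$n_response / 4)^2))

  # conditions are randomly interleaved across the session, as in an
  # actual recording; blocked ordering would let slow-trend removal leak
  # condition-correlated structure between neighbouring trials
  cond_seq <- sample(rep(seq_len(n_cond), each = spec$n_trials))
  frames <- array(rnorm(ny * nx * n_frames, sd = spec$noise_sd),
                  c(ny, nx, n_frames))
  epochs <- tibble(
    trial = seq_len(n_trial_total),
    condition = cond_seq,
    first_frame = (seq_len(n_trial_total) - 1) * frames_per_trial + 1
  )
  epochs$onset_frame <- epochs$first_frame + spec$n_baseline
  epochs$last_frame <- epochs$first_frame + frames_per_trial - 1
  for (k in seq_len(n_trial_total)) {
    pat <- cond_pattern[[epochs$condition[k]]]
    for (f in seq_len(spec$n_response)) {
      fr <- epochs$onset_frame[k] + f - 1
      frames[, , fr] <- frames[, , fr] + pat * tk[f]
    }
  }
  tt <- (seq_len(n_frames) - 1) / spec$fs
  extra <- spec$drift_amp * sin(2 * pi * tt / (n_frames / spec$fs)) +
    spec$artifact_amp * sin(2 * pi * 12 * tt)
  if (any(extra != 0)) {
    frames <- frames + rep(extra, each = ny * nx)
  }

  proj <- function(u) {
    p <- (rows - ctr[1]) * u[1] + (cols - ctr[2]) * u[2]
    p / (L / 2)
  }
  out <- pixel_movie(frames, epochs, grid, fs = spec$fs)
  attr(out, "ground_truth") <- list(
    vis_map = proj(u_vis), tact_map = proj(u_tact),
    offset_deg = spec$offset_deg, center = ctr, span = L, spec = spec
  )
  out
}
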