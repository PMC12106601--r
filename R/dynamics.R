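#' Initial network state
#'
#' Rates and private-noise states start at zero.  The network state is
#' re-initialized at the start of every trial (see [run_trial()]); the
#' 200 ms inter-stimulus interval then provides a noisy pre-stimulus
#' baseline.  Because the inter-areal loops settle into a strongly active
#' state once a subnetwork has been driven, carrying rates across trials
#' would leave the network saturated and insensitive to the next stimulus.
#'
#' @param connectome an [build_connectome()] object.
#' @return list of class `xmodal_state` with `r` (rates, one per unit), `x`
#'   (Ornstein-Uhlenbeck noise state, one per unit; only excitatory units
#'   receive `sigma_r * x` in their input) and time `t` in ms.
#' @export
network_state <- function(connectome) {
  n <- nrow(connectome$units)
  structure(list(r = numeric(n), x = numeric(n), t = 0),
            class = "xmodal_state")
}

#' One Euler-Maruyama step of the rate dynamics
#'
#' Updates rates according to
#' `tau_i dr_i = (-r_i + f(W r + I(t) + sigma_r x_i)) dt` with `tau_E` for
#' excitatory and `tau_I` for inhibitory units, and the private noise process
#' `dx_i = -x_i dt + sigma_x dW`.  `sigma_r` multiplies `x` for excitatory
#' units only.  The rate update uses the pre-update noise state; both are
#' advanced from the current values.
#'
#' This is the reference (dense-matrix) implementation; long experiments use
#' an exactly equivalent compiled kernel (see [run_experiment()]).
#'
#' @param state an [network_state()] object.
#' @param connectome an [build_connectome()] object.
#' @param I_t external input vector (see [stimulus_input()]), or a scalar 0.
#' @param params an [model_params()] object.
#' @param noise logical; set `FALSE` to force a deterministic (noiseless)
#'   step regardless of `sigma_x`.
#' @return the updated `xmodal_state`.
#' @export
step_dynamics <- function(state, connectome, I_t, params, noise = TRUE) {
  if (any(!is.finite(state$r)) || any(!is.finite(state$x))) {
    stop("non-finite network state")
  }
  dt <- params$dt
  is_E <- connectome$units$type == "E"
  tau <- ifelse(is_E, params$tau_E, params$tau_I)
  drive <- as.numeric(connectome$W %*% state$r) + I_t +
    params$sigma_r * state$x * is_E
  r_new <- state$r + dt / tau * (-state$r + transfer_function(drive, params))
  x_new <- if (noise) {
    state$x * (1 - dt) +
      params$sigma_x * sqrt(dt) * rnorm(length(state$x))
  } else {
    state$x * (1 - dt)
  }
  structure(list(r = r_new, x = x_new, t = state$t + dt),
            class = "xmodal_state")
}

#' Initial readout state with plastic weights
#'
#' Two abstract readout units (`z1` = go, `z2` = no-go) receive weighted
#' input from the excitatory units of V1, S1 and RL (in that order, bottom
#' then top subnetwork within each area).  Plastic weights are initialized
#' from a Gaussian with mean `w_init_mean` and sd `w_init_sd`, clipped to
#' `[0, W_max]` and renormalized per (readout x source area) block so block
#' means start exactly at `w_init_mean` (the value every later plasticity
#' update renormalizes back to).
#'
#' @param params an [model_params()] object.
#' @param silenced `"none"`, `"RL"` or `"AL"`; a silenced RL contributes no
#'   readout input (its weight block is zeroed and frozen).
#' @return list of class `xmodal_readout` with the `2 x 6*N_E` weight matrix
#'   `W_z`, readout values `z`, decision variables `delta`, reward value
#'   `c_r`, the source-block table `source_area`, and `frozen` (logical per
#'   column).
#' @export
readout_state <- function(params, silenced = "none") {
  n <- params$N_E
  src_area <- rep(c("V1", "S1", "RL"), each = 2 * n)
  W_z <- matrix(pmin(params$W_max,
                     pmax(0, rnorm(2 * 6 * n, params$w_init_mean,
                                   params$w_init_sd))),
                nrow = 2)
  for (a in unique(src_area)) {
    cols <- which(src_area == a)
    for (i in 1:2) {
      W_z[i, cols] <- renormalize_block(W_z[i, cols], params$w_init_mean,
                                        params$W_max)
    }
  }
  frozen <- rep(FALSE, 6 * n)
  if (identical(silenced, "RL")) {
    frozen[src_area == "RL"] <- TRUE
    W_z[, frozen] <- 0
  }
  structure(list(W_z = W_z, z = c(0, 0), delta = c(0, 0), c_r = 0,
                 source_area = src_area, frozen = frozen),
            class = "xmodal_readout")
}

#' Readout values from the current rates
#'
#' `z_i = alpha * sum_j W_z[i, j] r_j` over the excitatory units of V1, S1
#' and RL.
#'
#' @param readout an [readout_state()] object.
#' @param state an [network_state()] object.
#' @param connectome the matching connectome.
#' @param params an [model_params()] object.
#' @param alpha readout scaling; defaults to `params$alpha` (use
#'   `params$alpha_lesion` when RL is silenced).
#' @return numeric vector `c(z1, z2)`.
#' @export
readout_values <- function(readout, state, connectome, params,
                           alpha = params$alpha) {
  src <- readout_source_units(connectome)
  as.numeric(alpha * (readout$W_z %*% state$r[src]))
}

readout_source_units <- function(connectome) {
  u <- connectome$units
  which(u$area %in% c("V1", "S1", "RL") & u$type == "E")
}

#' Renormalize a weight block to a target mean under a cap
#'
#' Multiplicative rescale of a nonnegative weight vector so that its mean is
#' exactly `target`, with values capped at `w_max`.  When the plain rescale
#' would push weights past the cap, the scale for the remaining (uncapped)
#' weights is re-solved so the block mean still equals `target` exactly
#' (water-filling).  An all-zero block is returned unchanged.
#'
#' @param w nonnegative numeric vector.
#' @param target target mean.
#' @param w_max upper bound per weight.
#' @return rescaled vector with `mean(out) == target` (to numerical
#'   precision) unless `w` is all zero.
#' @export
renormalize_block <- function(w, target, w_max) {
  n <- length(w)
  if (all(w == 0)) return(w)
  free <- rep(TRUE, n)
  repeat {
    s_free <- sum(w[free])
    if (s_free <= 0) break
    s <- (target * n - w_max * sum(!free)) / s_free
    newly <- free & (s * w > w_max)
    if (!any(newly)) {
      w[free] <- s * w[free]
      w[!free] <- w_max
      break
    }
    free[newly] <- FALSE
  }
  w
}

#' Apply one reward-modulated Hebbian plasticity step
#'
#' Increments the plastic readout weights by `gamma * dt * z_tilde_i * r_j`,
#' clips to `[0, W_max]`, then renormalizes each (readout unit x source
#' area) block multiplicatively to mean `w_init_mean`.  `z_tilde` is the
#' readout value, with the reward feedback `c_r` already added to the chosen
#' readout after a decision.
#'
#' @param readout an [readout_state()] object.
#' @param rates rate vector of the readout source units (excitatory V1, S1,
#'   RL units, in readout column order).
#' @param params an [model_params()] object.
#' @param z_tilde length-2 vector of (possibly reward-modified) readout
#'   values; defaults to `readout$z`.
#' @return the updated `xmodal_readout`.
#' @export
apply_plasticity <- function(readout, rates, params, z_tilde = readout$z) {
  stopifnot(length(rates) == ncol(readout$W_z))
  W <- readout$W_z
  upd <- !readout$frozen
  W[, upd] <- W[, upd] +
    params$gamma * params$dt * outer(z_tilde, rates[upd])
  W <- pmin(pmax(W, 0), params$W_max)
  for (a in unique(readout$source_area)) {
    cols <- which(readout$source_area == a & !readout$frozen)
    if (length(cols) == 0) next
    for (i in 1:2) {
      W[i, cols] <- renormalize_block(W[i, cols], params$w_init_mean,
                                      params$W_max)
    }
  }
  readout$W_z <- W
  readout
}

#' Simulate one 400 ms trial (reference implementation)
#'
#' A trial is 200 ms without stimulation followed by a 200 ms step stimulus
#' `I(t) = c_s` to one subnetwork of one sensory area.  At stimulus onset the
#' decision variables are reset and then integrate the readouts in noise,
#' `d delta_i = z_i dt + sigma dW`.  The first decision variable to cross
#' `theta0` fixes the action (readout 1 = go, readout 2 = no-go); if neither
#' crosses, the action is no-go.  From the decision step to the end of the
#' stimulus the chosen readout is reward-modified, `z~ = z + c_r`, with
#' `c_r > 0` for correct and `c_r < 0` for incorrect decisions and
#' `|c_r|` equal to the difference between the readout at decision time and
#' its last value before the stimulus.  Plasticity runs at every stimulus
#' step.  Network rates and noise states are re-initialized to zero at the
#' start of the trial (the readout weights, of course, persist).
#'
#' @param state an [network_state()] object.
#' @param readout an [readout_state()] object.
#' @param connectome an [build_connectome()] object.
#' @param spec list with `area` (`"S1"` or `"V1"`), `location` (`"bottom"` or
#'   `"top"`) and `go_location` (the currently rewarded location).
#' @param params an [model_params()] object.
#' @param noise logical; `FALSE` disables all noise sources for this trial.
#' @return list with `result` (one-row tibble: `action`, `decision_time`,
#'   `correct`, `crossed`, `chosen`, `delta1`, `delta2`), `state`, `readout`.
#' @export
run_trial <- function(state, readout, connectome, spec, params,
                      noise = TRUE) {
  alpha <- if (identical(connectome$silenced, "RL")) params$alpha_lesion
           else params$alpha
  dt <- params$dt
  n_isi <- round(params$t_isi / dt)
  n_stim <- round(params$t_stim / dt)
  src <- readout_source_units(connectome)
  I0 <- numeric(nrow(connectome$units))
  I1 <- stimulus_input(connectome, spec$area, spec$location, params)

  state <- network_state(connectome)
  for (k in seq_len(n_isi)) {
    state <- step_dynamics(state, connectome, I0, params, noise = noise)
  }
  z_pre <- as.numeric(alpha * (readout$W_z %*% state$r[src]))

  delta <- c(0, 0)
  decided <- FALSE
  chosen <- NA_integer_
  decision_time <- NA_real_
  c_r <- 0
  is_go_stim <- identical(spec$location, spec$go_location)

  for (k in seq_len(n_stim)) {
    state <- step_dynamics(state, connectome, I1, params, noise = noise)
    z <- as.numeric(alpha * (readout$W_z %*% state$r[src]))
    dW <- if (noise) params$sigma * sqrt(dt) * rnorm(2) else c(0, 0)
    delta <- delta + z * dt + dW
    if (!decided && any(delta >= params$theta0)) {
      decided <- TRUE
      chosen <- which.max(delta)
      decision_time <- k * dt
      decision_correct <- if (chosen == 1L) is_go_stim else !is_go_stim
      c_r <- (if (decision_correct) 1 else -1) * abs(z[chosen] - z_pre[chosen])
    }
    z_tilde <- z
    if (decided) z_tilde[chosen] <- z_tilde[chosen] + c_r
    readout$z <- z
    readout$delta <- delta
    readout$c_r <- c_r
    readout <- apply_plasticity(readout, state$r[src], params,
                                z_tilde = z_tilde)
  }

  action <- if (decided && chosen == 1L) "go" else "no-go"
  correct <- (action == "go") == is_go_stim
  list(
    result = tibble(
      action = action, decision_time = decision_time, correct = correct,
      crossed = decided, chosen = chosen,
      delta1 = delta[1], delta2 = delta[2]
    ),
    state = state, readout = readout
  )
}
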