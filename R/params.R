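#' Default parameters of the four-area rate-network model
#'
#' Constructs the full parameter set of the recurrent excitatory/inhibitory
#' rate model of generalized sensorimotor learning: four areas (V1, S1, RL,
#' AL), each split into a top- and a bottom-preferring subnetwork of `N_E`
#' excitatory and `N_E` inhibitory units.  Defaults are the model's reference
#' values; any field can be overridden by name.
#'
#' Weight entries are magnitudes: contributions from inhibitory source units
#' enter the input sum with a negative sign.  `alpha` and `alpha_lesion`
#' scale the readout sum and default to `1/(6*N_E)` and `1/(2*N_E)`; they are
#' recomputed from `N_E` unless given explicitly.  Time constants and the
#' integration step `dt` are in milliseconds; a trial is `t_isi + t_stim` =
#' 400 ms.
#'
#' @param ... named overrides of any parameter field.
#'
#' @return An object of class `xmodal_params`: a named list with fields
#'   `W_EE`, `W_EI`, `W_IE`, `W_II` (recurrent weight magnitudes), `c_s`
#'   (stimulus amplitude), `rho`, `x0`, `beta` (transfer function), `N_E`,
#'   `alpha`, `alpha_lesion`, `gamma` (learning rate), `sigma` (decision
#'   noise), `sigma_x`, `sigma_r` (unit noise), `tau_E`, `tau_I`, `theta0`
#'   (decision threshold), `t_stim`, `t_isi`, `dt`, `ff_scale`,
#'   `fb_scale_RL`, `fb_scale_AL`, `W_max`, `w_init_mean`, `w_init_sd`.
#'
#' @examples
#' p <- model_params()
#' p$theta0
#' model_params(N_E = 10)$alpha  # 1/60
#' @export
model_params <- function(...) {
  p <- list(
    W_EE = 0.05, W_EI = 0.065, W_IE = 0.055, W_II = 0.045,
    c_s = 20, rho = 15, x0 = 20, beta = 30,
    N_E = 40,
    alpha = NULL, alpha_lesion = NULL,
    gamma = 4e-7,
    sigma = 0.08, sigma_x = sqrt(2), sigma_r = 0.75,
    tau_E = 20, tau_I = 10,
    theta0 = 80,
    t_stim = 200, t_isi = 200, dt = 1,
    ff_scale = 3.2, fb_scale_RL = 0.4, fb_scale_AL = 0.04,
    W_max = 1, w_init_mean = 0.5, w_init_sd = 0.1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  if (is.null(p$alpha)) p$alpha <- 1 / (6 * p$N_E)
  if (is.null(p$alpha_lesion)) p$alpha_lesion <- 1 / (2 * p$N_E)
  validate_params(p)
  structure(p, class = "xmodal_params")
}

validate_params <- function(p) {
  pos <- c("W_EE", "W_EI", "W_IE", "W_II", "c_s", "rho", "beta", "alpha",
           "alpha_lesion", "tau_E", "tau_I", "theta0", "t_stim", "t_isi",
           "dt", "W_max", "N_E")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("parameter '", f, "' must be a positive finite scalar")
    }
  }
  if (p$tau_E <= p$tau_I) stop("tau_E must exceed tau_I")
  if (p$dt > p$tau_I / 5) {
    stop("dt must be <= tau_I / 5 for a stable Euler integration")
  }
  invisible(p)
}

#' Saturating transfer function of the rate units
#'
#' The rate nonlinearity is a logistic sigmoid shifted so that f(0) = 0
#' exactly and thresholded at zero:
#' `f(x) = beta * max(0, sigmoid((x - x0)/rho) - 1/(1 + exp(x0/rho)))`.
#' It is bounded in `[0, beta * (1 - 1/(1 + exp(x0/rho))))`.
#'
#' @param x numeric vector of net inputs.
#' @param params an [model_params()] object (fields `beta`, `x0`, `rho`).
#' @return numeric vector of firing rates, same length as `x`.
#' @examples
#' p <- model_params()
#' transfer_function(0, p)    # exactly 0
#' transfer_function(p$x0, p) # mid-saturation
#' @export
transfer_function <- function(x, params) {
  offset <- plogis(-params$x0 / params$rho) # = 1/(1 + exp(x0/rho))
  params$beta * pmax(0, plogis((x - params$x0) / params$rho) - offset)
}

#' Configuration of a switch/silencing simulation experiment
#'
#' Describes one model experiment: `n_pre` tactile (S1-driven) training trials
#' followed by `n_post` visual (V1-driven) trials after a modality switch that
#' either preserves or reverses the rewarded spatial location, optionally with
#' one associative area disconnected throughout.
#'
#' @param switch `"preserve"` or `"reverse"`: whether the rewarded location
#'   (bottom during training) is kept or inverted after the modality switch.
#' @param silence `"none"`, `"RL"` or `"AL"`: area disconnected from the rest
#'   of the network (and, for RL, from the readouts) for the whole experiment.
#' @param n_pre,n_post number of trials before / after the switch.
#' @param n_runs number of independent simulated runs.
#' @param window sliding-window width (trials) for performance curves.
#' @param criterion accuracy criterion in (0.5, 1) used for time-to-criterion.
#' @param seed base random seed; run `k` uses `seed + k - 1`.
#' @return an object of class `xmodal_config` (named list).
#' @examples
#' experiment_config(switch = "reverse", n_runs = 2, seed = 1)
#' @export
experiment_config <- function(switch = c("preserve", "reverse"),
                              silence = c("none", "RL", "AL"),
                              n_pre = 100, n_post = 100,
                              n_runs = 20, window = 15, criterion = 0.75,
                              seed = 1) {
  switch <- match.arg(switch)
  silence <- match.arg(silence)
  stopifnot(n_runs >= 1, criterion > 0.5, criterion < 1,
            n_pre >= 0, n_post >= 1, window >= 1)
  structure(
    list(switch = switch, silence = silence, n_pre = n_pre, n_post = n_post,
         n_runs = n_runs, window = window, criterion = criterion,
         seed = seed),
    class = "xmodal_config"
  )
}
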