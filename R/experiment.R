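#' Run a switch/silencing experiment of the network model
#'
#' Simulates `n_runs` independent model runs.  Each run initializes fresh
#' plastic readout weights, performs `n_pre` S1-driven (tactile) trials with
#' the bottom location rewarded, then switches the stimulus to V1 (visual)
#' for `n_post` trials, keeping (`"preserve"`) or inverting (`"reverse"`) the
#' rewarded location.  Stimulus location is i.i.d. uniform over
#' \{bottom, top\} on every trial.  With `silence = "RL"` the readout
#' scaling `alpha` is replaced by `alpha_lesion` and the silenced area is
#' fully disconnected.  Network state is re-initialized at every trial
#' start; the plastic readout weights persist across the whole run.
#'
#' Uses the compiled simulation kernel; run `k` is seeded with
#' `config$seed + k - 1` so any run can be reproduced in isolation.
#'
#' @param config an [experiment_config()] object.
#' @param params an [model_params()] object.
#' @param noise logical; `FALSE` turns off all stochastic terms (used for
#'   numerical checks).
#' @return an object of class `xmodal_experiment`: a tibble with one row per
#'   trial (`run`, `trial`, `phase` = "pre"/"post", `trial_in_phase`, `area`,
#'   `location`, `go_location`, `action`, `correct`, `crossed`,
#'   `decision_time`, `delta1`, `delta2`) with the config and params stored
#'   as attributes.
#' @examples
#' \donttest{
#' cfg <- experiment_config(n_runs = 2, n_pre = 10, n_post = 10, seed = 1)
#' ex <- run_experiment(cfg, model_params())
#' dplyr::count(ex, run, phase)
#' }
#' @export
run_experiment <- function(config, params = model_params(), noise = TRUE) {
  stopifnot(inherits(config, "xmodal_config"),
            inherits(params, "xmodal_params"))
  connectome <- build_connectome(params, silenced = config$silence)
  blocks <- connectome_blocks(connectome, params)
  alpha <- if (config$silence == "RL") params$alpha_lesion else params$alpha
  n_total <- config$n_pre + config$n_post
  post_go <- if (config$switch == "preserve") 1L else 2L

  runs <- lapply(seq_len(config$n_runs), function(k) {
    set.seed(config$seed + k - 1)
    loc <- sample(c(1L, 2L), n_total, replace = TRUE)
    area <- rep(c(2L, 1L), c(config$n_pre, config$n_post)) # S1 then V1
    go <- rep(c(1L, post_go), c(config$n_pre, config$n_post))
    readout <- readout_state(params, silenced = config$silence)
    sim <- simulate_trials_cpp(
      unclass(params), blocks$EE, blocks$EI, blocks$IE, blocks$II,
      blocks$AEE, blocks$AEI, blocks$AIE, blocks$AII,
      params$N_E, readout$W_z, readout$frozen,
      area, loc, go, alpha, noise
    )
    tibble(
      run = k,
      trial = seq_len(n_total),
      phase = rep(c("pre", "post"), c(config$n_pre, config$n_post)),
      trial_in_phase = c(seq_len(config$n_pre), seq_len(config$n_post)),
      area = c("V1", "S1")[area],
      location = c("bottom", "top")[loc],
      go_location = c("bottom", "top")[go],
      action = c("no-go", "go")[sim$action + 1L],
      correct = as.logical(sim$correct),
      crossed = as.logical(sim$crossed),
      decision_time = sim$decision_time,
      delta1 = sim$delta1, delta2 = sim$delta2
    )
  })
  out <- dplyr::bind_rows(runs)
  attr(out, "config") <- config
  attr(out, "params") <- params
  class(out) <- c("xmodal_experiment", class(out))
  out
}

#' Sliding-window performance of model runs
#'
#' Computes, in a trailing window of `window` trials (separately within the
#' pre- and post-switch phases of each run), the conditional go
#' probabilities `P(go | bottom)` and `P(go | top)` and the accuracy
#' `P(correct)`.  With `mode = "outcome"` correctness is the recorded trial
#' outcome (go to the rewarded location, no-go otherwise); with
#' `mode = "readout"` it is the comparison of the two decision variables
#' (readout 1 larger on rewarded-location trials and readout 2 larger
#' otherwise).
#'
#' @param outcomes an [run_experiment()] result (or any tibble with columns
#'   `run`, `phase`, `trial_in_phase`, `location`, `go_location`, `action`,
#'   `correct`, and `delta1`/`delta2` for the readout mode).
#' @param window sliding-window width in trials.
#' @param mode accuracy estimator, `"outcome"` (default) or `"readout"`.
#' @return a tibble of class `xmodal_performance`: `run`, `phase`,
#'   `window_end` (index of the last trial in the window, within phase),
#'   `p_go_bottom`, `p_go_top`, `accuracy`.  Conditional probabilities are
#'   `NA` when the window contains no trial of that class.
#' @export
model_performance <- function(outcomes, window = 15,
                              mode = c("outcome", "readout")) {
  mode <- match.arg(mode)
  stopifnot(window >= 1)
  if (window > max(outcomes$trial_in_phase)) {
    stop("window wider than the number of trials in a phase")
  }
  df <- as_tibble(outcomes)
  if (mode == "readout") {
    df$correct <- ifelse(df$location == df$go_location,
                         df$delta1 > df$delta2, df$delta2 > df$delta1)
  }
  df$went <- df$action == "go"
  out <- df |>
    dplyr::group_by(.data$run, .data$phase) |>
    dplyr::arrange(.data$trial_in_phase, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < window) return(tibble())
      ends <- window:n
      win_stat <- function(end) {
        w <- d[(end - window + 1):end, ]
        bot <- w$location == "bottom"
        tibble(
          window_end = end,
          p_go_bottom = if (any(bot)) mean(w$went[bot]) else NA_real_,
          p_go_top = if (any(!bot)) mean(w$went[!bot]) else NA_real_,
          accuracy = mean(w$correct)
        )
      }
      dplyr::bind_rows(lapply(ends, win_stat))
    }) |>
    dplyr::ungroup()
  class(out) <- c("xmodal_performance", class(out))
  out
}

#' Trials to reach the relearning criterion after the switch
#'
#' For each run, scans the post-switch sliding-window accuracy trace and
#' returns the index (within-phase trial number of the window's last trial)
#' of the first window whose accuracy reaches `criterion`; `NA` if the
#' criterion is never reached within the run.
#'
#' @param trace an [model_performance()] tibble.
#' @param criterion accuracy criterion (default 0.75).
#' @param phase which phase to scan (default `"post"`).
#' @return tibble with one row per run: `run`, `time_to_criterion`.
#' @export
time_to_criterion <- function(trace, criterion = 0.75, phase = "post") {
  trace |>
    dplyr::filter(.data$phase == !!phase) |>
    dplyr::group_by(.data$run) |>
    dplyr::arrange(.data$window_end, .by_group = TRUE) |>
    dplyr::summarise(
      time_to_criterion = {
        hit <- which(.data$accuracy >= criterion)
        if (length(hit) == 0) NA_real_ else .data$window_end[hit[1]]
      },
      .groups = "drop"
    )
}

#' @export
tidy.xmodal_experiment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Per-run summary of a model experiment
#'
#' @param x an [run_experiment()] result.
#' @param ... passed on; `window` and `criterion` default to the values in
#'   the experiment's config.
#' @return tibble with one row per run: accuracy in each phase, maximum
#'   post-switch windowed accuracy, and time to criterion.
#' @export
glance.xmodal_experiment <- function(x, ...) {
  cfg <- attr(x, "config")
  perf <- model_performance(x, window = cfg$window)
  ttc <- time_to_criterion(perf, criterion = cfg$criterion)
  base <- as_tibble(x) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      accuracy_pre = mean(.data$correct[.data$phase == "pre"]),
      accuracy_post = mean(.data$correct[.data$phase == "post"]),
      .groups = "drop"
    )
  peak <- perf |>
    dplyr::filter(.data$phase == "post") |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(max_post_accuracy = max(.data$accuracy),
                     .groups = "drop")
  dplyr::left_join(dplyr::left_join(base, peak, by = "run"), ttc, by = "run")
}

#' @export
autoplot.xmodal_performance <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("p_go_bottom", "p_go_top", "accuracy"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(
      t = ifelse(.data$phase == "post", .data$window_end,
                 .data$window_end - max(.data$window_end[.data$phase == "pre"]))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$measure,
                                   group = interaction(.data$run,
                                                       .data$measure))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "trial relative to modality switch", y = NULL,
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
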