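#' Validate and normalize a Go/No-go session log
#'
#' A session log is a tibble with one ordered row per trial and at least the
#' columns `type` (one of `"go"`, `"no-go"`, `"catch"`) and `lick`
#' (logical).  Extra columns (e.g. `trial_index`, `task`, `rewarded_side`)
#' are preserved.
#'
#' @param log data frame of trials.
#' @return the log as a tibble with normalized types.
#' @export
as_session_log <- function(log) {
  log <- as_tibble(log)
  if (nrow(log) == 0) stop("empty session log")
  stopifnot(all(c("type", "lick") %in% names(log)))
  log$type <- as.character(log$type)
  bad <- setdiff(unique(log$type), c("go", "no-go", "catch"))
  if (length(bad) > 0) stop("unknown trial type(s): ",
                            paste(bad, collapse = ", "))
  log$lick <- as.logical(log$lick)
  if (anyNA(log$lick)) stop("lick column contains NA")
  log
}

#' Windowed conditional lick probabilities
#'
#' For every trial index and every stimulus class, the fraction of licked
#' trials among presentations of that class within a sliding window of
#' `window` trials.  The default window is trailing (ends at the current
#' trial); `align = "center"` centers it instead.  Windows containing no
#' presentation of a class yield `NA`, not 0.
#'
#' @param log a session log (see [as_session_log()]).
#' @param window window width in trials (default 60).
#' @param align `"trailing"` (default) or `"center"`.
#' @return tibble of class `xmodal_lick_curves`: `trial`, `type`, `p_lick`,
#'   `n_in_window`, with the window width as attribute.
#' @examples
#' log <- gen_session(lick_policy(1, 0, 0), n_trials = 50, seed = 1)
#' head(conditional_lick_probability(log, window = 10))
#' @export
conditional_lick_probability <- function(log, window = 60,
                                         align = c("trailing", "center")) {
  align <- match.arg(align)
  log <- as_session_log(log)
  stopifnot(window >= 1)
  n <- nrow(log)
  types <- c("go", "no-go", "catch")
  rows <- lapply(seq_len(n), function(t) {
    if (align == "trailing") {
      lo <- max(1, t - window + 1); hi <- t
    } else {
      half <- (window - 1) / 2
      lo <- max(1, ceiling(t - half)); hi <- min(n, floor(t + half))
    }
    w <- log[lo:hi, ]
    tibble(
      trial = t,
      type = types,
      n_in_window = vapply(types, function(ty) sum(w$type == ty), 0L,
                           USE.NAMES = FALSE),
      p_lick = vapply(types, function(ty) {
        sel <- w$type == ty
        if (!any(sel)) NA_real_ else mean(w$lick[sel])
      }, 0.0, USE.NAMES = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)[, c("trial", "type", "p_lick", "n_in_window")]
  attr(out, "window") <- window
  class(out) <- c("xmodal_lick_curves", class(out))
  out
}

confusion_rates <- function(log) {
  log <- as_session_log(log)
  go <- log$type == "go"; ng <- log$type == "no-go"; ca <- log$type == "catch"
  list(
    hit = if (any(go)) mean(log$lick[go]) else NA_real_,
    fa = if (any(ng)) mean(log$lick[ng]) else NA_real_,
    catch_lick = if (any(ca)) mean(log$lick[ca]) else NA_real_,
    n_go = sum(go), n_nogo = sum(ng), n_catch = sum(ca)
  )
}

#' Discrimination performance
#'
#' The average of the hit rate (lick probability on Go trials) and the
#' correct-reject rate (1 - false-alarm rate on No-go trials):
#' `(Hit + (1 - FA)) / 2`.  By construction insensitive to the proportion of
#' Go and No-go trials.
#'
#' @param log a session log with at least one go and one no-go trial.
#' @return a single fraction in \[0, 1\].
#' @examples
#' log <- tibble::tibble(
#'   type = rep(c("go", "no-go"), c(10, 10)),
#'   lick = rep(c(TRUE, FALSE), c(9, 10))
#' )
#' discrimination_performance(log)  # (0.9 + 1)/2
#' @export
discrimination_performance <- function(log) {
  cr <- confusion_rates(log)
  if (cr$n_go == 0 || cr$n_nogo == 0) {
    stop("discrimination requires at least one go and one no-go trial")
  }
  (cr$hit + (1 - cr$fa)) / 2
}

#' Detection performance
#'
#' The maximum of the Go detection rate (mean of the hit rate and the catch
#' correct-reject rate) and the No-go detection rate (mean of the
#' false-alarm rate and the catch correct-reject rate).
#'
#' @param log a session log with at least one catch trial (and go/no-go
#'   trials for the corresponding rates).
#' @return a single fraction in \[0, 1\].
#' @export
detection_performance <- function(log) {
  cr <- confusion_rates(log)
  if (cr$n_catch == 0) stop("detection requires at least one catch trial")
  if (cr$n_go == 0 || cr$n_nogo == 0) {
    stop("detection requires go and no-go trials")
  }
  catch_cr <- 1 - cr$catch_lick
  max((cr$hit + catch_cr) / 2, (cr$fa + catch_cr) / 2)
}

#' Session end (disengagement) index
#'
#' The session is considered over at the first trial, after the peak of the
#' Go conditional-lick curve, where that curve drops strictly below 66% of
#' its maximum; if it never does, the session runs to its last trial.
#'
#' @param curves an [conditional_lick_probability()] result (or any tibble
#'   with `trial`, `type`, `p_lick`).
#' @param threshold fraction of the curve maximum (default 0.66).
#' @return the session-end trial index.
#' @export
session_end_index <- function(curves, threshold = 0.66) {
  go <- dplyr::filter(as_tibble(curves), .data$type == "go",
                      !is.na(.data$p_lick))
  if (nrow(go) == 0) stop("Go lick curve is undefined everywhere")
  peak_at <- go$trial[which.max(go$p_lick)]
  cutoff <- threshold * max(go$p_lick)
  after <- go[go$trial > peak_at, ]
  drop <- which(after$p_lick < cutoff)
  if (length(drop) == 0) max(dplyr::last(go$trial)) else after$trial[drop[1]]
}

#' Switch-aligned average of session performances across mice
#'
#' Realigns per-session values around the session of task switch and
#' averages across mice at each relative session index.
#'
#' @param sessions tibble with columns `mouse`, `session_rel` (session index
#'   relative to the switch, 0 = first post-switch session) and `value` (a
#'   per-session performance or lick probability, computed on engaged trials).
#' @return tibble: `session_rel`, `mean`, `sem` (`NA` for a single mouse),
#'   `n_mice`.
#' @export
switch_aligned_average <- function(sessions) {
  stopifnot(all(c("mouse", "session_rel", "value") %in% names(sessions)))
  as_tibble(sessions) |>
    dplyr::group_by(.data$session_rel) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n())
            else NA_real_,
      n_mice = dplyr::n(),
      .groups = "drop"
    )
}

#' Post-switch learning rate
#'
#' Least-squares slope of session performance over exactly three consecutive
#' sessions after a task switch, in performance units per session.
#'
#' @param session_performances numeric vector of exactly 3 values.
#' @return the fitted slope.
#' @examples
#' learning_rate(c(0.5, 0.6, 0.7))  # 0.1
#' @export
learning_rate <- function(session_performances) {
  if (length(session_performances) != 3) {
    stop("learning_rate expects exactly 3 consecutive session values")
  }
  x <- seq_along(session_performances)
  unname(coef(lm(session_performances ~ x))[2])
}

#' @export
autoplot.xmodal_lick_curves <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$trial, y = .data$p_lick,
                               colour = .data$type)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "trial", y = "conditional lick probability",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}
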