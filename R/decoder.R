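#' Train the Bayesian top/bottom population decoder
#'
#' Training computes, for each neuron, the average tuning (stimulus-
#' triggered mean feature) for the "top" and "bottom" stimulus categories
#' over the training trials, floors it at `epsilon`, and stores its
#' logarithm.  Decoding (see [decode()]) evaluates, per trial, the Poisson-
#' form log-likelihood `sum_j f_j * log(t_j(class)) - sum_j t_j(class)`,
#' the second term being the corrective bias proportional to the sum of
#' the tuning curves.
#'
#' @param features `trials x neurons` numeric matrix (typically integrated
#'   window responses, min-max normalized per neuron on training data).
#' @param labels character vector (`"top"`/`"bottom"`), one per trial.
#' @param epsilon floor applied to tuning values before the log.
#' @return object of class `xmodal_decoder`: list with `tuning` and
#'   `log_tuning` (`2 x neurons`, rows "top", "bottom"), `classes`,
#'   `epsilon`.
#' @export
train_bayes_decoder <- function(features, labels, epsilon = 1e-3) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  classes <- c("top", "bottom")
  if (!all(labels %in% classes)) stop("labels must be 'top' or 'bottom'")
  if (!all(classes %in% labels)) {
    stop("both classes must be present in the training data")
  }
  tuning <- rbind(
    top = colMeans(features[labels == "top", , drop = FALSE]),
    bottom = colMeans(features[labels == "bottom", , drop = FALSE])
  )
  tuning <- pmax(tuning, epsilon)
  structure(list(tuning = tuning, log_tuning = log(tuning),
                 classes = classes, epsilon = epsilon),
            class = "xmodal_decoder")
}

#' Decode stimulus category from population features
#'
#' Assigns to each trial the class with the highest log-likelihood under
#' the trained decoder; exact ties are broken uniformly at random (using
#' the current RNG state, so seeded by the caller).
#'
#' @param model an [train_bayes_decoder()] object.
#' @param features `trials x neurons` matrix (or a single trial vector)
#'   matching the model's neuron count.
#' @return tibble: `pred`, `ll_top`, `ll_bottom`.
#' @export
decode <- function(model, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$tuning)) {
    stop("feature length does not match the decoder")
  }
  ll <- features %*% t(model$log_tuning)
  ll <- sweep(ll, 2, rowSums(model$tuning), "-")
  pred <- vapply(seq_len(nrow(ll)), function(i) {
    if (ll[i, 1] == ll[i, 2]) sample(model$classes, 1)
    else model$classes[which.max(ll[i, ])]
  }, "")
  tibble(pred = pred, ll_top = unname(ll[, 1]), ll_bottom = unname(ll[, 2]))
}

#' @export
tidy.xmodal_decoder <- function(x, ...) {
  n <- ncol(x$tuning)
  tibble(
    neuron = rep(seq_len(n), 2),
    class = rep(x$classes, each = n),
    tuning = c(x$tuning[1, ], x$tuning[2, ]),
    log_tuning = c(x$log_tuning[1, ], x$log_tuning[2, ])
  )
}

#' @export
glance.xmodal_decoder <- function(x, ...) {
  tibble(n_neurons = ncol(x$tuning), epsilon = x$epsilon)
}

#' Per-neuron, per-category decoder feature sets from a trial tensor
#'
#' For each neuron and each stimulus category ("top", "bottom") of the
#' requested modality, extracts the per-trial feature: the z-score response
#' integrated over the response window at the neuron's most responsive
#' stimulus position within the category (visual top = positions 5-8,
#' bottom = 1-4; tactile top = B2, bottom = C2), pooling unimodal trials
#' over both delay labels.
#'
#' @param tensor an [trial_tensor()] object.
#' @param modality `"tactile"` or `"visual"`.
#' @param params an [analysis_params()] object.
#' @return list with `top` and `bottom`: `trials x neurons` feature
#'   matrices.
#' @export
decoder_features <- function(tensor, modality = c("tactile", "visual"),
                             params = analysis_params()) {
  modality <- match.arg(modality)
  grid <- tensor_conditions(tensor)
  win <- response_window_bins(tensor, params$window)
  n_neuron <- dim(tensor)[1]
  cat_col <- if (modality == "visual") grid$visual_category
             else grid$tactile_category
  uni <- grid$modality == modality

  feat_class <- function(cat) {
    conds <- grid$condition[uni & !is.na(cat_col) & cat_col == cat]
    # per neuron: most responsive condition (position) within the category
    mats <- lapply(conds, function(cc) {
      m <- tensor[, cc, , win, drop = FALSE]
      dim(m) <- dim(m)[c(1, 3, 4)]
      apply(m, c(1, 2), sum) # neuron x trial integrated response
    })
    # pool trials across delay labels of the same position
    pos_of <- grid$vis_pos[match(conds, grid$condition)]
    whisker_of <- grid$whisker[match(conds, grid$condition)]
    key <- if (modality == "visual") pos_of else whisker_of
    pooled <- lapply(unique(key), function(k) {
      do.call(cbind, mats[key == k])
    })
    best <- vapply(seq_len(n_neuron), function(i) {
      which.max(vapply(pooled, function(m) mean(m[i, ]), 0.0))
    }, 0L)
    n_tr <- min(vapply(pooled, ncol, 0L))
    out <- matrix(NA_real_, n_tr, n_neuron)
    for (i in seq_len(n_neuron)) {
      out[, i] <- pooled[[best[i]]][i, seq_len(n_tr)]
    }
    out
  }
  list(top = feat_class("top"), bottom = feat_class("bottom"))
}

minmax_train_test <- function(train, test) {
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  scale01 <- function(m) {
    m <- sweep(m, 2, lo, "-")
    m <- sweep(m, 2, rng, "/")
    pmin(pmax(m, 0), 1)
  }
  list(train = scale01(train), test = scale01(test))
}

#' Within- and cross-modal decoding accuracy versus pool size
#'
#' Trains the Bayesian classifier on one modality and tests it both on
#' held-out trials of the same modality (fourfold cross-validation) and on
#' all trials of the other modality.  For each pool size, neuron pools are
#' resampled without replacement `n_resample` times; within each
#' resampling, trials are randomly reordered within class per neuron to
#' remove noise correlations, and feature min-max normalization constants
#' are taken from the training folds only.
#'
#' @param tensor an [trial_tensor()] object.
#' @param train_modality,test_modality `"tactile"` or `"visual"`.
#' @param pool_sizes integer vector of population sizes.
#' @param n_resample pool resamplings per size (default 40).
#' @param folds cross-validation folds (default 4).
#' @param params an [analysis_params()] object.
#' @param neurons optional neuron subset to draw pools from.
#' @param shuffle_labels permute trial labels (control analysis).
#' @return tibble of class `xmodal_decoding`: `pool_size`, `resample`,
#'   `within_accuracy`, `cross_accuracy` (fold-averaged).
#' @export
crossmodal_accuracy <- function(tensor, train_modality = "tactile",
                                test_modality = "visual",
                                pool_sizes = NULL, n_resample = NULL,
                                folds = NULL,
                                params = analysis_params(),
                                neurons = NULL,
                                shuffle_labels = FALSE) {
  if (is.null(pool_sizes)) pool_sizes <- params$pool_sizes
  if (is.null(n_resample)) n_resample <- params$resamplings
  if (is.null(folds)) folds <- params$folds
  tr <- decoder_features(tensor, train_modality, params)
  te <- decoder_features(tensor, test_modality, params)
  n_neuron <- ncol(tr$top)
  pool_from <- if (is.null(neurons)) seq_len(n_neuron) else neurons
  if (max(pool_sizes) > length(pool_from)) {
    stop("pool size exceeds the available population")
  }
  n_tr <- min(nrow(tr$top), nrow(tr$bottom))
  fold_of <- rep_len(seq_len(folds), n_tr)

  one <- function(pool_size, rs) {
    pool <- sample(pool_from, pool_size)
    # random reorder of trials within class, per neuron
    reorder <- function(m) {
      apply(m[, pool, drop = FALSE], 2, function(col) sample(col))
    }
    ftr <- list(top = reorder(tr$top)[seq_len(n_tr), , drop = FALSE],
                bottom = reorder(tr$bottom)[seq_len(n_tr), , drop = FALSE])
    fte <- list(top = reorder(te$top), bottom = reorder(te$bottom))
    test_x <- rbind(fte$top, fte$bottom)
    test_y <- rep(c("top", "bottom"), c(nrow(fte$top), nrow(fte$bottom)))
    if (shuffle_labels) test_y <- sample(test_y)
    acc_w <- acc_x <- numeric(folds)
    for (f in seq_len(folds)) {
      tr_idx <- fold_of != f
      x_train <- rbind(ftr$top[tr_idx, , drop = FALSE],
                       ftr$bottom[tr_idx, , drop = FALSE])
      y_train <- rep(c("top", "bottom"), each = sum(tr_idx))
      if (shuffle_labels) y_train <- sample(y_train)
      x_test <- rbind(ftr$top[!tr_idx, , drop = FALSE],
                      ftr$bottom[!tr_idx, , drop = FALSE])
      y_test <- rep(c("top", "bottom"), each = sum(!tr_idx))
      if (shuffle_labels) y_test <- sample(y_test)
      nm1 <- minmax_train_test(x_train, x_test)
      nm2 <- minmax_train_test(x_train, test_x)
      model <- train_bayes_decoder(nm1$train, y_train)
      acc_w[f] <- mean(decode(model, nm1$test)$pred == y_test)
      acc_x[f] <- mean(decode(model, nm2$test)$pred == test_y)
    }
    tibble(pool_size = pool_size, resample = rs,
           within_accuracy = mean(acc_w), cross_accuracy = mean(acc_x))
  }
  out <- dplyr::bind_rows(lapply(pool_sizes, function(ps) {
    dplyr::bind_rows(lapply(seq_len(n_resample), function(rs) one(ps, rs)))
  }))
  class(out) <- c("xmodal_decoding", class(out))
  out
}

#' @export
autoplot.xmodal_decoding <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("within_accuracy", "cross_accuracy"),
                        names_to = "test", values_to = "accuracy") |>
    dplyr::group_by(.data$pool_size, .data$test) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sem = sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pool_size, y = .data$mean,
                                   colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem,
                                      fill = .data$test),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "neurons in decoding pool", y = "decoding accuracy",
                  colour = NULL, fill = NULL) +
    ggplot2::ylim(0, 1)
}
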