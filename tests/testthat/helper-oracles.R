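# Brute-force reference implementations shared by unit and acceptance tests.

# Naive-Bayes decoder oracle: per-class log-likelihood computed with plain
# loops, independent of the package's matrix code path.
oracle_bayes <- function(features, labels, test, epsilon = 1e-3) {
  classes <- c("top", "bottom")
  tuning <- sapply(seq_len(ncol(features)), function(j) {
    c(mean(features[labels == "top", j]), mean(features[labels == "bottom", j]))
  })
  tuning <- matrix(pmax(tuning, epsilon), nrow = 2)
  ll <- matrix(NA_real_, nrow(test), 2)
  for (i in seq_len(nrow(test))) {
    for (k in 1:2) {
      acc <- 0
      for (j in seq_len(ncol(test))) {
        acc <- acc + test[i, j] * log(tuning[k, j])
      }
      ll[i, k] <- acc - sum(tuning[k, ])
    }
  }
  colnames(ll) <- classes
  ll
}

# Confusion-count behavior oracle computed with integer counts only.
oracle_confusion <- function(log) {
  go <- log$type == "go"
  ng <- log$type == "no-go"
  ca <- log$type == "catch"
  list(
    hit = sum(log$lick & go) / sum(go),
    fa = sum(log$lick & ng) / sum(ng),
    catch_lick = sum(log$lick & ca) / sum(ca),
    n_go = sum(go), n_nogo = sum(ng), n_catch = sum(ca)
  )
}

# Random session log guaranteed to contain every trial type.
random_log <- function(n, seed) {
  set.seed(seed)
  types <- c("go", "no-go", "catch",
             sample(c("go", "no-go", "catch"), n - 3, replace = TRUE))
  tibble::tibble(type = sample(types), lick = runif(n) < runif(1))
}

# Damped fixed-point iteration oracle for the noiseless rate equations:
# solves r = f(W r + I) by under-relaxed iteration, independently of the
# time-stepping code.
oracle_fixed_point <- function(connectome, I_t, params, eta = 0.05,
                               tol = 1e-12, max_iter = 2e5) {
  n <- nrow(connectome$units)
  r <- numeric(n)
  for (k in seq_len(max_iter)) {
    target <- transfer_function(as.numeric(connectome$W %*% r) + I_t, params)
    r_new <- (1 - eta) * r + eta * target
    if (max(abs(r_new - r)) < tol) return(r_new)
    r <- r_new
  }
  stop("fixed-point oracle did not converge")
}

# Congruent bimodal population: top-preferring neurons pair visual
# positions 5-8 with whisker B2, bottom-preferring pair 1-4 with C2.
congruent_specs <- function(n_neuron, amp = 2.5, noise_sd = 1) {
  dplyr::bind_rows(lapply(seq_len(n_neuron), function(k) {
    top <- k %% 2 == 0
    neuron_spec("visuo-tactile",
                pref_vis = if (top) sample(5:8, 1) else sample(1:4, 1),
                pref_whisker = if (top) "B2" else "C2",
                amp_vis = amp, amp_tact = amp, noise_sd = noise_sd)
  }))
}
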