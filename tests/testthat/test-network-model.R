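test_that("model_params defaults, overrides and validation", {
  p <- model_params()
  expect_s3_class(p, "xmodal_params")
  expect_equal(p$N_E, 40)
  expect_equal(p$alpha, 1 / 240)
  expect_equal(p$alpha_lesion, 1 / 80)
  expect_equal(model_params(N_E = 10)$alpha, 1 / 60)
  p2 <- model_params(theta0 = 50, alpha = 0.1)
  expect_equal(p2$theta0, 50)
  expect_equal(p2$alpha, 0.1)
  expect_error(model_params(not_a_param = 1), "unknown parameter")
  expect_error(model_params(tau_E = 5, tau_I = 10), "tau_E must exceed")
  expect_error(model_params(dt = 5), "dt must be")
  expect_error(model_params(theta0 = -1), "positive finite")
})

test_that("transfer function is zero at zero, monotone and saturating", {
  p <- model_params()
  expect_identical(transfer_function(0, p), 0)
  expect_identical(transfer_function(-100, p), 0)
  x <- seq(-50, 400, by = 0.5)
  f <- transfer_function(x, p)
  expect_true(all(diff(f) >= 0))
  f_max <- p$beta * (1 - plogis(-p$x0 / p$rho))
  expect_lt(max(f), f_max)
  expect_equal(transfer_function(1e9, p), f_max, tolerance = 1e-12)
})

test_that("unit table enumerates areas, subnets and cell types", {
  p <- model_params(N_E = 3)
  u <- unit_table(p)
  expect_equal(nrow(u), 4 * 2 * 2 * 3)
  expect_equal(sort(unique(u$block)), 1:8)
  counts <- dplyr::count(u, area, subnet, type)
  expect_true(all(counts$n == 3))
  expect_equal(u$unit, seq_len(nrow(u)))
})

test_that("connectome has the printed block structure", {
  p <- model_params(N_E = 4)
  con <- build_connectome(p)
  u <- con$units
  W <- con$W
  e_b <- u$area == "V1" & u$subnet == "bottom" & u$type == "E"
  i_b <- u$area == "V1" & u$subnet == "bottom" & u$type == "I"
  expect_true(all(W[e_b, e_b] == p$W_EE))
  expect_true(all(W[e_b, i_b] == -p$W_EI))
  expect_true(all(W[i_b, e_b] == p$W_IE))
  expect_true(all(W[i_b, i_b] == -p$W_II))
  # feedforward onto E and I of the association areas
  rl_b <- u$area == "RL" & u$subnet == "bottom"
  expect_true(all(W[rl_b, e_b] == p$ff_scale * p$W_EE))
  # feedback onto E only
  rl_be <- u$area == "RL" & u$subnet == "bottom" & u$type == "E"
  al_be <- u$area == "AL" & u$subnet == "bottom" & u$type == "E"
  expect_true(all(W[e_b, rl_be] == p$fb_scale_RL * p$W_EE))
  expect_true(all(W[e_b, al_be] == p$fb_scale_AL * p$W_EE))
  expect_true(all(W[i_b, rl_be] == 0))
  # top and bottom subnetworks never touch
  top <- u$subnet == "top"
  expect_true(all(W[top, !top] == 0))
  expect_true(all(W[!top, top] == 0))
})

test_that("silencing disconnects the area completely", {
  p <- model_params(N_E = 4)
  con <- build_connectome(p, silenced = "RL")
  rl <- con$units$area == "RL"
  expect_true(all(con$W[rl, ] == 0))
  expect_true(all(con$W[, rl] == 0))
  expect_identical(con$silenced, "RL")
})

test_that("connectome_blocks reconstructs the dense matrix exactly", {
  p <- model_params(N_E = 5)
  for (sil in c("none", "RL", "AL")) {
    con <- build_connectome(p, silenced = sil)
    b <- connectome_blocks(con, p)
    u <- con$units
    n <- p$N_E
    W2 <- matrix(0, nrow(u), nrow(u))
    for (i in 1:8) {
      for (j in 1:8) {
        ti_e <- which(u$block == i & u$type == "E")
        ti_i <- which(u$block == i & u$type == "I")
        sj_e <- which(u$block == j & u$type == "E")
        sj_i <- which(u$block == j & u$type == "I")
        W2[ti_e, sj_e] <- b$EE[i, j] + diag(b$AEE[i, j], n)
        W2[ti_e, sj_i] <- b$EI[i, j] + diag(b$AEI[i, j], n)
        W2[ti_i, sj_e] <- b$IE[i, j] + diag(b$AIE[i, j], n)
        W2[ti_i, sj_i] <- b$II[i, j] + diag(b$AII[i, j], n)
      }
    }
    expect_identical(W2, con$W)
  }
})

test_that("connectome_blocks rejects non-conforming structure", {
  p <- model_params(N_E = 4)
  con <- build_connectome(p)
  con$W[1, 2] <- 99
  expect_error(connectome_blocks(con, p), "non-uniform")
})

test_that("stimulus input drives excitatory units of one subnetwork only", {
  p <- model_params(N_E = 4)
  con <- build_connectome(p)
  I <- stimulus_input(con, "S1", "top", p)
  u <- con$units
  on <- u$area == "S1" & u$subnet == "top" & u$type == "E"
  expect_true(all(I[on] == p$c_s))
  expect_true(all(I[!on] == 0))
})

test_that("renormalize_block hits the target mean exactly under the cap", {
  set.seed(1)
  w <- runif(40, 0, 0.4)
  out <- renormalize_block(w, 0.5, 1)
  expect_equal(mean(out), 0.5, tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 1))
  # water-filling: a dominant weight is capped, the mean still exact
  w2 <- c(10, runif(19, 0, 0.1))
  out2 <- renormalize_block(w2, 0.5, 1)
  expect_equal(out2[1], 1)
  expect_equal(mean(out2), 0.5, tolerance = 1e-12)
  # proportions among free weights preserved
  expect_equal(out2[3] / out2[2], w2[3] / w2[2], tolerance = 1e-9)
  expect_identical(renormalize_block(numeric(8), 0.5, 1), numeric(8))
})

test_that("readout initialization renormalizes each area block", {
  p <- model_params(N_E = 10)
  set.seed(7)
  ro <- readout_state(p)
  expect_equal(dim(ro$W_z), c(2, 60))
  for (a in c("V1", "S1", "RL")) {
    cols <- ro$source_area == a
    expect_equal(mean(ro$W_z[1, cols]), p$w_init_mean, tolerance = 1e-9)
    expect_equal(mean(ro$W_z[2, cols]), p$w_init_mean, tolerance = 1e-9)
  }
  ro_rl <- readout_state(p, silenced = "RL")
  expect_true(all(ro_rl$W_z[, ro_rl$source_area == "RL"] == 0))
  expect_true(all(ro_rl$frozen[ro_rl$source_area == "RL"]))
})

test_that("plasticity is a no-op at zero readout and preserves block means", {
  p <- model_params(N_E = 8)
  set.seed(3)
  ro <- readout_state(p)
  rates <- runif(48, 0, 20)
  same <- apply_plasticity(ro, rates, p, z_tilde = c(0, 0))
  expect_equal(same$W_z, ro$W_z, tolerance = 1e-12)
  upd <- apply_plasticity(ro, rates, p, z_tilde = c(5, -3))
  for (a in c("V1", "S1", "RL")) {
    cols <- ro$source_area == a
    expect_equal(mean(upd$W_z[1, cols]), p$w_init_mean, tolerance = 1e-9)
    expect_equal(mean(upd$W_z[2, cols]), p$w_init_mean, tolerance = 1e-9)
  }
  expect_true(all(upd$W_z >= 0 & upd$W_z <= p$W_max))
})

test_that("compiled kernel matches the dense R reference noiselessly", {
  p <- model_params(N_E = 8)
  con <- build_connectome(p)
  blocks <- connectome_blocks(con, p)
  set.seed(11)
  ro <- readout_state(p)
  W0 <- ro$W_z
  trials <- list(area = c(2L, 1L, 2L), loc = c(1L, 2L, 1L),
                 go = c(1L, 1L, 2L))
  sim <- simulate_trials_cpp(
    unclass(p), blocks$EE, blocks$EI, blocks$IE, blocks$II,
    blocks$AEE, blocks$AEI, blocks$AIE, blocks$AII,
    p$N_E, W0, ro$frozen, trials$area, trials$loc, trials$go,
    p$alpha, FALSE
  )
  state <- network_state(con)
  res <- list()
  for (k in 1:3) {
    spec <- list(area = c("V1", "S1")[trials$area[k]],
                 location = c("bottom", "top")[trials$loc[k]],
                 go_location = c("bottom", "top")[trials$go[k]])
    out <- run_trial(state, ro, con, spec, p, noise = FALSE)
    state <- out$state
    ro <- out$readout
    res[[k]] <- out$result
  }
  ref <- dplyr::bind_rows(res)
  expect_equal(sim$delta1, ref$delta1, tolerance = 1e-9)
  expect_equal(sim$delta2, ref$delta2, tolerance = 1e-9)
  expect_equal(as.logical(sim$crossed), ref$crossed)
  expect_equal(c("no-go", "go")[sim$action + 1L], ref$action)
  expect_equal(sim$W_z, ro$W_z, tolerance = 1e-9)
})

test_that("run_experiment returns a tidy per-trial log", {
  cfg <- experiment_config(n_runs = 2, n_pre = 8, n_post = 8, window = 4,
                           seed = 5)
  p <- model_params(N_E = 8)
  ex <- run_experiment(cfg, p)
  expect_s3_class(ex, "xmodal_experiment")
  expect_equal(nrow(ex), 2 * 16)
  expect_equal(unique(ex$area[ex$phase == "pre"]), "S1")
  expect_equal(unique(ex$area[ex$phase == "post"]), "V1")
  expect_true(all(ex$go_location == "bottom"))
  # per-run seeding: rerunning run 2 alone reproduces its trials
  cfg2 <- experiment_config(n_runs = 1, n_pre = 8, n_post = 8, window = 4,
                            seed = 6)
  ex2 <- run_experiment(cfg2, p)
  expect_equal(ex2$delta1, ex$delta1[ex$run == 2])
  g <- glance(ex)
  expect_equal(nrow(g), 2)
  expect_true(all(c("accuracy_pre", "accuracy_post", "max_post_accuracy",
                    "time_to_criterion") %in% names(g)))
  expect_s3_class(tidy(ex), "tbl_df")
})

test_that("reverse switch rewards the top location after the switch", {
  cfg <- experiment_config(switch = "reverse", n_runs = 1, n_pre = 4,
                           n_post = 4, window = 2, seed = 1)
  ex <- run_experiment(cfg, model_params(N_E = 8))
  expect_true(all(ex$go_location[ex$phase == "pre"] == "bottom"))
  expect_true(all(ex$go_location[ex$phase == "post"] == "top"))
})

test_that("model_performance matches hand-computed sliding windows", {
  df <- tibble::tibble(
    run = 1, phase = "post", trial_in_phase = 1:6,
    location = c("bottom", "top", "bottom", "top", "bottom", "bottom"),
    go_location = "bottom",
    action = c("go", "go", "no-go", "no-go", "go", "no-go"),
    correct = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    delta1 = 0, delta2 = 0
  )
  perf <- model_performance(df, window = 3)
  expect_equal(perf$window_end, 3:6)
  expect_equal(perf$accuracy, c(1 / 3, 1 / 3, 2 / 3, 2 / 3))
  # window 3..5: bottom trials 3,5 -> went (no-go, go) = 1/2
  expect_equal(perf$p_go_bottom[3], 1 / 2)
  # window 2..4 has top trials 2,4 -> went (go, no-go) = 1/2
  expect_equal(perf$p_go_top[2], 1 / 2)
  # window 4..6 contains one top trial (4, no-go)
  expect_equal(perf$p_go_top[4], 0)
  expect_error(model_performance(df, window = 10), "wider than")
})

test_that("readout accuracy mode scores the delta comparison", {
  df <- tibble::tibble(
    run = 1, phase = "post", trial_in_phase = 1:2,
    location = c("bottom", "top"), go_location = "bottom",
    action = "no-go", correct = FALSE,
    delta1 = c(5, 1), delta2 = c(1, 5)
  )
  perf <- model_performance(df, window = 2, mode = "readout")
  expect_equal(perf$accuracy, 1) # delta1 wins on go-stim, delta2 otherwise
})

test_that("time_to_criterion finds the first qualifying window", {
  tr <- tibble::tibble(
    run = c(1, 1, 1, 2, 2, 2), phase = "post",
    window_end = rep(c(15, 16, 17), 2),
    accuracy = c(0.5, 0.8, 0.9, 0.6, 0.6, 0.6),
    p_go_bottom = NA_real_, p_go_top = NA_real_
  )
  ttc <- time_to_criterion(tr, criterion = 0.75)
  expect_equal(ttc$time_to_criterion, c(16, NA))
})

test_that("network state stays finite and step_dynamics validates input", {
  p <- model_params(N_E = 4)
  con <- build_connectome(p)
  st <- network_state(con)
  st$r[1] <- NaN
  expect_error(step_dynamics(st, con, 0, p), "non-finite")
})
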