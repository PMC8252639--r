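gamma <- 0.97

test_that("reduced and genuine SR features match their definitions", {
  spec <- chain_spec()
  x <- reduced_features(spec)
  expect_equal(x, gamma^(10 - 1:10), tolerance = 1e-14)
  expect_equal(x[10], 1)
  expect_true(all(diff(x) > 0))
  # feature of the never-experienced post-goal state is 0
  px <- reduced_features(chain_spec(has_punishment = TRUE,
                                    punishment_size = -2))
  expect_length(px, 11)
  expect_equal(px[11], 0)

  m <- genuine_features(spec)
  expect_equal(diag(m), rep(1, 10))
  expect_equal(m[2, 1], 0)
  expect_equal(m[lower.tri(m)], rep(0, 45))
  expect_equal(m[1, 10], gamma^9, tolerance = 1e-14)
})

test_that("both SR value approximations start exact under the Non-Resistant policy", {
  for (n in c(2, 5, 10, 20)) {
    for (g in c(0.9, 0.95, 0.97, 0.99)) {
      spec <- chain_spec(n_states = n, gamma = g)
      truth <- true_values_nonresistant(spec)
      expect_equal(spec$reward_size * reduced_features(spec), truth,
                   tolerance = 1e-14)
      gl <- genuine_sr_learner(spec)
      expect_equal(as.numeric(gl$m %*% gl$w), truth, tolerance = 1e-14)
    }
  }
})

test_that("punctate TD step reproduces the update arithmetic", {
  spec <- chain_spec()
  lr <- td_learner(spec)  # values at the Non-Resistant fixed point
  expect_equal(td_step(lr, 1, 2, 0)$rpe, 0)

  res <- td_step(lr, 1, 1, 0)  # No-Go at the start state
  expected_rpe <- (gamma - 1) * gamma^9
  expect_equal(res$rpe, expected_rpe, tolerance = 1e-12)
  expect_equal(res$learner$v[1], gamma^9 + 0.5 * expected_rpe,
               tolerance = 1e-12)

  naive <- td_learner(spec, init = "zero")
  expect_equal(td_step(naive, 10, NA, 1)$rpe, 1)
})

test_that("rigid reduced-SR step has zero Go RPEs and the stated updates", {
  spec <- chain_spec()
  for (w in c(0.2, 0.83, 1, 1.7)) {
    lr <- reduced_sr_learner(spec, w = w)
    for (k in 1:9) {
      res <- td_step(lr, k, k + 1, 0)
      expect_identical(res$rpe, 0)          # exact, for any w
      expect_identical(res$learner$w, w)    # hence no coefficient drift
    }
  }

  lr <- reduced_sr_learner(spec)  # w = 1
  res <- td_step(lr, 1, 1, 0)
  expected_rpe <- (gamma - 1) * gamma^9
  expect_equal(res$rpe, expected_rpe, tolerance = 1e-12)
  expect_equal(res$learner$w, 1 + 0.5 * gamma^9 * expected_rpe,
               tolerance = 1e-12)

  res <- td_step(reduced_sr_learner(spec, w = 0.6), 10, NA, 1)
  expect_equal(res$rpe, 0.4)
  expect_equal(res$learner$w, 0.8)

  # punishment state: x = 0, so the negative RPE updates nothing
  pspec <- chain_spec(has_punishment = TRUE, punishment_size = -2)
  lr <- reduced_sr_learner(pspec, w = 0.9)
  res <- td_step(lr, 11, NA, -2)
  expect_equal(res$rpe, -2)
  expect_identical(res$learner$w, 0.9)
})

test_that("feature TD step adapts all features except the goal's", {
  spec <- chain_spec()
  lr <- reduced_sr_learner(spec, alpha_feature = 0.05)
  expect_equal(feature_td_step(lr, 9, 10)$feature_rpe, 0)

  res <- feature_td_step(lr, 1, 1)
  expected <- (gamma - 1) * gamma^9
  expect_equal(res$feature_rpe, expected, tolerance = 1e-12)
  expect_equal(res$learner$x[1], gamma^9 + 0.05 * expected,
               tolerance = 1e-12)
  expect_identical(res$learner$x[10], 1)

  expect_error(feature_td_step(reduced_sr_learner(spec), 1, 1), "rigid")
  expect_error(feature_td_step(lr, 10, 10), "frozen")

  # the combined td_step keeps the goal feature at 1 through a full episode
  cfg <- run_config(spec, policy_spec("resistant", 0.75),
                    learner = "reduced_sr", episodes = 5, n_sims = 2,
                    base_seed = 2, alpha_feature = 0.05)
  run <- run_simulation(cfg)
  xg <- dplyr::filter(run$snapshots, quantity == "x", state == 10)
  expect_true(all(xg$value == 1))
})

test_that("genuine-SR step credits weights by feature loading", {
  spec <- chain_spec()
  gl <- genuine_sr_learner(spec)
  expect_equal(td_step(gl, 1, 2, 0)$rpe, 0)
  expect_equal(td_step(gl, 10, NA, 1)$rpe, 0)

  res <- td_step(gl, 9, 9, 0)  # No-Go at S_9: only j = 10 contributes value
  delta <- gamma * (gamma - 1)
  expect_equal(res$rpe, delta, tolerance = 1e-12)
  expect_equal(res$learner$w[1:8], rep(0, 8))  # x_j(S_9) = 0 for j < 9
  expect_equal(res$learner$w[9], 0.5 * 1 * delta, tolerance = 1e-12)
  expect_equal(res$learner$w[10], 1 + 0.5 * gamma * delta, tolerance = 1e-12)

  # at goal arrival only w_n can change (x_j(S_n) = 0 for j < n)
  res <- td_step(genuine_sr_learner(spec), 10, NA, 1)
  expect_equal(res$learner$w[1:9], rep(0, 9))
})

test_that("cue values equal the initiation RPE formulas", {
  spec <- chain_spec()
  expect_equal(cue_value(td_learner(spec)), gamma^10, tolerance = 1e-12)
  expect_equal(cue_value(reduced_sr_learner(spec)), gamma^10,
               tolerance = 1e-12)
  expect_equal(cue_value(genuine_sr_learner(spec)), gamma^10,
               tolerance = 1e-12)
  zero <- td_learner(spec, init = "zero")
  expect_identical(cue_value(zero), 0)
})

test_that("naive punctate learning follows the closed-form goal recursion", {
  cfg <- run_config(chain_spec(), policy_spec("non_resistant"),
                    learner = "punctate", episodes = 30, n_sims = 1,
                    base_seed = 1, init = "zero")
  run <- run_simulation(cfg)
  goal <- dplyr::filter(run$steps, action == "goal_arrival")
  expect_equal(goal$rpe, oracle_naive_goal_rpes(30), tolerance = 1e-12)
  # the initiation RPE climbs towards gamma^n as values propagate back
  init <- dplyr::filter(run$steps, action == "initiation")
  expect_true(all(diff(init$rpe) >= 0))
  expect_lt(abs(init$rpe[30] - 0.97^10), 0.05)
})

test_that("punishment leaves the reduced SR untouched but drains punctate values", {
  pspec <- chain_spec(has_punishment = TRUE, punishment_size = -2)
  pol <- policy_spec("non_resistant")

  crun <- run_simulation(run_config(pspec, pol, "reduced_sr", episodes = 25,
                                    n_sims = 1, base_seed = 1))
  w <- dplyr::filter(crun$snapshots, quantity == "w")$value
  cue <- dplyr::filter(crun$snapshots, quantity == "cue_value")$value
  expect_identical(w, rep(1, 25))             # bit-identical across episodes
  expect_identical(cue, rep(cue[1], 25))

  prun <- run_simulation(run_config(pspec, pol, "punctate", episodes = 200,
                                    n_sims = 1, base_seed = 1))
  cues <- dplyr::filter(prun$steps, action == "initiation")$rpe
  expect_true(all(diff(cues) <= 0))           # non-increasing throughout
  expect_lt(cues[25], cues[1])                # and strictly lower by ep 25
  vstar <- oracle_punishment_values()         # Bellman fixed point
  limit <- 0.97 * vstar[1]                    # = gamma^10 (R + gamma * (-2))
  expect_equal(limit, 0.97^10 * (1 + 0.97 * -2), tolerance = 1e-10)
  expect_lt(abs(cues[200] - limit), 1e-3)
})

test_that("adaptive features steepen in expectation under resistance", {
  cfg <- run_config(chain_spec(), policy_spec("resistant", 0.75),
                    learner = "reduced_sr", episodes = 50, n_sims = 20,
                    base_seed = 5, alpha_feature = 0.05)
  run <- run_simulation(cfg)
  x50 <- run$snapshots |>
    dplyr::filter(quantity == "x", episode == 50) |>
    dplyr::group_by(state) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  x0 <- reduced_features(chain_spec())
  expect_true(all(x50$m[1:9] < x0[1:9]))
  expect_equal(x50$m[10], 1)
})

test_that("tidy and glance summarise learner state", {
  spec <- chain_spec()
  td <- tidy(reduced_sr_learner(spec, w = 0.8))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("state", "feature", "w", "value"))
  expect_equal(td$value, 0.8 * reduced_features(spec), tolerance = 1e-14)
  gl <- glance(td_learner(spec))
  expect_equal(gl$cue_value, 0.97^10, tolerance = 1e-12)
  expect_equal(glance(genuine_sr_learner(spec))$architecture,
               "genuine_sr_learner")
})
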