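gamma <- 0.97

test_that("initial action values are the Non-Resistant truths", {
  q <- init_action_values(chain_spec())
  expect_length(q$q_go, 9)
  expect_equal(q$q_go, gamma^(9 - 1:9), tolerance = 1e-14)
  expect_equal(q$q_go[9], 1)
  expect_equal(q$q_no_go, gamma^(10 - 1:9), tolerance = 1e-14)
  expect_true(all(q$q_go > q$q_no_go))
})

test_that("Q-learning RPEs vanish identically at the initial values", {
  ds <- dual_system(chain_spec(), kappa = 0, rpe_type = "q_learning")
  # after Go from S_{k-1} and after No-Go at S_k, at every pre-goal state
  for (k in 2:9) {
    expect_identical(
      action_rpe(ds, k, 0, "go", credit = list(state = k - 1, action = "go")),
      0
    )
    expect_identical(
      action_rpe(ds, k, 0, "go", credit = list(state = k, action = "no_go")),
      0
    )
  }
  # goal arrival after Go at the pre-goal state
  expect_identical(
    action_rpe(ds, 10, 1, NULL, credit = list(state = 9, action = "go")), 0
  )
})

test_that("SARSA and goal-arrival RPEs follow their definitions", {
  ds <- dual_system(chain_spec(), kappa = 0, rpe_type = "sarsa")
  # previous Go at S_4, No-Go chosen at S_5: gamma Q(NoGo_S5) - Q(Go_S4)
  rpe <- action_rpe(ds, 5, 0, "no_go",
                    credit = list(state = 4, action = "go"))
  expect_equal(rpe, (gamma - 1) * gamma^5, tolerance = 1e-12)
  expect_error(action_rpe(ds, 5, 0, NULL,
                          credit = list(state = 4, action = "go")),
               "SARSA")

  # middle term dropped at the goal, for either type
  for (type in c("q_learning", "sarsa")) {
    ds <- dual_system(chain_spec(), rpe_type = type)
    ds$q_go[9] <- 0.8
    expect_equal(
      action_rpe(ds, 10, 1, NULL, credit = list(state = 9, action = "go")),
      0.2
    )
  }

  # last term dropped at the initial time step
  ds <- dual_system(chain_spec(), rpe_type = "q_learning")
  expect_equal(action_rpe(ds, 1, 0, "go", credit = NULL),
               gamma * max(ds$q_go[1], ds$q_no_go[1]), tolerance = 1e-14)
})

test_that("combined_update mixes the two RPEs with weight kappa", {
  spec <- chain_spec()
  credit <- list(state = 9, action = "go")

  ds0 <- dual_system(spec, kappa = 0)
  up <- combined_update(ds0, 0.3, 99, credit)
  expect_equal(up$q_go[9], ds0$q_go[9] + 0.5 * 0.3)   # companion ignored

  ds1 <- dual_system(spec, kappa = 1)
  up <- combined_update(ds1, 99, 0.3, credit)
  expect_equal(up$q_go[9], ds1$q_go[9] + 0.5 * 0.3)   # action RPE ignored

  ds <- dual_system(spec, kappa = 0.4)
  up <- combined_update(ds, 0, 0.4, credit)
  expect_equal(up$q_go[9] - ds$q_go[9], 0.08)         # 0.5 * 0.4 * 0.4

  # no previous action to credit: a no-op, and only one value ever changes
  expect_identical(combined_update(ds, 1, 1, NULL), ds)
  up <- combined_update(ds, 0.1, 0.2, list(state = 3, action = "no_go"))
  expect_identical(up$q_go, ds$q_go)
  expect_equal(sum(up$q_no_go != ds$q_no_go), 1)
})

test_that("kappa = 0 Q-learning values are a bit-exact fixed point", {
  cfg <- run_config(chain_spec(), policy_spec("resistant", 0.75),
                    episodes = 60, n_sims = 5, base_seed = 9,
                    dual = list(kappa = 0, rpe_type = "q_learning",
                                companion = "reduced_sr"))
  run <- run_simulation(cfg)
  q0 <- init_action_values(chain_spec())
  for (sid in 1:5) {
    last <- dplyr::filter(run$snapshots, sim_id == sid, episode == 60)
    expect_identical(dplyr::filter(last, quantity == "q_go")$value, q0$q_go)
    expect_identical(dplyr::filter(last, quantity == "q_no_go")$value,
                     q0$q_no_go)
  }
  # every action RPE with a previous action to compare against is exactly
  # zero; the initial time step (last term dropped) logs gamma * max Q
  expect_identical(unique(run$steps$rpe_action[run$steps$t > 1]), 0)
  expect_equal(unique(run$steps$rpe_action[run$steps$t == 1]), 0.97^9,
               tolerance = 1e-12)
})

test_that("kappa = 0 SARSA devalues all actions except Go at the pre-goal state", {
  cfg <- run_config(chain_spec(), policy_spec("resistant", 0.75),
                    episodes = 60, n_sims = 20, base_seed = 4,
                    dual = list(kappa = 0, rpe_type = "sarsa",
                                companion = "reduced_sr"))
  run <- run_simulation(cfg)
  q0 <- init_action_values(chain_spec())
  final <- run$snapshots |>
    dplyr::filter(episode == 60, quantity %in% c("q_go", "q_no_go")) |>
    dplyr::group_by(quantity, state) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  go <- dplyr::filter(final, quantity == "q_go")
  no_go <- dplyr::filter(final, quantity == "q_no_go")
  expect_true(all(go$m[1:8] < q0$q_go[1:8]))
  expect_true(all(no_go$m < q0$q_no_go))
  # Go at the pre-goal state keeps its value (goal RPE bootstraps nothing)
  expect_gt(go$m[9], 0.95)
})

test_that("dual runs log both system RPEs and reject punishment chains", {
  expect_error(run_config(chain_spec(has_punishment = TRUE,
                                     punishment_size = -1),
                          policy_spec("non_resistant"),
                          episodes = 1,
                          dual = list(kappa = 0, rpe_type = "sarsa")),
               "punishment")
  cfg <- run_config(chain_spec(), policy_spec("resistant", 0.75),
                    episodes = 2, n_sims = 1, base_seed = 1,
                    dual = list(kappa = 0.2, rpe_type = "sarsa",
                                companion = "punctate"))
  run <- run_simulation(cfg)
  expect_true(all(c("rpe", "rpe_action") %in% names(run$steps)))
  expect_true(all(is.finite(run$steps$rpe)))
  body <- dplyr::filter(run$steps, t > 0)
  expect_true(all(is.finite(body$rpe_action)))
  expect_s3_class(tidy(dual_system(chain_spec())), "tbl_df")
  expect_equal(glance(dual_system(chain_spec(), 0.2))$kappa, 0.2)
})
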