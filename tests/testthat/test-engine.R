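test_that("zero-need populations never buy and the stock never moves", {
  for (seed in c(1, 17, 202)) {
    cfg <- simulation_config(
      network = network_params(100, 3),
      needs = needs_spec(m0_mean = 0, m0_sd = 0, s0_mean = 0, s0_sd = 0),
      horizon = 12, seed = seed
    )
    s <- run_simulation(cfg)$series
    expect_true(all(s$buyer_count == 0))
    expect_true(all(s$stock == 1))
  }
})

test_that("identical configuration and seed give byte-identical outputs", {
  cfg <- small_config(n = 150, horizon = 12, seed = 9)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$series, b$series)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_run(a, fa); write_run(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("the stock is monotonically non-increasing without supply monitoring", {
  for (seed in 1:3) {
    s <- run_simulation(small_config(n = 150, horizon = 15, seed = seed))$series
    expect_true(all(diff(s$stock) <= 1e-12))
  }
})

test_that("state variables respect their ranges at every tick", {
  cfg <- small_config(
    n = 150, m0 = 0.6, s0 = 0.4, horizon = 15, seed = 4,
    iv = intervention_config(supply_enabled = TRUE,
                             review_guidance_enabled = TRUE,
                             official_enabled = TRUE,
                             counseling_enabled = TRUE)
  )
  s <- run_simulation(cfg)$series
  expect_true(all(s$buyer_count >= 0 & s$buyer_count <= 150))
  expect_true(all(s$stock >= 0))
  expect_true(all(s$mean_emotion >= 0 & s$mean_emotion <= 1))
})

test_that("single-agent trajectories match the hand-rolled oracle exactly", {
  settings <- list(
    list(m0 = 0.9, s0 = 0.1, iv = intervention_config()),
    list(m0 = 0.7, s0 = 0.5, iv = intervention_config()),
    list(m0 = 0.9, s0 = 0.2,
         iv = intervention_config(official_enabled = TRUE, gov_strength = 1,
                                  t_timelyG = 1)),
    list(m0 = 0.9, s0 = 0.3,
         iv = intervention_config(counseling_enabled = TRUE, str_pr = 1,
                                  t_timelyP = 2)),
    list(m0 = 0.95, s0 = 0.1,
         iv = intervention_config(supply_enabled = TRUE, q_move = 1))
  )
  for (st in settings) {
    cfg <- single_agent_config(st$m0, st$s0, iv = st$iv, horizon = 12)
    sim <- run_simulation(cfg)
    oracle <- single_agent_oracle(st$m0, st$s0, iv = st$iv, horizon = 12)
    expect_equal(sim$series$buyer_count, oracle$state,
                 info = paste("m0 =", st$m0))
    expect_equal(sim$series$stock, oracle$Q, info = paste("m0 =", st$m0))
    expect_equal(sim$series$mean_emotion, oracle$E,
                 info = paste("m0 =", st$m0))
  }
})

test_that("run summaries capture peak, stop and replenishment structure", {
  fake <- function(bc) tibble::tibble(
    tick = seq_along(bc), buyer_count = bc, stock = 1, mean_emotion = 0.5,
    posts_true = NA_integer_, posts_rumor = NA_integer_, replenished = FALSE
  )
  s <- summarize_run(fake(rep(0, 10)))
  expect_identical(s$max_buyers, 0)
  expect_identical(s$t_max, 1L)
  expect_true(s$stopped)
  expect_identical(s$t_stop, 1L)

  s <- summarize_run(fake(c(0, 200, 1000, 1000, 1000)))
  expect_identical(s$max_buyers, 1000)
  expect_identical(s$t_max, 3L)
  expect_false(s$stopped)
  expect_identical(s$t_stop, NA_integer_)

  s <- summarize_run(fake(c(0, 800, 400, 0, 0, 0)))
  expect_true(s$stopped)
  expect_identical(s$t_stop, 4L)
  expect_identical(s$final_buyers, 0)

  # a transient zero is not a stop
  s <- summarize_run(fake(c(0, 800, 0, 50, 0, 0)))
  expect_identical(s$t_stop, 5L)
})

test_that("replicates use shifted seeds and reproduce deterministically", {
  cfg <- small_config(n = 120, horizon = 10, seed = 100)
  reps <- run_replicates(cfg, 4)
  expect_identical(nrow(reps), 4L)
  expect_identical(reps$seed, 101:104)
  reps2 <- run_replicates(cfg, 4)
  expect_identical(tidy(reps), tidy(reps2))
  one <- run_simulation({cfg1 <- cfg; cfg1$seed <- 101L; cfg1})
  expect_identical(reps$series[[1]], one$series)
})

test_that("higher material need produces weakly higher replicate-mean peaks", {
  peaks <- sapply(c(0.2, 0.5, 0.8), function(m0) {
    cfg <- simulation_config(
      network = network_params(300, 3),
      needs = needs_spec(m0_mean = m0, s0_mean = 0.5),
      horizon = 12, seed = 10
    )
    mean(run_replicates(cfg, 8)$max_buyers)
  })
  expect_true(peaks[1] <= peaks[2] && peaks[2] <= peaks[3])
})

test_that("supply monitoring weakly shortens stop times alongside an official response", {
  as_stop <- function(reps, horizon) {
    ifelse(reps$stopped, reps$t_stop, horizon + 1L)
  }
  iv_off <- intervention_config(official_enabled = TRUE)
  iv_both <- intervention_config(official_enabled = TRUE,
                                 supply_enabled = TRUE, q_move = 2)
  r_off <- run_replicates(small_config(n = 300, horizon = 25, seed = 11,
                                       iv = iv_off), 8)
  r_both <- run_replicates(small_config(n = 300, horizon = 25, seed = 11,
                                        iv = iv_both), 8)
  expect_lte(mean(as_stop(r_both, 25)), mean(as_stop(r_off, 25)))
})

test_that("tidy/glance/autoplot expose the expected shapes", {
  cfg <- small_config(n = 120, horizon = 8, seed = 1)
  sim <- run_simulation(cfg)
  expect_identical(tidy(sim), sim$series)
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  reps <- run_replicates(cfg, 2)
  expect_identical(nrow(tidy(reps)), 2L)
  agg <- glance(reps)
  expect_identical(agg$n_replicates, 2L)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(reps), "ggplot")
})
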