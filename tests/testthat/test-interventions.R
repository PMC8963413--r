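test_that("replenishment triggers strictly below the threshold", {
  expect_equal(replenish(0.5, 0.65, 1), list(Q = 1.5, event = TRUE))
  expect_equal(replenish(0.7, 0.65, 1), list(Q = 0.7, event = FALSE))
  expect_equal(replenish(0.65, 0.65, 1), list(Q = 0.65, event = FALSE))
})

test_that("post review matches the sign-table oracle over an (A, Q) grid", {
  d_SD <- 0.65; d_A <- 0.6
  grid <- expand.grid(A = seq(0, 1, by = 0.05), Q = seq(0, 1.6, by = 0.08))
  got <- classify_post(grid$A, grid$Q, d_SD, d_A)
  oracle <- ifelse(sign(grid$A - d_A) * sign(d_SD - grid$Q) == -1, 1L, 2L)
  expect_identical(got, oracle)
  # boundary: A exactly at the threshold is truthful
  expect_identical(classify_post(d_A, 0.9, d_SD, d_A), 2L)
})

test_that("authenticity factor inverts rumors and vanishes at gamma = 0", {
  expect_identical(authenticity_factor(c(1L, 2L), gamma = 1), c(-1, 1))
  expect_identical(authenticity_factor(c(1L, 2L), gamma = 0), c(0, 0))
  expect_error(authenticity_factor(3L, 1), class = "panicabm_invalid_parameter")
})

test_that("delayed effects switch on at tick 1 + delay + 1 and persist", {
  expect_equal(official_effect(1, 1, 1, horizon = 6), c(0, 0, 1, 1, 1, 1))
  expect_equal(official_effect(1, 0.5, 0, horizon = 4), c(0, 0.5, 0.5, 0.5))
  expect_equal(official_effect(1, 0, 1, horizon = 4), rep(0, 4))
  expect_equal(counseling_effect(0.5, 0.8, 2, horizon = 6),
               c(0, 0, 0, 0.4, 0.4, 0.4))
  expect_equal(counseling_effect(0, 1, 0, horizon = 3), rep(0, 3))
})

test_that("guided influence reduces to plain neighbor influence for truthful posts", {
  A <- c(0.9, 0.7, 0.65)
  tf_true <- authenticity_factor(rep(2L, 3), gamma = 1)
  expect_equal(guided_influence(A, trust = 1, tf = tf_true, d_A = 0.6),
               neighbor_influence(A, trust = 1, d_A = 0.6))
  # a rumor post contributes with inverted sign
  expect_equal(guided_influence(0.8, trust = 1,
                                tf = authenticity_factor(1L, 1), d_A = 0.6),
               -0.2)
})

test_that("disabled mechanisms are tick-for-tick identical to zeroed parameters", {
  base <- small_config(n = 150, horizon = 12, seed = 3)
  plain <- run_simulation(base)$series

  zeroed <- list(
    official = intervention_config(official_enabled = TRUE, gov_strength = 0),
    counseling = intervention_config(counseling_enabled = TRUE, str_pr = 0),
    supply = intervention_config(supply_enabled = TRUE, q_move = 0)
  )
  for (nm in names(zeroed)) {
    cfg <- small_config(n = 150, horizon = 12, seed = 3, iv = zeroed[[nm]])
    got <- run_simulation(cfg)$series
    cols <- c("tick", "buyer_count", "stock", "mean_emotion")
    expect_equal(got[cols], plain[cols], info = nm)
  }
})

test_that("review delay shifts when neighbor information first acts", {
  # With review on and t_exam = 2, posts published at tick t can first move
  # material needs at tick t + 3; before that the trajectories with and
  # without review agree except through the review's sign flips, which also
  # cannot act earlier.
  iv0 <- intervention_config()
  iv2 <- intervention_config(review_guidance_enabled = TRUE, t_exam = 2)
  cfg0 <- small_config(n = 150, m0 = 0.5, s0 = 0.5, horizon = 10, seed = 5,
                       iv = iv0)
  cfg2 <- small_config(n = 150, m0 = 0.5, s0 = 0.5, horizon = 10, seed = 5,
                       iv = iv2)
  s0 <- run_simulation(cfg0)$series
  s2 <- run_simulation(cfg2)$series
  # ticks 1-3: no pending posts have matured in the reviewed run, and in the
  # plain run neighbor info arrives from tick 2 -> the runs may only diverge
  # from tick 2 on via the *absence* of plain info; ticks where both have no
  # matured info must agree: that is ticks 1 (identical init) and, in the
  # reviewed run, buyer counts cannot respond to posts before tick 4.
  expect_identical(s0$buyer_count[1], s2$buyer_count[1])
  expect_true(all(is.na(s0$posts_true)))
  expect_false(any(is.na(s2$posts_true)))
  expect_identical(s2$posts_true + s2$posts_rumor, s2$buyer_count)
})

test_that("supply monitoring with q_move >= d_SD keeps the recorded stock above the threshold floor", {
  iv <- intervention_config(supply_enabled = TRUE, q_move = 1)
  cfg <- small_config(n = 200, m0 = 0.8, s0 = 0.8, horizon = 20, seed = 2,
                      iv = iv)
  sim <- run_simulation(cfg)
  expect_true(all(sim$series$stock >= min(1, cfg$model$d_SD)))
  expect_identical(sim$n_replenishments, sum(sim$series$replenished))
})

test_that("oversized official strength is accepted with a warning", {
  expect_warning(intervention_config(gov_strength = 10), "exceeds")
})
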