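test_that("emotion weights complement each other across the unit interval", {
  w <- emotion_weights(c(0, 1, 0.3))
  expect_equal(w$theta1, c(1, 0, 0.7))
  expect_equal(w$theta2, c(0, 1, 0.3))
  E <- seq(0, 1, by = 0.01)
  w <- emotion_weights(E)
  expect_equal(w$theta1 + w$theta2, rep(1, length(E)))
})

test_that("attitude blends need pressure and emotion and stays in [0, 1]", {
  mp <- model_params()
  expect_equal(attitude(0.5, 0.5, 0, mp), 0.5)
  expect_equal(attitude(0.2, 0.9, 1, mp), 1)   # fully emotional limit
  expect_equal(attitude(0.8, 0.2, 0.5, mp), 0.65)  # 0.5*(0.48+0.32)+0.25
  set.seed(42)
  M <- runif(200); S <- runif(200); E <- runif(200)
  A <- attitude(M, S, E, mp)
  expect_true(all(A >= 0 & A <= 1))
})

test_that("the buying threshold is inclusive", {
  expect_identical(buying_state(c(0.65, 0.6, 0.59), 0.6), c(1L, 1L, 0L))
})

test_that("purchase orders are a uniform random permutation of previous buyers", {
  expect_identical(assign_orders(integer()), setNames(integer(), character()))
  set.seed(1)
  r <- assign_orders(c(11L, 12L, 13L))
  expect_setequal(unname(r), 1:3)
  expect_identical(names(r), c("11", "12", "13"))
  # uniformity over the two orderings of two buyers
  set.seed(7)
  first_gets_1 <- replicate(10000, assign_orders(c(1L, 2L))[["1"]] == 1L)
  expect_equal(mean(first_gets_1), 0.5, tolerance = 0.04)
})

test_that("perceived stock decreases with rank and floors at zero", {
  expect_equal(perceived_materials(0.9, 1, 1000), 0.899)
  expect_equal(perceived_materials(0.9, 5, 1000), 0.895)
  expect_equal(perceived_materials(0.001, 5, 1000), 0)
  expect_error(perceived_materials(0.9, 0, 1000),
               class = "panicabm_contract_violation")
})

test_that("self experience is signed by perceived scarcity and zero for non-buyers", {
  mp <- model_params()
  expect_equal(self_experience(0, Q_i = 0.1, mp), 0)
  expect_equal(self_experience(1, Q_i = mp$d_SD, mp), 0)
  expect_equal(self_experience(1, Q_i = 0.45, mp), 0.04)
  expect_lt(self_experience(1, Q_i = 0.9, mp), 0)
})

test_that("neighbor influence averages trust-weighted attitude excess", {
  expect_equal(neighbor_influence(numeric(), d_A = 0.6), 0)
  expect_equal(neighbor_influence(c(0.9, 0.7), trust = 1, d_A = 0.6), 0.2)
  expect_equal(neighbor_influence(0.8, trust = 0.5, d_A = 0.6), 0.1)
})

test_that("material need follows the branch structure and clamps", {
  mp <- model_params()
  expect_equal(material_need_update(0.3, t = 1, prev_state = 0, Self = 1,
                                    I_net = 1, M0 = 0.3), 0.3)
  expect_equal(
    material_need_update(0.6, t = 2, prev_state = 1, Self = 0.04,
                         I_net = 99, i_gov = 1, params = mp),
    0.44
  )
  expect_equal(
    material_need_update(0.05, t = 2, prev_state = 0, Self = 99,
                         I_net = -0.2, i_gov = 0, params = mp),
    0
  )
})

test_that("safety need is constant over time", {
  expect_identical(safety_need(c(0, 0.3, 1)), c(0, 0.3, 1))
})

test_that("herd pressure scales buying prevalence by conformity", {
  expect_equal(herd_pressure(0, 10, 0.5), 0)
  expect_equal(herd_pressure(4, 10, 0.5), 0.2)
  expect_equal(herd_pressure(10, 10, 1), 1)
  expect_equal(herd_pressure(0, 0, 0.5), 0)  # isolated agent guard
})

test_that("emotion combines needs and herd pressure with clamping", {
  mp <- model_params()
  expect_equal(emotion(0.5, 0.5, 0, 0, mp), 0.5)
  expect_equal(emotion(0.8, 0.6, 0.2, 0, mp), 0.92)
  expect_equal(emotion(1, 1, 0.5, 0, mp), 1)     # raw 1.5, clamped
  expect_equal(emotion(0.5, 0.5, 0, pr = 1, mp), 0.3)  # lambda2 * PR = 0.2
})

test_that("stock depletion is proportional to buyers and floors at zero", {
  expect_equal(deplete_materials(0.8, 0, 1000), 0.8)
  expect_equal(deplete_materials(1, 100, 1000), 0.9)
  expect_equal(deplete_materials(0.05, 100, 1000), 0)
})

test_that("initialization draws the stated distributions and starts with full stock", {
  net <- generate_network(network_params(100, 3), seed = 1)
  degenerate <- needs_spec(m0_mean = 0.4, m0_sd = 0, s0_mean = 0.3, s0_sd = 0,
                           con_mean = 0.7, con_sd = 0)
  pop <- initialize_population(degenerate, net, seed = 1)
  expect_true(all(pop$M == 0.4))
  expect_true(all(pop$S == 0.3))
  expect_true(all(pop$con == 0.7))
  expect_identical(pop$Q, 1)
  expect_identical(pop$t, 1L)

  big <- generate_network(network_params(10000, 3), seed = 2)
  pop2 <- initialize_population(needs_spec(), big, seed = 2)
  expect_equal(mean(pop2$M), 0.5, tolerance = 0.01)
  expect_true(all(pop2$M >= 0 & pop2$M <= 1))
  expect_identical(pop2$NI, sum(pop2$state))
})
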