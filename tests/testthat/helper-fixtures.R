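# Shared fixtures: small configurations and an independent single-agent
# oracle (a hand-rolled recursion, kept deliberately separate from the
# engine's vectorised code path).

small_config <- function(n = 200, m0 = 0.8, s0 = 0.2, horizon = 15L,
                         seed = 1L, iv = intervention_config(), ...) {
  simulation_config(
    network = network_params(n_agents = n),
    needs = needs_spec(m0_mean = m0, s0_mean = s0),
    interventions = iv,
    horizon = horizon, seed = seed, ...
  )
}

one_agent_network <- function() {
  social_network(matrix(integer(), ncol = 2), n = 1, leader_fraction = 0)
}

single_agent_config <- function(m0, s0, con = 0.5, mp = model_params(),
                                iv = intervention_config(), horizon = 12L) {
  simulation_config(
    network = one_agent_network(),
    model = mp,
    needs = needs_spec(m0_mean = m0, m0_sd = 0, s0_mean = s0, s0_sd = 0,
                       con_mean = con, con_sd = 0),
    interventions = iv,
    horizon = horizon, seed = 1L
  )
}

# Independent recursion for one isolated agent (no neighbors, so no herd
# pressure and no neighbor information). Supports the official-response and
# counseling schedules; supply monitoring can be layered on the stock.
single_agent_oracle <- function(m0, s0, mp = model_params(),
                                iv = intervention_config(), horizon = 12L) {
  clamp <- function(x) min(max(x, 0), 1)
  i_gov <- pr <- numeric(horizon)
  onset_g <- 1 + iv$t_timelyG + 1
  onset_p <- 1 + iv$t_timelyP + 1
  if (iv$official_enabled) {
    i_gov[seq_len(horizon) >= onset_g] <- iv$gov_strength * iv$tr_gov
  }
  if (iv$counseling_enabled) {
    pr[seq_len(horizon) >= onset_p] <- iv$str_pr * iv$tr_ol
  }
  M <- clamp(m0); S <- clamp(s0)
  E <- clamp(mp$alpha * M + mp$beta * S)
  A <- (1 - E) * (mp$alpha * M + mp$beta * (1 - S)) + E * E
  state <- as.integer(A >= mp$d_A)
  Q <- 1
  out <- data.frame(tick = 1L, M = M, E = E, A = A, state = state, Q = Q)
  for (t in 2:horizon) {
    Q_prev <- Q
    Q <- max(Q - state / 1, 0)
    if (iv$supply_enabled && Q < mp$d_SD) Q <- Q + iv$q_move
    if (state == 1L) {
      Q_i <- max(Q_prev - 1, 0)
      M <- clamp(M + mp$mu * (mp$d_SD - Q_i) - mp$lambda1 * i_gov[t])
    } else {
      M <- clamp(M - mp$lambda1 * i_gov[t])  # I_net = 0: no neighbors
    }
    E <- clamp(mp$alpha * M + mp$beta * S - mp$lambda2 * pr[t])
    A <- (1 - E) * (mp$alpha * M + mp$beta * (1 - S)) + E * E
    state <- as.integer(A >= mp$d_A)
    out <- rbind(out, data.frame(tick = t, M = M, E = E, A = A,
                                 state = state, Q = Q))
  }
  out
}
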