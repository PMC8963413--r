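#' Emotion-derived decision weights
#'
#' The weight an agent gives to rational need pressure versus panic emotion
#' when forming a buying attitude. The more panicked an agent is, the less
#' the rational term counts: `theta1 = |1 - E|`, `theta2 = |E|`, so
#' `theta1 + theta2 = 1` for `E` in \[0, 1\].
#'
#' @param E panic emotion in \[0, 1\] (vectorised).
#' @return a list with numeric components `theta1` and `theta2`.
#' @examples
#' emotion_weights(0.3)  # theta1 = 0.7, theta2 = 0.3
#' @export
emotion_weights <- function(E) {
  list(theta1 = abs(1 - E), theta2 = abs(E))
}

#' Buying attitude
#'
#' An agent's support for panic buying: a convex combination of need
#' pressure `alpha * M + beta * (1 - S)` and panic emotion `E`, weighted by
#' [emotion_weights()]. Higher safety need `S` keeps people at home, hence
#' the `1 - S` term. The result lies in \[0, 1\] automatically.
#'
#' @param M,S,E material need, safety need and panic emotion in \[0, 1\]
#'   (vectorised).
#' @param params a [model_params()] object.
#' @return attitude values in \[0, 1\].
#' @examples
#' attitude(M = 0.8, S = 0.2, E = 0.5, model_params())  # 0.65
#' @export
attitude <- function(M, S, E, params = model_params()) {
  w <- emotion_weights(E)
  w$theta1 * (params$alpha * M + params$beta * (1 - S)) + w$theta2 * E
}

#' Buying state from attitude
#'
#' An agent is a panic buyer exactly when its attitude reaches the buying
#' threshold (`A >= d_A`, boundary inclusive). The state is memoryless and
#' recomputed every tick, so agents can revert to not buying.
#'
#' @param A attitude in \[0, 1\] (vectorised).
#' @param d_A panic-buying threshold.
#' @return integer 0/1 vector.
#' @examples
#' buying_state(c(0.59, 0.6, 0.65), d_A = 0.6)
#' @export
buying_state <- function(A, d_A) {
  as.integer(A >= d_A)
}

#' Random purchase order among the previous tick's buyers
#'
#' Buyers reach the shelves in a uniformly random order each tick; the rank
#' determines how much stock each buyer sees. Non-buyers get no rank.
#'
#' @param previous_buyers integer vector of agent ids that bought at `t - 1`.
#' @return a named integer vector of ranks `1..length(previous_buyers)`
#'   (names are agent ids); empty for an empty buyer set.
#' @export
assign_orders <- function(previous_buyers) {
  n <- length(previous_buyers)
  if (n == 0L) return(stats::setNames(integer(), character()))
  ranks <- sample.int(n)
  stats::setNames(ranks, previous_buyers)
}

#' Stock as perceived by an individual buyer
#'
#' The `order`-th buyer of a tick sees the previous stock minus the share
#' already taken by the buyers ahead of it: `Q_i = Q_prev - order / N`,
#' floored at 0.
#'
#' @param Q_prev recorded stock at the previous tick.
#' @param order purchase rank (1-based, vectorised).
#' @param N population size.
#' @return perceived stock, non-negative.
#' @examples
#' perceived_materials(0.9, order = 1:5, N = 1000)
#' @export
perceived_materials <- function(Q_prev, order, N) {
  if (any(order < 1)) {
    rlang::abort("`order` is defined only for previous-tick buyers (rank >= 1).",
                 class = "panicabm_contract_violation")
  }
  pmax(Q_prev - order / N, 0)
}

#' Self experience of a buyer
#'
#' What a buyer learns at the shelves: if the perceived stock is below the
#' supply-demand threshold the material need grows (`Self > 0`), above it
#' the need relaxes (`Self < 0`). Agents who did not buy last tick learn
#' nothing first-hand (`Self = 0`).
#'
#' @param prev_state 0/1 buying state at the previous tick (vectorised).
#' @param Q_i perceived stock for previous-tick buyers.
#' @param params a [model_params()] object (uses `mu` and `d_SD`).
#' @return self-experience increments.
#' @examples
#' self_experience(1, Q_i = 0.45, model_params())  # 0.2 * (0.65 - 0.45) = 0.04
#' @export
self_experience <- function(prev_state, Q_i, params = model_params()) {
  ifelse(prev_state == 1L, params$mu * (params$d_SD - Q_i), 0)
}

#' Influence of buying neighbors' information
#'
#' The mean, over an agent's panic-buying neighbors, of how far each
#' neighbor's attitude exceeds the buying threshold, weighted by role-based
#' trust: `I_net = sum_j (A_j - d_A) * TR(j) / NI_i`. Defined as 0 when the
#' agent has no buying neighbors. Under review/guidance each term is further
#' multiplied by the authenticity factor of the neighbor's post.
#'
#' @param attitudes attitudes of the buying neighbors.
#' @param trust trust weights `TR(j)` for those neighbors (recycled).
#' @param d_A buying threshold.
#' @param tf authenticity factors `TF_j` (recycled; 1 when review is off).
#' @return a single influence value (may be negative).
#' @examples
#' neighbor_influence(c(0.9, 0.7), trust = 1, d_A = 0.6)  # 0.2
#' @export
neighbor_influence <- function(attitudes, trust = 1, d_A = 0.6, tf = 1) {
  if (length(attitudes) == 0L) return(0)
  mean((attitudes - d_A) * trust * tf)
}

#' Material-need update
#'
#' At tick 1 the material need is the initial draw. Afterwards, previous
#' buyers update from first-hand experience (`Self`), previous non-buyers
#' from neighbors' posts (`I_net`); an active official response subtracts
#' `lambda1 * I_gov` from everyone. Clamped to \[0, 1\].
#'
#' @param prev_M material need at `t - 1` (vectorised).
#' @param t current tick.
#' @param prev_state 0/1 buying state at `t - 1`.
#' @param Self self-experience increments (used where `prev_state == 1`).
#' @param I_net neighbor-information influence (used where `prev_state == 0`).
#' @param i_gov official-response effect `I_gov(t)` (0 when disabled or
#'   before onset).
#' @param params a [model_params()] object (uses `lambda1`).
#' @param M0 initial draws, returned unchanged when `t == 1`.
#' @return updated material need in \[0, 1\].
#' @export
material_need_update <- function(prev_M, t, prev_state, Self, I_net,
                                 i_gov = 0, params = model_params(),
                                 M0 = prev_M) {
  if (t == 1L) return(clamp01(M0))
  raw <- prev_M + ifelse(prev_state == 1L, Self, I_net) - params$lambda1 * i_gov
  clamp01(raw)
}

#' Safety need
#'
#' Safety information comes from official news and does not evolve inside
#' the model: `S(t) = S0` at every tick.
#'
#' @param S0 initial safety need in \[0, 1\].
#' @return `S0`, unchanged.
#' @export
safety_need <- function(S0) {
  S0
}

#' Herd pressure from buying neighbors
#'
#' The fraction of an agent's neighbors that bought at the previous tick,
#' scaled by the agent's conformity: `F = (NI_prev / N_prev) * con`.
#'
#' @param NI_prev number of buying neighbors at `t - 1` (vectorised).
#' @param N_prev number of neighbors (degree), at least 1 where `NI_prev > 0`.
#' @param con conformity in \[0, 1\].
#' @return herd pressure in \[0, 1\]; 0 for isolated agents.
#' @examples
#' herd_pressure(4, 10, con = 0.5)  # 0.2
#' @export
herd_pressure <- function(NI_prev, N_prev, con) {
  ifelse(N_prev > 0, NI_prev / N_prev, 0) * con
}

#' Panic-emotion update
#'
#' Emotion grows with unmet needs and with the surrounding buying
#' atmosphere: `E = alpha * M + beta * S + F - lambda2 * PR`, where active
#' counseling subtracts `lambda2 * PR`. Clamped to \[0, 1\].
#'
#' @param M,S material and safety need (vectorised).
#' @param F_herd herd pressure.
#' @param pr counseling effect `PR(t)` (0 when disabled or before onset).
#' @param params a [model_params()] object (uses `alpha`, `beta`, `lambda2`).
#' @return panic emotion in \[0, 1\].
#' @examples
#' emotion(M = 0.8, S = 0.6, F_herd = 0.2)  # 0.92
#' @export
emotion <- function(M, S, F_herd = 0, pr = 0, params = model_params()) {
  clamp01(params$alpha * M + params$beta * S + F_herd - params$lambda2 * pr)
}

#' Deplete the shared material stock
#'
#' Each buyer of the previous tick consumes `1/N` of a unit of stock:
#' `Q = Q_prev - NI_prev / N`, floored at 0. The initial stock is 1, one
#' unit covering the whole population's basic purchases once.
#'
#' @param Q_prev stock at the previous tick.
#' @param NI_prev number of buyers at the previous tick.
#' @param N population size.
#' @return updated stock, non-negative.
#' @examples
#' deplete_materials(1, NI_prev = 100, N = 1000)  # 0.9
#' @export
deplete_materials <- function(Q_prev, NI_prev, N) {
  max(Q_prev - NI_prev / N, 0)
}

#' Initialize the agent population
#'
#' Draws initial material need, safety need and conformity per agent from
#' the clipped normal distributions of `spec`, then computes tick-1 emotion,
#' attitude and buying state with no herd pressure and no interventions
#' (there is no prior tick). The initial stock is 1.
#'
#' @param spec a [needs_spec()] object.
#' @param network a `social_network`.
#' @param params a [model_params()] object.
#' @param seed integer seed for the draws.
#' @return a list with per-agent vectors `M`, `S`, `E`, `A`, `con`, `state`,
#'   plus scalars `Q = 1`, `NI` and `t = 1`.
#' @export
initialize_population <- function(spec, network, params = model_params(),
                                  seed = 1L) {
  stopifnot(inherits(spec, "needs_spec"), inherits(network, "social_network"))
  set.seed(derive_seed(seed, 2L))
  n <- network$n
  M <- clamp01(stats::rnorm(n, spec$m0_mean, spec$m0_sd))
  S <- clamp01(stats::rnorm(n, spec$s0_mean, spec$s0_sd))
  con <- clamp01(stats::rnorm(n, spec$con_mean, spec$con_sd))
  E <- emotion(M, S, F_herd = 0, pr = 0, params = params)
  A <- attitude(M, S, E, params)
  state <- buying_state(A, params$d_A)
  list(M = M, S = S, E = E, A = A, con = con, state = state,
       Q = 1, NI = sum(state), t = 1L)
}
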