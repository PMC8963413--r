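#' Model constants
#'
#' The behavioural constants of the panic-buying model. `alpha` and `beta`
#' weight material versus safety needs and must sum to 1 with
#' `alpha > beta` (physiological needs dominate safety needs in Maslow's
#' hierarchy). `d_SD` is the supply-demand threshold below which the stock is
#' perceived as insufficient; `d_A` is the attitude threshold at which an
#' agent flips into the buying state.
#'
#' @param alpha weight of material need in individual needs, in \[0, 1\].
#' @param beta weight of safety need; `alpha + beta` must equal 1.
#' @param mu influence of first-hand experience of the stock on material
#'   need.
#' @param d_SD supply-demand threshold in (0, 1).
#' @param d_A panic-buying attitude threshold in (0, 1).
#' @param gamma influence of information authenticity (review/guidance).
#' @param lambda1 influence of the official response on material need.
#' @param lambda2 influence of psychological counseling on panic emotion.
#' @return an object of class `model_params`.
#' @examples
#' model_params()                     # the default experimental constants
#' model_params(d_SD = 0.6, d_A = 0.5) # case-study thresholds
#' @export
model_params <- function(alpha = 0.6, beta = 0.4, mu = 0.2,
                         d_SD = 0.65, d_A = 0.6, gamma = 1,
                         lambda1 = 0.2, lambda2 = 0.2) {
  check_prob(alpha, "alpha"); check_prob(beta, "beta")
  if (abs(alpha + beta - 1) > 1e-12) abort_bad_arg("`alpha` + `beta` must equal 1.")
  if (alpha <= beta) abort_bad_arg("`alpha` must exceed `beta` (material needs dominate).")
  for (nm in c("mu", "gamma", "lambda1", "lambda2")) check_nonneg(get(nm), nm)
  check_prob(d_SD, "d_SD"); check_prob(d_A, "d_A")
  if (d_SD <= 0 || d_SD >= 1 || d_A <= 0 || d_A >= 1) {
    abort_bad_arg("`d_SD` and `d_A` must lie strictly inside (0, 1).")
  }
  structure(
    list(alpha = alpha, beta = beta, mu = mu, d_SD = d_SD, d_A = d_A,
         gamma = gamma, lambda1 = lambda1, lambda2 = lambda2),
    class = "model_params"
  )
}

#' Initial-need distributions
#'
#' Initial material need, safety need and conformity are drawn independently
#' per agent from normal distributions clipped to \[0, 1\] (draws above 1 are
#' set to 1, below 0 to 0). The canonical scenario levels map low / medium /
#' high need to means 0.2 / 0.5 / 0.8 with sd 0.15.
#'
#' @param m0_mean,m0_sd mean and sd of initial material need `M0`.
#' @param s0_mean,s0_sd mean and sd of initial safety need `S0`.
#' @param con_mean,con_sd mean and sd of conformity `Con(i)`.
#' @return an object of class `needs_spec`.
#' @examples
#' needs_spec(m0_mean = 0.8, s0_mean = 0.2)  # high material, low safety
#' @export
needs_spec <- function(m0_mean = 0.5, m0_sd = 0.15,
                       s0_mean = 0.5, s0_sd = 0.15,
                       con_mean = 0.5, con_sd = 0.15) {
  for (nm in c("m0_sd", "s0_sd", "con_sd")) check_nonneg(get(nm), nm)
  for (nm in c("m0_mean", "s0_mean", "con_mean")) {
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L || is.na(get(nm))) {
      abort_bad_arg(sprintf("`%s` must be a single number.", nm))
    }
  }
  structure(
    list(m0_mean = m0_mean, m0_sd = m0_sd, s0_mean = s0_mean, s0_sd = s0_sd,
         con_mean = con_mean, con_sd = con_sd),
    class = "needs_spec"
  )
}

#' Social-intervention configuration
#'
#' The five intervention mechanisms as independently switchable effects.
#' A disabled mechanism contributes exactly zero to every update. Information
#' review and information guidance are bundled under one switch because
#' review is the prerequisite of guidance.
#'
#' Delayed mechanisms follow one onset convention: the disturbance starts at
#' tick 1, so a mechanism with delay `d` first acts at tick `1 + d + 1` and
#' persists every tick thereafter.
#'
#' @param supply_enabled monitor the stock and replenish when it falls below
#'   `d_SD`.
#' @param q_move quantity of materials moved in per replenishment event.
#' @param review_guidance_enabled review buyers' posts (rumor vs truth) and
#'   guide readers accordingly; rumor posts act with inverted sign.
#' @param t_exam review delay in ticks: influence computed from tick-`t`
#'   posts first affects need updates at tick `t + 1 + t_exam`.
#' @param official_enabled persistent official response reducing material
#'   need by `lambda1 * Gov * TR_gov` per tick after onset.
#' @param gov_strength official response intensity `Gov(t)`. Values above 1
#'   are accepted with a warning (used by the China case study).
#' @param t_timelyG official-response delay in ticks.
#' @param tr_gov public trust in the government, in \[0, 1\].
#' @param counseling_enabled persistent psychological counseling reducing
#'   panic emotion by `lambda2 * Str_PR * TR_ol` per tick after onset.
#' @param str_pr counseling strength `Str_PR(t)` in \[0, 1\].
#' @param t_timelyP counseling delay in ticks.
#' @param tr_ol trust in opinion leaders, in \[0, 1\].
#' @param tr_ordinary trust in ordinary netizens, in \[0, 1\]; completes the
#'   role-based trust table `TR(j)`.
#' @param post_probability probability that a buyer posts about their
#'   experience each tick (1 = every buyer posts).
#' @param perceive_current_stock if `TRUE`, buyers perceive the current
#'   tick's post-replenishment stock instead of the previous tick's recorded
#'   stock (the default, which follows the perceived-stock recursion
#'   verbatim).
#' @return an object of class `intervention_config`.
#' @examples
#' intervention_config()                       # everything off
#' intervention_config(supply_enabled = TRUE)  # supply monitoring only
#' @export
intervention_config <- function(supply_enabled = FALSE,
                                q_move = 1,
                                review_guidance_enabled = FALSE,
                                t_exam = 1L,
                                official_enabled = FALSE,
                                gov_strength = 1,
                                t_timelyG = 1L,
                                tr_gov = 1,
                                counseling_enabled = FALSE,
                                str_pr = 1,
                                t_timelyP = 1L,
                                tr_ol = 1,
                                tr_ordinary = 1,
                                post_probability = 1,
                                perceive_current_stock = FALSE) {
  check_nonneg(q_move, "q_move")
  check_nonneg(gov_strength, "gov_strength")
  if (gov_strength > 1) {
    rlang::warn(sprintf(
      "`gov_strength` = %g exceeds the nominal (0, 1) range; accepted as-is.",
      gov_strength))
  }
  check_prob(str_pr, "str_pr")
  check_prob(tr_gov, "tr_gov"); check_prob(tr_ol, "tr_ol")
  check_prob(tr_ordinary, "tr_ordinary")
  check_prob(post_probability, "post_probability")
  t_exam <- check_count(t_exam, "t_exam")
  t_timelyG <- check_count(t_timelyG, "t_timelyG")
  t_timelyP <- check_count(t_timelyP, "t_timelyP")
  structure(
    list(
      supply_enabled = isTRUE(supply_enabled), q_move = q_move,
      review_guidance_enabled = isTRUE(review_guidance_enabled),
      t_exam = t_exam,
      official_enabled = isTRUE(official_enabled),
      gov_strength = gov_strength, t_timelyG = t_timelyG, tr_gov = tr_gov,
      counseling_enabled = isTRUE(counseling_enabled),
      str_pr = str_pr, t_timelyP = t_timelyP, tr_ol = tr_ol,
      tr_ordinary = tr_ordinary,
      post_probability = post_probability,
      perceive_current_stock = isTRUE(perceive_current_stock)
    ),
    class = "intervention_config"
  )
}

#' Full simulation configuration
#'
#' Bundles network, model constants, initial-need distributions,
#' interventions, horizon and seed into one validated object consumed by
#' [run_simulation()].
#'
#' @param network a [network_params()] object (a fresh network is generated
#'   per run/replicate) or a fixed `social_network`.
#' @param model a [model_params()] object.
#' @param needs a [needs_spec()] object.
#' @param interventions an [intervention_config()] object.
#' @param horizon number of ticks to simulate (tick 1 is the initial state).
#' @param seed master integer seed; sub-streams for the network build, the
#'   initial draws and the per-tick purchase orders are derived from it.
#' @return an object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(needs = needs_spec(m0_mean = 0.8, s0_mean = 0.2))
#' @export
simulation_config <- function(network = network_params(),
                              model = model_params(),
                              needs = needs_spec(),
                              interventions = intervention_config(),
                              horizon = 30L,
                              seed = 1L) {
  if (!inherits(network, "network_params") && !inherits(network, "social_network")) {
    abort_bad_arg("`network` must be a `network_params` or `social_network` object.")
  }
  stopifnot(inherits(model, "model_params"), inherits(needs, "needs_spec"),
            inherits(interventions, "intervention_config"))
  horizon <- check_count(horizon, "horizon", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(network = network, model = model, needs = needs,
         interventions = interventions, horizon = horizon, seed = seed),
    class = "simulation_config"
  )
}
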