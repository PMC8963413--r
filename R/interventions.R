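#' Supply-monitoring replenishment
#'
#' When supply monitoring is active the stock is checked after depletion
#' each tick: if it has fallen below the supply-demand threshold,
#' `q_move` units are moved in from elsewhere; otherwise nothing happens.
#' Events are counted per run.
#'
#' @param Q current stock (after depletion).
#' @param d_SD supply-demand threshold.
#' @param q_move quantity added per replenishment event.
#' @return a list with the new stock `Q` and logical `event`.
#' @examples
#' replenish(0.5, d_SD = 0.65, q_move = 1)   # 1.5, event
#' replenish(0.65, d_SD = 0.65, q_move = 1)  # unchanged (>= threshold)
#' @export
replenish <- function(Q, d_SD, q_move) {
  if (Q < d_SD) {
    list(Q = Q + q_move, event = TRUE)
  } else {
    list(Q = Q, event = FALSE)
  }
}

#' Review a buyer's post: rumor or truth
#'
#' A post is truthful when the publisher's buying tendency is consistent
#' with actual scarcity: type 2 (true) iff `(A - d_A) * (d_SD - Q) >= 0`,
#' type 1 (rumor) otherwise. A buyer claiming shortage while the stock is
#' genuinely below threshold posts truth; a buyer claiming shortage while
#' shelves are full posts a rumor.
#'
#' @param A_j publisher attitude (vectorised).
#' @param Q global stock at publication time.
#' @param d_SD,d_A model thresholds.
#' @return integer vector: 1 = rumor, 2 = true.
#' @examples
#' classify_post(c(0.5, 0.8), Q = 0.8, d_SD = 0.65, d_A = 0.6)  # 2, 1
#' @export
classify_post <- function(A_j, Q, d_SD, d_A) {
  ifelse((A_j - d_A) * (d_SD - Q) < 0, 1L, 2L)
}

#' Authenticity factor of a reviewed post
#'
#' Guidance flips the influence of a rumor and reinforces truth:
#' `TF = -gamma` for rumors (type 1), `+gamma` for true posts (type 2).
#'
#' @param info_type integer vector of 1 (rumor) / 2 (true).
#' @param gamma information-authenticity influence parameter.
#' @return signed authenticity factors.
#' @examples
#' authenticity_factor(c(1L, 2L), gamma = 1)  # -1, +1
#' @export
authenticity_factor <- function(info_type, gamma) {
  if (!all(info_type %in% c(1L, 2L))) {
    abort_bad_arg("`info_type` must contain only 1 (rumor) or 2 (true).")
  }
  ifelse(info_type == 1L, -gamma, gamma)
}

#' Delayed-effect schedule for official response and counseling
#'
#' Both mechanisms are persistent, trust-scaled effects with a delay: an
#' effect with delay `d` is 0 through tick `1 + d` and equals
#' `strength * trust` from tick `1 + d + 1` onward (the disturbance starts
#' at tick 1).
#'
#' @param strength `Gov(t)` for the official response, `Str_PR(t)` for
#'   counseling (held constant over a run).
#' @param trust `TR_gov` or `TR_ol`.
#' @param delay `t_timelyG` or `t_timelyP`, in ticks.
#' @param horizon run length; the schedule has one value per tick.
#' @return numeric vector of length `horizon`.
#' @examples
#' official_effect(gov_strength = 1, tr_gov = 1, t_timelyG = 1, horizon = 5)
#' @name effect_schedule
NULL

effect_schedule <- function(strength, trust, delay, horizon) {
  onset <- 1L + delay + 1L
  value <- strength * trust
  ifelse(seq_len(horizon) >= onset, value, 0)
}

#' @rdname effect_schedule
#' @param gov_strength,tr_gov,t_timelyG official-response intensity, trust
#'   and delay.
#' @export
official_effect <- function(gov_strength, tr_gov, t_timelyG, horizon) {
  effect_schedule(gov_strength, tr_gov, t_timelyG, horizon)
}

#' @rdname effect_schedule
#' @param str_pr,tr_ol,t_timelyP counseling strength, trust in opinion
#'   leaders and delay.
#' @export
counseling_effect <- function(str_pr, tr_ol, t_timelyP, horizon) {
  effect_schedule(str_pr, tr_ol, t_timelyP, horizon)
}

#' Reviewed, delayed neighbor influence
#'
#' The guided counterpart of [neighbor_influence()]: each buying neighbor's
#' post contributes `(A_j - d_A) * TR(j) * TF_j / NI_i`, and the whole
#' contribution is applied `t_exam` ticks later than the un-reviewed
#' influence would be. With all posts truthful, `gamma = 1` and
#' `t_exam = 0`, this reduces exactly to [neighbor_influence()].
#'
#' @param attitudes attitudes of the posting (buying) neighbors.
#' @param trust trust weights for those neighbors.
#' @param tf authenticity factors of their posts.
#' @param d_A buying threshold.
#' @return a single influence value, to be applied at `t + t_exam`.
#' @export
guided_influence <- function(attitudes, trust, tf, d_A) {
  neighbor_influence(attitudes, trust = trust, d_A = d_A, tf = tf)
}
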