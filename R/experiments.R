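need_level <- function(level) {
  switch(level, low = 0.2, medium = 0.5, high = 0.8,
         abort_bad_arg(sprintf("unknown need level '%s'.", level)))
}

grid_needs <- function(s_level, m_level) {
  needs_spec(m0_mean = need_level(m_level), s0_mean = need_level(s_level))
}

# Section defaults for each mechanism when it participates in a combination
# strategy or a single-mechanism study.
iv_defaults <- function(supply = FALSE, review = FALSE, official = FALSE,
                        counseling = FALSE, ...) {
  args <- list(
    supply_enabled = supply, q_move = 1,
    review_guidance_enabled = review, t_exam = 1L,
    official_enabled = official, gov_strength = 1, t_timelyG = 1L, tr_gov = 1,
    counseling_enabled = counseling, str_pr = 1, t_timelyP = 1L, tr_ol = 1
  )
  do.call(intervention_config, utils::modifyList(args, list(...)))
}

combo_flags <- function() {
  tibble::tibble(
    plan = c("none", paste0("combo_", 1:10), "comprehensive"),
    combination = c(
      "No intervention",
      "Supply + Information", "Supply + Official", "Supply + Psychology",
      "Information + Official", "Information + Psychology",
      "Official + Psychology",
      "Supply + Information + Official", "Supply + Information + Psychology",
      "Supply + Official + Psychology", "Information + Official + Psychology",
      "Supply + Information + Official + Psychology"
    ),
    supply = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
               TRUE, TRUE, TRUE, FALSE, TRUE),
    review = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
               TRUE, TRUE, FALSE, TRUE, TRUE),
    official = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                 TRUE, FALSE, TRUE, TRUE, TRUE),
    counseling = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                   FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

case_model <- function() {
  model_params(d_SD = 0.6, d_A = 0.5, lambda1 = 0.1, lambda2 = 0.1)
}

preset_builders <- function() {
  grid <- list(
    grid_highS_highM = c("high", "high"),
    grid_highS_lowM = c("high", "low"),
    grid_lowS_highM = c("low", "high"),
    grid_lowS_lowM = c("low", "low"),
    grid_medS_medM = c("medium", "medium")
  )
  builders <- purrr::imap(grid, function(levels, nm) {
    force(levels)
    function(seed, horizon) simulation_config(
      needs = grid_needs(levels[1], levels[2]),
      horizon = horizon %||% 20L, seed = seed
    )
  })
  builders$no_intervention_highM <- function(seed, horizon) simulation_config(
    needs = grid_needs("low", "high"), horizon = horizon %||% 20L, seed = seed
  )
  builders$supply_qmove1 <- function(seed, horizon) simulation_config(
    needs = grid_needs("high", "high"),
    interventions = iv_defaults(supply = TRUE),
    horizon = horizon %||% 30L, seed = seed
  )
  builders$supply_qmove2 <- function(seed, horizon) simulation_config(
    needs = grid_needs("high", "high"),
    interventions = iv_defaults(supply = TRUE, q_move = 2),
    horizon = horizon %||% 30L, seed = seed
  )
  for (te in 0:2) {
    local({
      te_local <- te
      builders[[paste0("review_texam", te_local)]] <<- function(seed, horizon) {
        simulation_config(
          needs = grid_needs("medium", "medium"),
          interventions = iv_defaults(review = TRUE, t_exam = te_local),
          horizon = horizon %||% 30L, seed = seed
        )
      }
    })
  }
  builders$official_baseline <- function(seed, horizon) simulation_config(
    needs = grid_needs("low", "high"),
    interventions = iv_defaults(official = TRUE),
    horizon = horizon %||% 20L, seed = seed
  )
  builders$official_low_trust <- function(seed, horizon) simulation_config(
    needs = grid_needs("low", "high"),
    interventions = iv_defaults(official = TRUE, tr_gov = 0.5),
    horizon = horizon %||% 20L, seed = seed
  )
  builders$official_delayed <- function(seed, horizon) simulation_config(
    needs = grid_needs("medium", "medium"),
    interventions = iv_defaults(official = TRUE, t_timelyG = 3L),
    horizon = horizon %||% 30L, seed = seed
  )
  builders$counseling <- function(seed, horizon) simulation_config(
    needs = grid_needs("medium", "medium"),
    interventions = iv_defaults(counseling = TRUE),
    horizon = horizon %||% 30L, seed = seed
  )
  flags <- combo_flags()
  for (k in seq_len(nrow(flags))) {
    local({
      row <- flags[k, ]
      nm <- if (row$plan == "none") "no_intervention" else row$plan
      builders[[nm]] <<- function(seed, horizon) simulation_config(
        needs = grid_needs("low", "high"),
        interventions = iv_defaults(supply = row$supply, review = row$review,
                                    official = row$official,
                                    counseling = row$counseling),
        horizon = horizon %||% 30L, seed = seed
      )
    })
  }
  builders$china_case <- function(seed, horizon) simulation_config(
    model = case_model(),
    needs = needs_spec(m0_mean = 0.5, s0_mean = 0),
    interventions = intervention_config(
      supply_enabled = TRUE, q_move = 1,
      review_guidance_enabled = TRUE, t_exam = 1L,
      official_enabled = TRUE, gov_strength = 10, t_timelyG = 2L, tr_gov = 1,
      counseling_enabled = TRUE, str_pr = 1, t_timelyP = 1L, tr_ol = 0.8
    ),
    horizon = horizon %||% 20L, seed = seed
  )
  builders$uk_march <- function(seed, horizon) simulation_config(
    model = case_model(),
    needs = needs_spec(m0_mean = 0.6, s0_mean = 0.3),
    interventions = intervention_config(
      supply_enabled = TRUE, q_move = 1,
      review_guidance_enabled = FALSE,
      official_enabled = TRUE, gov_strength = 1, t_timelyG = 1L, tr_gov = 0.5,
      counseling_enabled = TRUE, str_pr = 1, t_timelyP = 1L, tr_ol = 0.8
    ),
    horizon = horizon %||% 20L, seed = seed
  )
  builders$uk_december <- function(seed, horizon) simulation_config(
    model = case_model(),
    needs = needs_spec(m0_mean = 0.8, s0_mean = 0.6),
    interventions = intervention_config(
      supply_enabled = TRUE, q_move = 0.5,
      review_guidance_enabled = TRUE, t_exam = 1L,
      official_enabled = TRUE, gov_strength = 1, t_timelyG = 1L, tr_gov = 0.5,
      counseling_enabled = TRUE, str_pr = 0.5, t_timelyP = 2L, tr_ol = 0.8
    ),
    horizon = horizon %||% 20L, seed = seed
  )
  builders
}

#' The built-in scenario presets
#'
#' One preset per study: the five need-level grid scenarios, the
#' single-mechanism studies (supply monitoring at `Q_move` 1 and 2, review
#' and guidance at `t_exam` 0/1/2, official response at baseline / low
#' trust / delayed, psychological counseling), the ten combination
#' strategies plus the comprehensive plan and the no-intervention baseline
#' in the (low safety, high material) regime, and the three case
#' parameterizations (China/Shijiazhuang, UK March, UK December).
#'
#' @return a tibble with columns `name` and `description`.
#' @seealso [scenario_preset()] to materialize one preset as a
#'   [simulation_config()].
#' @examples
#' scenario_library()
#' @export
scenario_library <- function() {
  nms <- names(preset_builders())
  tibble::tibble(
    name = nms,
    description = purrr::map_chr(nms, preset_description)
  )
}

preset_description <- function(name) {
  flags <- combo_flags()
  if (name %in% c(flags$plan, "no_intervention")) {
    key <- if (name == "no_intervention") "none" else name
    return(sprintf("Combination strategy (low safety, high material need): %s",
                   flags$combination[flags$plan == key]))
  }
  switch(name,
    grid_highS_highM = "No intervention; high safety, high material need",
    grid_highS_lowM = "No intervention; high safety, low material need",
    grid_lowS_highM = "No intervention; low safety, high material need",
    grid_lowS_lowM = "No intervention; low safety, low material need",
    grid_medS_medM = "No intervention; medium safety, medium material need",
    no_intervention_highM = "No intervention; low safety, high material need",
    supply_qmove1 = "Supply monitoring, Q_move = 1; high/high needs",
    supply_qmove2 = "Supply monitoring, Q_move = 2; high/high needs",
    review_texam0 = "Information review & guidance, t_exam = 0; medium/medium needs",
    review_texam1 = "Information review & guidance, t_exam = 1; medium/medium needs",
    review_texam2 = "Information review & guidance, t_exam = 2; medium/medium needs",
    official_baseline = "Official response (Gov = 1, TR_gov = 1, delay 1); low/high needs",
    official_low_trust = "Official response with low trust (TR_gov = 0.5); low/high needs",
    official_delayed = "Official response with delay t_timelyG = 3; medium/medium needs",
    counseling = "Psychological counseling (Str_PR = 1, TR_ol = 1, delay 1); medium/medium needs",
    china_case = "China (Shijiazhuang) case: all mechanisms, Gov = 10, thresholds 0.6/0.5",
    uk_march = "UK March case: supply + official + counseling, TR_gov = 0.5",
    uk_december = "UK December case: all mechanisms, Q_move = 0.5, Str_PR = 0.5",
    "Scenario preset"
  )
}

#' Materialize a named scenario preset
#'
#' @param name a preset name from [scenario_library()].
#' @param seed master seed for the materialized configuration.
#' @param horizon optional override of the preset's default horizon.
#' @return a [simulation_config()] object.
#' @examples
#' cfg <- scenario_preset("no_intervention", seed = 1)
#' cfg$interventions$supply_enabled
#' @export
scenario_preset <- function(name, seed = 1L, horizon = NULL) {
  builders <- preset_builders()
  if (!name %in% names(builders)) {
    rlang::abort(
      sprintf("unknown preset '%s'. Available presets:\n  %s",
              name, paste(names(builders), collapse = ", ")),
      class = "panicabm_unknown_preset"
    )
  }
  builders[[name]](seed = seed, horizon = horizon)
}

#' Combination-strategy study
#'
#' Runs the no-intervention baseline, the ten pairwise/triple combination
#' strategies and the comprehensive plan in the (low safety, high material)
#' regime, aggregating over replicates: mean peak buyers, median
#' time-to-peak, the fraction of replicates whose panic buying stopped, the
#' median stop time among stopped replicates, and the mean final buyer
#' count.
#'
#' @param replicates replicates per strategy.
#' @param seed base seed (shared across strategies so they face the same
#'   replicate seeds).
#' @param horizon ticks per run.
#' @param n_agents population size.
#' @return a tibble with 12 strategy rows.
#' @examples
#' \donttest{
#' combination_study(replicates = 2, seed = 1, n_agents = 200)
#' }
#' @export
combination_study <- function(replicates = 10L, seed = 1L, horizon = 30L,
                              n_agents = 1000L) {
  flags <- combo_flags()
  purrr::pmap_dfr(flags, function(plan, combination, supply, review,
                                  official, counseling) {
    cfg <- simulation_config(
      network = network_params(n_agents = n_agents),
      needs = grid_needs("low", "high"),
      interventions = iv_defaults(supply = supply, review = review,
                                  official = official,
                                  counseling = counseling),
      horizon = horizon, seed = seed
    )
    reps <- run_replicates(cfg, replicates)
    agg <- glance(reps)
    tibble::tibble(
      plan = plan, combination = combination,
      mean_max_buyers = agg$mean_max_buyers,
      median_t_max = agg$median_t_max,
      stopped_fraction = agg$stopped_fraction,
      median_t_stop = agg$median_t_stop,
      mean_final_buyers = agg$mean_final_buyers
    )
  })
}

#' Random-needs sweep
#'
#' Repeats the simulation with randomly drawn initial need levels: per run,
#' the material-need and safety-need means are drawn uniformly on \[0, 1\]
#' (individual draws stay normal with sd 0.15, clipped), the model runs to
#' the horizon, and the final buyer count is recorded. Three intervention
#' regimes are supported: no intervention, the combined plan without supply
#' monitoring, and the comprehensive plan including supply monitoring.
#'
#' @param n_runs number of sweep runs.
#' @param scenario `"none"`, `"no_supply"` or `"comprehensive"`.
#' @param seed master seed (drives both the mean draws and the run seeds).
#' @param horizon ticks per run (final buyers are read at this tick).
#' @param n_agents population size.
#' @return a tibble with one row per run: `run`, `scenario`, `s0_mean`,
#'   `m0_mean`, `final_buyers`, `stopped`.
#' @examples
#' \donttest{
#' needs_sweep(n_runs = 3, scenario = "comprehensive", n_agents = 200,
#'             horizon = 30)
#' }
#' @export
needs_sweep <- function(n_runs = 100L,
                        scenario = c("none", "no_supply", "comprehensive"),
                        seed = 1L, horizon = 100L, n_agents = 1000L) {
  scenario <- rlang::arg_match(scenario)
  n_runs <- check_count(n_runs, "n_runs", min = 1L)
  iv <- switch(scenario,
    none = iv_defaults(),
    no_supply = iv_defaults(review = TRUE, official = TRUE, counseling = TRUE),
    comprehensive = iv_defaults(supply = TRUE, review = TRUE, official = TRUE,
                                counseling = TRUE)
  )
  set.seed(derive_seed(seed, 4L))
  m_means <- stats::runif(n_runs)
  s_means <- stats::runif(n_runs)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    cfg <- simulation_config(
      network = network_params(n_agents = n_agents),
      needs = needs_spec(m0_mean = m_means[r], s0_mean = s_means[r]),
      interventions = iv, horizon = horizon, seed = seed + r
    )
    sim <- run_simulation(cfg)
    s <- summarize_run(sim)
    tibble::tibble(run = r, scenario = scenario,
                   s0_mean = s_means[r], m0_mean = m_means[r],
                   final_buyers = s$final_buyers, stopped = s$stopped)
  })
}
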