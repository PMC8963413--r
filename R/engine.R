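#' Run one seeded simulation
#'
#' Executes the synchronous tick pipeline for `horizon` ticks. Per tick
#' `t >= 2`: (1) deplete the stock by the previous tick's buyers;
#' (2) supply-monitoring check/replenish; (3) assign random purchase orders
#' among previous buyers; (4) previous buyers compute perceived stock and
#' self experience, previous non-buyers the neighbor-information influence
#' (reviewed and delayed when guidance is on); (5) update material need,
#' including any official-response subtraction; (6) compute herd pressure
#' from previous-tick neighbor states; (7) update panic emotion, including
#' any counseling subtraction; (8) recompute decision weights and attitude;
#' (9) recompute the buying state. Buyers then publish posts consumed
#' `1 + t_exam` ticks later. Tick 1 records the initialized population.
#'
#' The run is fully deterministic given `(config, seed)`: the network build,
#' the initial draws and the per-tick order permutations use independent
#' derived seed streams.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `panic_sim`: a list carrying the per-tick
#'   tibble `series` (columns `tick`, `buyer_count`, `stock`,
#'   `mean_emotion`, `posts_true`, `posts_rumor`, `replenished`; the post
#'   counts are `NA` when review is disabled), the `config`, the `network`,
#'   and `n_replenishments`.
#' @examples
#' cfg <- simulation_config(
#'   network = network_params(n_agents = 200),
#'   needs = needs_spec(m0_mean = 0.8, s0_mean = 0.2),
#'   horizon = 15, seed = 7
#' )
#' sim <- run_simulation(cfg)
#' dplyr::glimpse(sim$series)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mp <- config$model
  iv <- config$interventions
  horizon <- config$horizon
  seed <- config$seed

  net <- if (inherits(config$network, "social_network")) {
    config$network
  } else {
    generate_network(config$network, seed = seed)
  }
  n <- net$n
  adj <- net$adjacency
  deg <- net$degree
  trust <- ifelse(net$role == "opinion_leader", iv$tr_ol, iv$tr_ordinary)

  i_gov <- if (iv$official_enabled) {
    official_effect(iv$gov_strength, iv$tr_gov, iv$t_timelyG, horizon)
  } else {
    rep(0, horizon)
  }
  pr <- if (iv$counseling_enabled) {
    counseling_effect(iv$str_pr, iv$tr_ol, iv$t_timelyP, horizon)
  } else {
    rep(0, horizon)
  }

  pop <- initialize_population(config$needs, net, mp, seed = seed)
  M <- pop$M; S <- pop$S; con <- pop$con
  E <- pop$E; A <- pop$A; state <- pop$state

  review <- iv$review_guidance_enabled
  delay <- if (review) iv$t_exam else 0L

  buyer_count <- integer(horizon)
  stock <- numeric(horizon)
  mean_emotion <- numeric(horizon)
  posts_true <- rep(NA_integer_, horizon)
  posts_rumor <- rep(NA_integer_, horizon)
  replenished <- logical(horizon)

  # pending neighbor-information contributions, indexed by application tick:
  # each entry holds the publishers' signed contribution vector and their
  # buying indicator at publication time (the NI_i denominator).
  pending <- vector("list", horizon)

  set.seed(derive_seed(seed, 3L))  # tick stream: orders + posting draws

  publish <- function(t, A_now, state_now, Q_now) {
    posting <- state_now == 1L
    if (iv$post_probability < 1 && any(posting)) {
      posting <- posting & (stats::runif(n) < iv$post_probability)
    }
    tf <- rep(1, n)
    if (review) {
      type <- classify_post(A_now, Q_now, mp$d_SD, mp$d_A)
      tf <- authenticity_factor(type, mp$gamma)
      posts_true[t] <<- sum(posting & type == 2L)
      posts_rumor[t] <<- sum(posting & type == 1L)
    }
    contrib <- numeric(n)
    contrib[posting] <- (A_now[posting] - mp$d_A) * trust[posting] * tf[posting]
    app_tick <- t + 1L + delay
    if (app_tick <= horizon) {
      pending[[app_tick]] <<- list(contrib = contrib,
                                   publishers = as.numeric(posting))
    }
  }

  Q <- 1
  buyer_count[1L] <- sum(state)
  stock[1L] <- Q
  mean_emotion[1L] <- mean(E)
  n_replenishments <- 0L
  publish(1L, A, state, Q)

  t <- 2L
  while (t <= horizon) {
    prev_state <- state
    prev_buyers <- which(prev_state == 1L)

    Q_prev <- Q
    Q <- deplete_materials(Q_prev, length(prev_buyers), n)
    if (iv$supply_enabled) {
      rep_out <- replenish(Q, mp$d_SD, iv$q_move)
      Q <- rep_out$Q
      if (rep_out$event) {
        replenished[t] <- TRUE
        n_replenishments <- n_replenishments + 1L
      }
    }

    orders <- assign_orders(prev_buyers)
    Self <- numeric(n)
    if (length(prev_buyers) > 0L) {
      q_seen <- if (iv$perceive_current_stock) Q else Q_prev
      Q_i <- perceived_materials(q_seen, unname(orders), n)
      Self[prev_buyers] <- mp$mu * (mp$d_SD - Q_i)
    }

    I_net <- numeric(n)
    batch <- pending[[t]]
    if (!is.null(batch)) {
      n_posting_nb <- as.numeric(adj %*% batch$publishers)
      total <- as.numeric(adj %*% batch$contrib)
      I_net <- ifelse(n_posting_nb > 0, total / n_posting_nb, 0)
      pending[t] <- list(NULL)
    }

    M <- material_need_update(M, t, prev_state, Self, I_net,
                              i_gov = i_gov[t], params = mp)
    NI_i <- as.numeric(adj %*% prev_state)
    F_herd <- herd_pressure(NI_i, deg, con)
    E <- emotion(M, S, F_herd, pr = pr[t], params = mp)
    A <- attitude(M, S, E, mp)
    state <- buying_state(A, mp$d_A)

    buyer_count[t] <- sum(state)
    stock[t] <- Q
    mean_emotion[t] <- mean(E)
    publish(t, A, state, Q)
    t <- t + 1L
  }

  series <- tibble::tibble(
    tick = seq_len(horizon),
    buyer_count = buyer_count,
    stock = stock,
    mean_emotion = mean_emotion,
    posts_true = posts_true,
    posts_rumor = posts_rumor,
    replenished = replenished
  )
  structure(
    list(series = series, config = config, network = net,
         n_replenishments = n_replenishments, seed = seed),
    class = "panic_sim"
  )
}

#' Summarize a run's time series
#'
#' Headline statistics of one run: the peak buyer count and the first tick
#' attaining it; whether panic buying stopped (a sustained zero buyer count
#' through the horizon, not a transient dip) and, if so, the first tick of
#' the sustained zero; the number of replenishment events; and the final
#' buyer count.
#'
#' @param x a `panic_sim` object or its `series` tibble.
#' @return a one-row tibble with columns `max_buyers`, `t_max`, `stopped`,
#'   `t_stop` (`NA` when not stopped), `n_replenishments`, `final_buyers`.
#' @examples
#' series <- tibble::tibble(
#'   tick = 1:6, buyer_count = c(0, 800, 400, 0, 0, 0),
#'   stock = 1, mean_emotion = 0.5, posts_true = NA_integer_,
#'   posts_rumor = NA_integer_, replenished = FALSE
#' )
#' summarize_run(series)  # stopped at tick 4
#' @export
summarize_run <- function(x) {
  series <- if (inherits(x, "panic_sim")) x$series else x
  bc <- series$buyer_count
  horizon <- length(bc)
  max_buyers <- max(bc)
  t_max <- which.max(bc)
  nonzero <- which(bc > 0)
  last_nonzero <- if (length(nonzero) == 0L) 0L else max(nonzero)
  stopped <- last_nonzero < horizon
  t_stop <- if (!stopped) NA_integer_ else max(last_nonzero + 1L, 1L)
  if (length(nonzero) == 0L) t_stop <- 1L
  tibble::tibble(
    max_buyers = max_buyers,
    t_max = as.integer(t_max),
    stopped = stopped,
    t_stop = as.integer(t_stop),
    n_replenishments = as.integer(sum(series$replenished)),
    final_buyers = bc[horizon]
  )
}

#' Run seeded replicates
#'
#' Replicate `r` reruns the configuration with seed `base_seed + r`, so the
#' network and all initial draws are regenerated per replicate. Results are
#' order-stable and reproducible.
#'
#' @param config a [simulation_config()] object; its `seed` is the base seed.
#' @param replicates number of replicates `R >= 1`.
#' @return an object of class `panic_sim_set`: a tibble with one row per
#'   replicate (`replicate`, `seed`, the [summarize_run()] columns, and a
#'   `series` list-column).
#' @examples
#' cfg <- simulation_config(network = network_params(150), horizon = 10)
#' reps <- run_replicates(cfg, replicates = 3)
#' reps$max_buyers
#' @export
run_replicates <- function(config, replicates = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  replicates <- check_count(replicates, "replicates", min = 1L)
  rows <- purrr::map(seq_len(replicates), function(r) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    sim <- run_simulation(cfg_r)
    dplyr::bind_cols(
      tibble::tibble(replicate = r, seed = cfg_r$seed),
      summarize_run(sim),
      tibble::tibble(series = list(sim$series))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("panic_sim_set", class(out))
  out
}

#' Write a run to plain-text outputs
#'
#' One CSV for the time series and (optionally) one JSON file for the run
#' summary, both reproducible byte-for-byte for a fixed `(config, seed)`.
#'
#' @param sim a `panic_sim` object.
#' @param csv_file path for the per-tick CSV.
#' @param json_file optional path for the summary JSON (requires jsonlite).
#' @return the paths, invisibly.
#' @export
write_run <- function(sim, csv_file, json_file = NULL) {
  stopifnot(inherits(sim, "panic_sim"))
  utils::write.csv(sim$series, csv_file, row.names = FALSE)
  if (!is.null(json_file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      rlang::abort("writing JSON summaries requires the jsonlite package.")
    }
    jsonlite::write_json(as.list(summarize_run(sim)), json_file,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_file, json_file))
}

#' @export
print.panic_sim <- function(x, ...) {
  s <- summarize_run(x)
  cat(sprintf(
    paste0("<panic_sim> %d agents, %d ticks, seed %d\n",
           "  peak %d buyers at tick %d; %s; %d replenishment(s)\n"),
    x$network$n, nrow(x$series), x$seed,
    s$max_buyers, s$t_max,
    if (s$stopped) sprintf("stopped at tick %d", s$t_stop) else "did not stop",
    s$n_replenishments
  ))
  invisible(x)
}
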