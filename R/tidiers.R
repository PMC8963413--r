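#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' `tidy()` returns the per-tick time series; `glance()` the one-row run
#' summary from [summarize_run()].
#'
#' @param x a `panic_sim` object.
#' @param ... unused.
#' @return a tibble.
#' @method tidy panic_sim
#' @export
tidy.panic_sim <- function(x, ...) {
  x$series
}

#' @rdname tidy.panic_sim
#' @method glance panic_sim
#' @export
glance.panic_sim <- function(x, ...) {
  summarize_run(x)
}

#' Tidy a replicate set
#'
#' `tidy()` returns one row per replicate (the summary columns without the
#' nested series); `glance()` aggregates across replicates: mean peak,
#' median time-to-peak, stopped fraction, median stop time among stopped
#' runs, mean final buyers and mean replenishment count.
#'
#' @param x a `panic_sim_set` from [run_replicates()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy panic_sim_set
#' @export
tidy.panic_sim_set <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"series")
}

#' @rdname tidy.panic_sim_set
#' @method glance panic_sim_set
#' @export
glance.panic_sim_set <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  tibble::tibble(
    n_replicates = nrow(tbl),
    mean_max_buyers = mean(tbl$max_buyers),
    median_t_max = stats::median(tbl$t_max),
    stopped_fraction = mean(tbl$stopped),
    median_t_stop = stats::median(tbl$t_stop[tbl$stopped], na.rm = TRUE),
    mean_final_buyers = mean(tbl$final_buyers),
    mean_replenishments = mean(tbl$n_replenishments)
  )
}

#' Plot a simulation run
#'
#' Buyer count, material stock and mean panic emotion over time, faceted on
#' free y scales.
#'
#' @param object a `panic_sim` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot panic_sim
#' @export
autoplot.panic_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$series, "tick", "buyer_count", "stock", "mean_emotion"),
    -"tick", names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tick, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "tick", y = NULL,
                  title = "Panic-buying simulation") +
    ggplot2::theme_minimal()
}

#' Plot buyer-count trajectories of a replicate set
#'
#' @param object a `panic_sim_set`.
#' @param ... unused.
#' @return a ggplot with one line per replicate.
#' @method autoplot panic_sim_set
#' @export
autoplot.panic_sim_set <- function(object, ...) {
  long <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(object), "replicate", "series"),
    "series"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tick, y = .data$buyer_count,
                                     group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "tick", y = "panic buyers",
                  title = "Replicate buyer-count trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a random-needs sweep
#'
#' Final buyer count against the drawn initial need means, colored by
#' outcome, one panel per intervention scenario.
#'
#' @param sweep a tibble from [needs_sweep()] (scenarios may be row-bound).
#' @return a ggplot.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$s0_mean, y = .data$m0_mean,
                                      color = .data$final_buyers)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "initial safety-need mean", y = "initial material-need mean",
                  color = "final buyers",
                  title = "Random-needs sweep: final panic buyers") +
    ggplot2::theme_minimal()
}
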