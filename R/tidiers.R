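#' Tidy a capacity result
#'
#' Returns the per-cell grid in long form, one row per (condition, CA3
#' size, set size, seed), without the per-pattern list column.
#'
#' @param x A [capacity_sweep()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.capacity_result <- function(x, ...) {
  out <- tibble::as_tibble(x)[, c("condition", "ca3_size", "dg_size",
                                  "set_size", "seed", "name_error")]
  out
}

#' Summarise a capacity result
#'
#' One row per (condition, CA3 size, set size): mean and standard deviation
#' of Name Error across seeds, plus the seed count.
#'
#' @inheritParams tidy.capacity_result
#' @return A tibble.
#' @export
glance.capacity_result <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$condition, .data$ca3_size, .data$set_size) |>
    dplyr::summarise(mean_name_error = mean(.data$name_error),
                     sd_name_error = stats::sd(.data$name_error),
                     n_seeds = dplyr::n(), .groups = "drop")
}

#' Plot a capacity result
#'
#' Mean Name Error against training-set size, one line per learning
#' condition, facetted by CA3 size (the flat analogue of the capacity
#' surface). Points show per-seed values.
#'
#' @param object A [capacity_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capacity_result <- function(object, ...) {
  d <- tidy(object)
  s <- glance(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$set_size,
                                  y = .data$mean_name_error,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(y = .data$name_error),
                        alpha = 0.4, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ca3_size),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "training-set size (patterns)",
                  y = "mean Name Error", colour = "condition") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.capacity_result
#' @param x A [capacity_sweep()] result.
#' @param y Unused.
#' @export
plot.capacity_result <- function(x, y, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
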