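#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a docking result
#'
#' Returns the per-generation history as a tibble: one row per island
#' iteration in scheduler order, with the island's current best energy, the
#' global best-so-far and the simulated completion time.
#'
#' @param x A `docking_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.docking_result <- function(x, ...) {
  x$history
}

#' One-row summary of a docking result
#'
#' @param x A `docking_result`.
#' @param ... Unused.
#' @return A tibble with the optimizer, island count, generations, best total
#'   energy, migration event count and simulated time.
#' @export
glance.docking_result <- function(x, ...) {
  tibble::tibble(
    optimizer = x$config$optimizer,
    n_islands = x$config$n_islands,
    n_pop = x$config$n_pop,
    generations = x$config$generations,
    best_energy = x$best_energy$e_total,
    n_migration_events = nrow(x$events),
    simulated_time = x$simulated_time
  )
}

#' Convergence plot of a docking run
#'
#' Island best energy per generation (one line per island) with the global
#' best-so-far envelope.
#'
#' @param object A `docking_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.docking_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$island_best,
                                  colour = factor(.data$island))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_so_far), colour = "black",
                       linetype = "dashed") +
    ggplot2::labs(x = "island generation", y = "best energy (kcal/mol)",
                  colour = "island",
                  title = "Convergence per island (dashed: global best-so-far)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a timing profile
#'
#' @param profile A `timing_profile`.
#' @return A ggplot object.
#' @export
plot_timing_profile <- function(profile) {
  d <- tibble::tibble(category = names(profile$fractions),
                      fraction = as.numeric(profile$fractions))
  d$category <- factor(d$category, levels = d$category)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of accounted run cost") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
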