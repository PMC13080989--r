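# broom-style accessors and ggplot2 autoplot methods for run objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GA run into its per-generation trajectory
#' @param x `mf_ga_run`
#' @param ... unused
#' @return tibble: generation, best_fitness, mean_fitness, best_genes
#' @method tidy mf_ga_run
#' @export
tidy.mf_ga_run <- function(x, ...) x$trajectory

#' One-row summary of a GA run
#' @param x `mf_ga_run`
#' @param ... unused
#' @return tibble: generations, unique evaluations, space size, evaluated
#'   fraction, best fitness
#' @method glance mf_ga_run
#' @export
glance.mf_ga_run <- function(x, ...) {
  tibble::tibble(
    n_generations = max(x$trajectory$generation),
    n_evaluations = nrow(x$evaluations),
    space_size = x$space_size,
    frac_evaluated = nrow(x$evaluations) / x$space_size,
    best_fitness = x$best$fitness,
    seed = x$seed
  )
}

#' Convergence plot of a GA run
#'
#' Best and population-mean fitness per generation.
#' @param object `mf_ga_run`
#' @param ... unused
#' @return a ggplot
#' @method autoplot mf_ga_run
#' @export
autoplot.mf_ga_run <- function(object, ...) {
  d <- object$trajectory |>
    tidyr::pivot_longer(c("best_fitness", "mean_fitness"),
                        names_to = "series", values_to = "fitness") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         best_fitness = "best",
                                         mean_fitness = "population mean"))
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "generation", y = "fitness", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a MOP structure into its atom table
#' @param x `mf_mop`
#' @param ... unused
#' @return atom tibble with unit provenance
#' @method tidy mf_mop
#' @export
tidy.mf_mop <- function(x, ...) x$atoms

#' One-row summary of a MOP structure
#' @param x `mf_mop`
#' @param ... unused
#' @return tibble: model, scale, atom and unit counts, cavity descriptors
#' @method glance mf_mop
#' @export
glance.mf_mop <- function(x, ...) {
  cav <- cavity_report(x)
  tibble::tibble(
    model = x$model_name, scale = x$scale,
    n_atoms = nrow(x$atoms), n_units = length(unique(x$atoms$unit)),
    inner_sphere_diameter = cav$inner_sphere_diameter,
    inner_sphere_volume = cav$inner_sphere_volume,
    window_diameter = cav$window_diameter
  )
}

#' Projection plot of a MOP structure
#'
#' Atoms projected on two coordinates, coloured by building unit.
#' @param object `mf_mop`
#' @param axes which coordinates to plot (two of "x","y","z")
#' @param ... unused
#' @return a ggplot
#' @method autoplot mf_mop
#' @export
autoplot.mf_mop <- function(object, axes = c("x", "y"), ...) {
  stopifnot(length(axes) == 2, all(axes %in% c("x", "y", "z")))
  d <- object$atoms
  ggplot2::ggplot(d, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                  colour = factor(.data$unit))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$element == "H"), alpha = 0.7) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 0.6, `FALSE` = 1.6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "unit", x = paste(axes[1], "(A)"), y = paste(axes[2], "(A)")) +
    ggplot2::theme_minimal()
}
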