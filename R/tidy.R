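# broom-style accessors and ggplot2 methods for fitted assembly objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-contig summary of an assembly
#'
#' @param x An `sx_assembly`.
#' @param ... Unused.
#' @return Tibble with one row per contig: class, layout length, read
#'   count, consensus length.
#' @export
tidy.sx_assembly <- function(x, ...) {
  x$contigs %>% arrange(desc(.data$length))
}

#' One-row assembly summary
#'
#' @param x An `sx_assembly`.
#' @param genome_size Optional genome size for NG50.
#' @param ... Unused.
#' @return One-row tibble: contig counts by class, total bases, N50, NG50,
#'   error-model median/MAD/cutoff.
#' @export
glance.sx_assembly <- function(x, genome_size = NULL, ...) {
  lens <- nchar(x$consensus)
  tibble(
    n_contigs = nrow(x$contigs),
    n_repeat = sum(x$contigs$class == "repeat"),
    n_bubble = sum(x$contigs$class == "bubble"),
    n_unassembled = length(x$unassembled),
    total_bases = sum(lens),
    n50 = nx_stat(lens),
    ng50 = if (is.null(genome_size)) NA_integer_ else
      nx_stat(lens, total = genome_size),
    error_median = x$model$median,
    error_mad = x$model$mad,
    error_cutoff = x$model$cutoff
  )
}

#' Plot contig lengths by class
#'
#' @param object An `sx_assembly`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sx_assembly <- function(object, ...) {
  d <- tidy(object) %>% mutate(contig = factor(.data$contig, .data$contig))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contig, y = .data$length,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "contig", y = "layout length (bp)", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot the best-edge error-rate model
#'
#' Histogram of best-edge error rates with the automatically selected
#' cutoff (median + 6 MAD) as a dashed line.
#'
#' @param object An `error_model`.
#' @param errors Optional raw error-rate vector to histogram.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_model <- function(object, errors = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(errors)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(error = errors),
      ggplot2::aes(x = .data$error), bins = 40, fill = "grey70"
    )
  }
  p +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "overlap error rate", y = "best edges") +
    ggplot2::theme_minimal()
}

#' Plot a contig error profile
#'
#' @param profile Output of [compute_error_profile()].
#' @param cutoff Optional global cutoff line.
#' @return A ggplot.
#' @export
plot_error_profile <- function(profile, cutoff = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$win_start,
                                             y = .data$median)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$median - .data$mad, 0),
                                      ymax = .data$median + .data$mad),
                         alpha = 0.3) +
    ggplot2::labs(x = "contig position (bp)", y = "local overlap error") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  p
}
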