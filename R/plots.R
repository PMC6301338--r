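# ggplot2 views of summaries, diffusion results and heat trajectories.

#' @exportS3Method ggplot2::autoplot
autoplot.network_summary <- function(object, ...) {
  counts <- bind_rows(
    tibble(kind = "node function", key = names(object$function_counts),
           count = as.integer(object$function_counts)),
    tibble(kind = "relation", key = names(object$relation_counts),
           count = as.integer(object$relation_counts)),
    tibble(kind = "namespace", key = names(object$namespace_counts),
           count = as.integer(object$namespace_counts))
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$key, .data$count),
                                       y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Knowledge network contents")
}

#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_result <- function(object, top_n = 20L, ...) {
  tab <- head(tidy(object), top_n)
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$node, abs(.data$heat)),
                                    y = .data$heat)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "final heat",
                  title = "Final heats after sign-aware diffusion")
}

#' Parallel-coordinates view of heat trajectories
#'
#' One line per biological process across the experiments (e.g. disease
#' stages), colored by K-means cluster, so progression patterns of
#' groups of processes can be read directly.
#'
#' @param object A `heat_trajectories` from [cluster_trajectories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.heat_trajectories <- function(object, ...) {
  tab <- object$trajectories
  long <- tidyr::pivot_longer(tab, cols = -c("node", "cluster"),
                              names_to = "experiment", values_to = "heat")
  long$experiment <- factor(long$experiment,
                            levels = setdiff(names(tab), c("node", "cluster")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$experiment, y = .data$heat,
                                     group = .data$node,
                                     color = factor(.data$cluster))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "final heat", color = "cluster",
                  title = "Biological process heat trajectories")
}
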