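#' Plot an ensemble population time course
#'
#' Mean viable/apoptotic/necrotic counts with a plus/minus one standard
#' deviation band. Requires ggplot2.
#'
#' @param reps a [run_replicates()] result.
#' @return a ggplot object.
#' @export
plot_population <- function(reps) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  s <- reps$summary
  long <- do.call(rbind, lapply(c("viable", "apoptotic", "necrotic"),
                                function(k) {
    data.frame(time_days = s$time / 1440, compartment = k,
               mean = s[[paste0(k, "_mean")]], sd = s[[paste0(k, "_sd")]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days, y = .data$mean,
                                     color = .data$compartment,
                                     fill = .data$compartment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "cells",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a release-state heatmap
#'
#' Rows are cells, columns the m release states (0 = fully loaded).
#'
#' @param mat a [release_state_histogram()] matrix.
#' @return a ggplot object.
#' @export
plot_release_states <- function(mat) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(cell = rep(seq_len(nrow(mat)), ncol(mat)),
                   state = rep(seq_len(ncol(mat)) - 1L, each = nrow(mat)),
                   count = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$cell,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "NPs") +
    ggplot2::labs(x = "release state", y = "cell") +
    ggplot2::theme_minimal()
}
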