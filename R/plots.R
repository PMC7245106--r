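# ggplot2 displays for the main result types.

#' Plot a seizure-pair matrix as a heat map
#'
#' @param object An `ictal_dissim` (dissimilarity or temporal distance
#'   matrix).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ictal_dissim <- function(object, ...) {
  m <- unclass(object)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- tibble::tibble(
    a = factor(rep(ids, times = ncol(m)), levels = ids),
    b = factor(rep(ids, each = nrow(m)), levels = rev(ids)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "value") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a temporal correlation pattern
#'
#' Valid timescales are drawn as bars (Spearman rho vs. timescale); masked
#' timescales are marked along the axis.
#'
#' @param object An `ictal_tcp`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ictal_tcp <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df[df$valid, ],
                  ggplot2::aes(x = .data$timescale, y = .data$rho)) +
    ggplot2::geom_col(width = 0.2, fill = "#2c7fb8") +
    ggplot2::geom_point(data = df[!df$valid, ],
                        ggplot2::aes(y = 0), shape = 4, colour = "grey60") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "timescale T (days)", y = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Plot seizure pathways in a 2D projection
#'
#' @param projection Tibble from [mds_project()].
#' @param windows Optional window-label tibble (as from
#'   [assemble_cohort_matrix()]) used to colour and connect pathways.
#' @return A ggplot.
#' @export
plot_pathways <- function(projection, windows = NULL) {
  df <- projection
  if (!is.null(windows)) {
    df <- dplyr::bind_cols(df, windows[c("seizure_id", "window")])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                     colour = .data$seizure_id)) +
      ggplot2::geom_path(ggplot2::aes(group = .data$seizure_id), alpha = 0.7) +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "seizure") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "MDS 1", y = "MDS 2") +
      ggplot2::theme_minimal()
  }
}

#' Plot model likelihoods over the parameter simplex
#'
#' @param object An `ictal_likelihoods`.
#' @param ... Unused.
#' @return A ggplot of likelihood against the linear and circadian weights.
#' @export
autoplot.ictal_likelihoods <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$l, y = .data$c, fill = .data$likelihood)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "L (%)", limits = c(0, 100)) +
    ggplot2::labs(x = "linear weight l", y = "circadian weight c") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
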