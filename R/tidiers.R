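#' Tidiers and plots for pipeline objects
#'
#' Broom-style accessors: `tidy()` returns the per-step (or per-row)
#' observations of an object as a tibble, `glance()` a one-row summary;
#' `autoplot()` draws the standard diagnostic for each result type.
#'
#' @param x a `removal_trace`, `community_partition`,
#'   `dissimilarity_profile` or `bootstrap_summary`.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.removal_trace <- function(x, ...) x$steps

#' @rdname tidiers
#' @export
glance.removal_trace <- function(x, ...) {
  best <- if (nrow(x$steps) > 0) which.max(x$steps$modularity) else NA_integer_
  tibble(
    n_steps = nrow(x$steps),
    n_events = nrow(x$events),
    max_modularity = if (is.na(best)) NA_real_ else x$steps$modularity[best],
    step_max_modularity = if (is.na(best)) NA_integer_ else x$steps$step[best],
    final_communities = if (nrow(x$steps) > 0) {
      x$steps$n_communities[nrow(x$steps)]
    } else {
      dplyr::n_distinct(x$memberships[, 1L])
    },
    completed = x$completed
  )
}

#' @rdname tidiers
#' @export
tidy.community_partition <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("organism", "community", "is_isolated")])
}

#' @rdname tidiers
#' @export
glance.community_partition <- function(x, ...) {
  tibble(
    n_communities = dplyr::n_distinct(x$community),
    n_isolated = sum(x$is_isolated),
    largest = max(table(x$community)),
    modularity = attr(x, "modularity")
  )
}

#' @rdname tidiers
#' @export
tidy.bootstrap_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("group", "support", "n_reps")])
}

#' @rdname tidiers
#' @param object object to plot.
#' @export
autoplot.dissimilarity_profile <- function(object, ...) {
  peaks <- profile_peaks(object)
  df <- tibble::as_tibble(unclass(object)[c("sigma", "delta")])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(sigma),
      y = expression(delta(sigma, sigma + Delta * sigma)),
      title = paste0(
        "Dissimilarity profile - ",
        attr(object, "layer_name")
      )
    )
  if (length(peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = peaks, linetype = "dashed",
      colour = "grey50"
    )
  }
  p
}

#' @rdname tidiers
#' @export
autoplot.removal_trace <- function(object, ...) {
  df <- object$steps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$modularity)) +
    ggplot2::geom_vline(
      xintercept = object$events$step,
      linetype = "dotted", colour = "grey60"
    ) +
    ggplot2::labs(
      x = "removal step", y = "multilayer modularity Q",
      title = "Modularity along the removal trace"
    )
}

#' @rdname tidiers
#' @export
autoplot.bootstrap_summary <- function(object, ...) {
  df <- tidy.bootstrap_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group,
    y = .data$support
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(
      x = NULL, y = "bootstrap support (%)",
      title = paste0("Community support (", df$n_reps[1], " replicates)")
    )
}
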