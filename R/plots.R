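#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an interaction scan
#'
#' Lollipop chart of interaction values by variable set, coloured by order;
#' non-finite values are dropped with a message.
#'
#' @param object An [interaction_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (any(!df$finite)) {
    message(sum(!df$finite), " non-finite interaction(s) not shown.")
    df <- df[df$finite, ]
  }
  df$variables <- stats::reorder(df$variables, df$order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variables, y = .data$value,
                                   colour = factor(.data$order))) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$variables, yend = 0),
                          linewidth = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "interaction (nats)", colour = "order",
                  title = if (isTRUE(df$dual[1])) "Dual model-free interactions"
                          else "Model-free interactions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an association panel
#'
#' Tile display of the sign and significance of every metric in an
#' [association_panel()], mirroring the qualitative comparison of causal
#' dynamics: green positive, red negative, blank not significant.
#'
#' @param object An [association_panel()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_panel <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$state <- ifelse(!df$defined | is.na(df$significant), "undefined",
              ifelse(!df$significant, "n.s.",
              ifelse(df$value > 0, "positive", "negative")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variables, y = .data$metric,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.5) +
    ggplot2::scale_fill_manual(values = c(positive = "#2e7d32",
                                          negative = "#c62828",
                                          n.s. = "grey85",
                                          undefined = "grey50")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a joint table
#'
#' Bar chart of state probabilities, states labelled by their codes.
#'
#' @param object A [joint_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_table <- function(object, ...) {
  vars <- jt_vars(object)
  df <- tibble::as_tibble(as.data.frame(object))
  df$state <- do.call(paste, c(df[vars], sep = ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$prob)) +
    ggplot2::geom_col(fill = "#37474f") +
    ggplot2::labs(x = paste(vars, collapse = ""), y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom rlang .data
NULL
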