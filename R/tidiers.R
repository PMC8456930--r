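#' Tidiers and plots for oxdock result objects
#'
#' broom-style `tidy()` / `glance()` methods and ggplot2 `autoplot()` methods
#' for the package's result classes.  `tidy()` returns the per-row detail as a
#' plain tibble; `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param object A result object (autoplot).
#' @param ... Unused.
#' @name oxdock-tidiers
NULL

strip_tbl <- function(x) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname oxdock-tidiers
#' @method tidy oxd_match_report
#' @export
tidy.oxd_match_report <- function(x, ...) strip_tbl(x)

#' @rdname oxdock-tidiers
#' @method glance oxd_match_report
#' @export
glance.oxd_match_report <- function(x, ...) {
  tibble(overall = pharmacophore_pass(x),
         n_pass = sum(x$pass), n_criteria = nrow(x))
}

#' @rdname oxdock-tidiers
#' @method tidy oxd_trajectory
#' @export
tidy.oxd_trajectory <- function(x, ...) strip_tbl(x)

#' @rdname oxdock-tidiers
#' @method glance oxd_trajectory
#' @export
glance.oxd_trajectory <- function(x, ...) {
  tibble(true_e = attr(x, "true_e"),
         stop_conversion = attr(x, "stop_conversion"),
         method = attr(x, "method"),
         n_points = nrow(x),
         final_ee_product = x$ee_product[nrow(x)])
}

#' @rdname oxdock-tidiers
#' @method tidy oxd_prediction
#' @export
tidy.oxd_prediction <- function(x, ...) strip_tbl(x)

#' @rdname oxdock-tidiers
#' @method glance oxd_prediction
#' @export
glance.oxd_prediction <- function(x, ...) {
  unpaired <- attr(x, "unpaired")
  tibble(n_pairs = nrow(x),
         n_unpaired = if (is.null(unpaired)) 0L else nrow(unpaired),
         temperature = attr(x, "temperature"),
         e_cap = attr(x, "e_cap"))
}

#' @rdname oxdock-tidiers
#' @method tidy oxd_resolution_analysis
#' @export
tidy.oxd_resolution_analysis <- function(x, ...) strip_tbl(x)

#' @rdname oxdock-tidiers
#' @method glance oxd_resolution_analysis
#' @export
glance.oxd_resolution_analysis <- function(x, ...) {
  tibble(n_observations = nrow(x), n_feasible = sum(x$feasible),
         temperature = attr(x, "temperature"), e_cap = attr(x, "e_cap"))
}

#' @rdname oxdock-tidiers
#' @method tidy oxd_comparison
#' @export
tidy.oxd_comparison <- function(x, ...) strip_tbl(x)

#' @rdname oxdock-tidiers
#' @method glance oxd_comparison
#' @export
glance.oxd_comparison <- function(x, ...) {
  matched <- sum(x$matched)
  tibble(n_keys = nrow(x), n_matched = matched,
         n_concordant = sum(x$concordant),
         concordance = if (matched > 0) sum(x$concordant) / matched else NA_real_,
         temperature = attr(x, "temperature"), e_cap = attr(x, "e_cap"))
}

#' @rdname oxdock-tidiers
#' @method autoplot oxd_trajectory
#' @export
autoplot.oxd_trajectory <- function(object, ...) {
  long <- tidy(object) %>%
    tidyr::pivot_longer(c("ee_product", "ee_substrate"),
                        names_to = "series", values_to = "ee")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$conversion, y = .data$ee,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "conversion", y = "enantiomeric excess",
      colour = NULL,
      title = sprintf("Kinetic resolution, E = %.3g", attr(object, "true_e"))
    ) +
    ggplot2::ylim(0, 1)
}

#' @rdname oxdock-tidiers
#' @method autoplot oxd_comparison
#' @export
autoplot.oxd_comparison <- function(object, ...) {
  dat <- tidy(object) %>%
    filter(.data$matched) %>%
    mutate(pair = paste0(.data$substrate_id, "-", .data$ez)) %>%
    tidyr::pivot_longer(c("e_pred_capped", "e_exp_capped"),
                        names_to = "source", values_to = "e_value") %>%
    mutate(source = ifelse(.data$source == "e_pred_capped",
                           "predicted", "experimental"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pair, y = .data$e_value,
                                    fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("E-value (capped at %g)",
                                        attr(object, "e_cap")),
                  fill = NULL)
}

#' @rdname oxdock-tidiers
#' @method autoplot oxd_match_report
#' @export
autoplot.oxd_match_report <- function(object, ...) {
  dat <- tidy(object) %>%
    mutate(rel_deviation = .data$deviation / .data$tolerance)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$descriptor,
                                    y = .data$rel_deviation,
                                    fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|deviation| / tolerance", fill = "pass")
}
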