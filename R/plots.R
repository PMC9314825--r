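#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_vline geom_hline labs facet_wrap theme_bw
NULL

#' Plot an A/Ci curve fit
#'
#' Observations, the fitted nonrectangular hyperbola, and the CO2
#' compensation point (dashed vertical line).
#'
#' @param object a `hyperbola_fit` from [fit_aci()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.hyperbola_fit <- function(object, ...) {
  grid <- tibble::tibble(ci = seq(0, max(object$data$ci), length.out = 200))
  grid$a_net <- predict(object, grid)
  ggplot(object$data, aes(x = .data$ci, y = .data$a_net)) +
    geom_line(data = grid, colour = "steelblue") +
    geom_point() +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_vline(xintercept = object$ccp, linetype = 2, colour = "grey40") +
    labs(x = expression(italic(C)[i] ~ (mu * mol ~ mol^-1)),
         y = expression(italic(A) ~ (mu * mol ~ m^-2 ~ s^-1)),
         title = ifelse(is.na(object$individual_id), "A/Ci fit", object$individual_id),
         subtitle = sprintf("CE = %.3g, CCP = %.3g", object$coef[["ce"]], object$ccp)) +
    theme_bw()
}

#' Plot a paternity assignment report
#'
#' Singleton match fractions per candidate pollen parent, with the number
#' of tested singletons annotated.
#'
#' @param object an `assignment_report` from [assign_pollen_parent()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.assignment_report <- function(object, ...) {
  d <- object$candidates
  ggplot(d, aes(x = stats::reorder(.data$candidate_id, .data$match_fraction),
                y = .data$match_fraction)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_text(aes(label = sprintf("%d/%d", .data$positive_matches,
                                           .data$singletons_tested)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1.15) +
    labs(x = NULL, y = "singleton match fraction",
         title = sprintf("%s: %s", object$hybrid_id, object$verdict)) +
    theme_bw()
}

#' Plot mid-parent additivity results
#'
#' Scaled dominance per trait and hybrid; the dotted lines mark the
#' parental range (-1, +1) and perfect additivity (0).
#'
#' @param additivity output of [midparent_analysis()].
#' @return A ggplot.
#' @export
plot_midparent <- function(additivity) {
  d <- dplyr::filter(tibble::as_tibble(additivity), !is.na(.data$scaled_dominance))
  ggplot(d, aes(x = .data$trait, y = .data$scaled_dominance)) +
    geom_hline(yintercept = 0, linetype = 1, colour = "grey60") +
    geom_hline(yintercept = c(-1, 1), linetype = 3) +
    geom_point(position = ggplot2::position_jitter(width = 0.15, height = 0),
               alpha = 0.7) +
    labs(x = NULL, y = "scaled dominance (0 = additive)") +
    theme_bw()
}
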