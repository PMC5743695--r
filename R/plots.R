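#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot SES values along the elevational gradient
#'
#' Scatter of per-site standardized effect sizes against elevation, one
#' facet per basis, coloured by metric, with OLS fits overlaid — the
#' standard way of eyeballing whether dispersion trends from clustering
#' (SES < 0) toward overdispersion (SES > 0) with altitude.
#'
#' @param ses SES tibble from [ses_dispersion()] / [ses_all_bases()].
#' @param sitetable site tibble with `site` and `elevation`.
#' @return a ggplot object.
#' @export
plot_ses_gradient <- function(ses, sitetable) {
  df <- dplyr::inner_join(dplyr::filter(ses, !.data$undefined_flag),
                          sitetable[c("site", "elevation")], by = "site")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elevation, y = .data$ses,
                                   colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$richness), alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$basis)) +
    ggplot2::labs(x = "Elevation (m)", y = "Standardized effect size",
                  size = "Richness", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of variance-partitioning fractions
#'
#' @param object a `varpart3` object.
#' @param hide_negative drop fractions below zero from the display (the
#'   underlying numbers are never altered).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.varpart3 <- function(object, hide_negative = TRUE, ...) {
  df <- tidy.varpart3(object)
  df <- dplyr::filter(df, .data$fraction != "residual")
  if (hide_negative) df <- dplyr::filter(df, .data$adj_r2 >= 0)
  df$fraction <- factor(df$fraction, levels = rev(unique(df$fraction)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adj_r2, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = object$response, x = "Adjusted R²", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot community-mean traits against elevation with fitted lines
#'
#' Companion display for [ecogeographic_report()]: one panel per trait,
#' points are sites, lines the order- or family-level OLS fits.
#'
#' @param community community list.
#' @param traits trait tibble.
#' @param sitetable site tibble.
#' @param trait trait name.
#' @param transform `"identity"` or `"log10"`.
#' @return a ggplot object.
#' @export
plot_trait_gradient <- function(community, traits, sitetable, trait,
                                transform = "identity") {
  v <- community_mean_trait(community, traits, trait, transform = transform)
  df <- tibble::tibble(site = names(v), value = unname(v))
  df <- dplyr::inner_join(df, sitetable[c("site", "elevation")], by = "site")
  ylab <- if (transform == "log10") paste0("mean log10(", trait, ")") else
    paste0("mean ", trait)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elevation, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "Elevation (m)", y = ylab) +
    ggplot2::theme_minimal()
}
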