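# ggplot2 views of the main result types.

#' Phenotype versus predicted breeding value, with selected tails
#'
#' Scatter of phenotypic scores against GBV for one family and trait, the
#' k individuals with the most favourable and least favourable GBV
#' highlighted.
#'
#' @param gbv,phenotypes Paired numeric vectors.
#' @param k Tail size.
#' @param direction Favourable direction ("high"/"low").
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_selection_tails <- function(gbv, phenotypes, k = 50,
                                 direction = c("high", "low"),
                                 title = NULL) {
  direction <- match.arg(direction)
  sgn <- if (direction == "high") 1 else -1
  n <- length(gbv)
  ord <- order(sgn * gbv, decreasing = TRUE)
  grp <- rep("other", n)
  grp[ord[seq_len(k)]] <- "favourable tail"
  grp[ord[seq(n - k + 1, n)]] <- "unfavourable tail"
  df <- tibble::tibble(gbv = gbv, score = phenotypes, group = grp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gbv, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_jitter(height = 0.12, width = 0, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      "favourable tail" = "forestgreen", "unfavourable tail" = "firebrick",
      other = "steelblue")) +
    ggplot2::labs(x = "predicted GBV", y = "phenotypic score",
                  title = title, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean accuracy against the square root of heritability
#'
#' Per-trait mean accuracies with the no-intercept regression line whose
#' slope is [accuracy_h2_regression()].
#'
#' @param by_trait Tibble with `trait`, `mean_r`.
#' @param varcomp Tibble with `trait`, `h2`.
#' @return A ggplot object.
#' @export
plot_accuracy_h2 <- function(by_trait, varcomp) {
  df <- dplyr::inner_join(by_trait, varcomp, by = "trait") |>
    dplyr::filter(.data$h2 > 0)
  slope <- accuracy_h2_regression(df$mean_r, df$h2)
  ggplot2::ggplot(df, ggplot2::aes(x = sqrt(.data$h2), y = .data$mean_r)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = slope, colour = "steelblue") +
    ggplot2::labs(x = expression(sqrt(h^2)), y = "mean accuracy",
                  subtitle = sprintf("no-intercept slope = %.2f", slope)) +
    ggplot2::theme_minimal()
}

#' LD decay by distance bin
#'
#' @param ld Result of [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(ld) {
  df <- dplyr::filter(ld$bins, !is.na(.data$mean_r2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "distance bin (cM)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_bayescpi Histogram of absolute SNP effects relative to
#'   the phenotypic standard deviation (`y_train` passed via `...` as
#'   `y_train =`), or of raw absolute effects when omitted.
#' @param object A `gs_bayescpi`.
#' @param ... Optionally `y_train` for relative effects.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.gs_bayescpi <- function(object, ...) {
  dots <- list(...)
  if (!is.null(dots$y_train)) {
    df <- relative_effects(object, dots$y_train)
    xlab <- "|effect| / sd(y)"
    v <- df$rel_effect
  } else {
    v <- abs(unname(object$effect))
    xlab <- "|posterior mean effect|"
  }
  ggplot2::ggplot(tibble::tibble(x = v), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue") +
    ggplot2::labs(x = xlab, y = "SNP count",
                  subtitle = sprintf("pi_hat = %.3f", object$pi_hat)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
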