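#' Tidy a clonal-trial fit
#'
#' @param x A `clonal_fit`.
#' @param ... Unused.
#' @return The variance-component tibble: `term`, `variance`, `se`, `pct`,
#'   `boundary` (boundary components have `se = NA`, mirroring the usual
#'   "0 (.)" table convention).
#' @export
#' @method tidy clonal_fit
tidy.clonal_fit <- function(x, ...) {
  x$components
}

#' One-row summary of a clonal-trial fit
#'
#' @param x A `clonal_fit`.
#' @param ... Unused.
#' @return Tibble: `trait`, `n_obs`, `n_clones`, `n_sites`, `sigma2_P`,
#'   `logLik`, `converged`.
#' @export
#' @method glance clonal_fit
glance.clonal_fit <- function(x, ...) {
  tibble(
    trait = x$trait,
    n_obs = x$n_obs,
    n_clones = x$spec$n_clones,
    n_sites = if (x$spec$include_site) length(x$spec$sites) else 1L,
    sigma2_P = sum(x$components$variance),
    logLik = x$loglik,
    converged = x$converged
  )
}

#' Tidy a bivariate fit
#'
#' @param x A `clonal_bifit`.
#' @param ... Unused.
#' @return Tibble with one row per stratum: variances, covariance and
#'   correlation.
#' @export
#' @method tidy clonal_bifit
tidy.clonal_bifit <- function(x, ...) {
  purrr::imap(x$strata, function(S, nm) {
    tibble(stratum = nm, var1 = S[1, 1], covariance = S[1, 2], var2 = S[2, 2])
  }) |>
    list_rbind() |>
    left_join(x$correlations, by = "stratum")
}

#' @export
#' @method glance clonal_bifit
glance.clonal_bifit <- function(x, ...) {
  tibble(trait1 = x$pair[1], trait2 = x$pair[2], n_trees = x$n_trees,
         n_complete = x$n_complete, logLik = x$loglik,
         converged = x$converged)
}

#' Gain curves of a selection-index weight scan
#'
#' Plots the relative genetic gain (%) of both traits against the weight
#' given to the first trait, with the chosen (rounded) weight marked.
#'
#' @param object A [optimize_index_weights()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot selection_index
autoplot.selection_index <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$w1, y = .data$gain_pct,
                               colour = .data$trait)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = object$weights[["w1"]],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = paste0("weight on ", object$traits[1], " (w1)"),
      y = "relative genetic gain (%)",
      colour = NULL,
      title = sprintf("Selection-index weight scan (top %d clones)", object$k),
      subtitle = sprintf("chosen weights %.2f / %.2f", object$weights[1],
                         object$weights[2])
    ) +
    ggplot2::theme_minimal()
}

#' Stability profile plot (ecovalence bars and HMRPGV line)
#'
#' Reproduces the customary stability figure for clonal trials: one bar per
#' clone with its share of the interaction sum of squares (BLUP-ecovalence
#' %), clones contributing significantly to the site-by-clone interaction in
#' a darker shade, overlaid with the (rescaled) HMRPGV profile. Clones are
#' shown in the row order of the tibble, typically selection-index order.
#'
#' @param object A [stability_analysis()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot clonal_stability
autoplot.clonal_stability <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(clone = factor(.data$clone, levels = .data$clone))
  scale_f <- max(d$W_pct) / max(d$HMRPGV)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$clone)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$W_pct, fill = .data$significant)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$HMRPGV * scale_f, group = 1),
                       colour = "black", linetype = "42") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey75", `TRUE` = "grey35"),
                               labels = c(`FALSE` = "stable",
                                          `TRUE` = "significant G×E"),
                               name = NULL) +
    ggplot2::scale_y_continuous(
      name = "BLUP-ecovalence (%)",
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "HMRPGV")
    ) +
    ggplot2::labs(x = NULL,
                  title = paste0("Clone stability",
                                 if (!is.null(attr(object, "trait"))) {
                                   paste0(" — ", attr(object, "trait"))
                                 } else "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
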