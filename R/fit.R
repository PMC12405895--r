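#' Fit the clonal-trial mixed model by REML
#'
#' Fits, for one trait, the linear mixed model
#' `Y = mu + site + block(site) + clone + site:clone + plot + residual`
#' where site and block-within-site are fixed (sum-to-zero coding, so `mu` is
#' the grand expectation) and clone, site-by-clone and plot (block-by-clone
#' within site) are independent random strata. Variance components are
#' estimated by REML through sparse mixed-model equations, with components
#' constrained non-negative; estimates that converge to the boundary are
#' pinned at zero and their standard errors reported as missing. Clone and
#' site-by-clone BLUPs are solved from the mixed-model equations at the REML
#' estimates.
#'
#' The plot stratum is included by default only when some plot carries more
#' than one measured tree for the trait; with single-tree plots the plot
#' effect is confounded with the residual and is dropped (`include_plot =
#' FALSE` forces this, `TRUE` forces inclusion).
#'
#' Rows with a missing response are dropped for the fit (no imputation).
#'
#' @param obs Observation tibble (see [read_observations()] or
#'   [simulate_clone_trial()]).
#' @param trait Name of the response column.
#' @param include_site Fit the multi-site model with site fixed effects and
#'   the site-by-clone stratum. Automatically `FALSE` when only one site is
#'   present; requesting it with a single site is an error.
#' @param include_plot `NULL` (auto-detect), `TRUE` or `FALSE`.
#' @param fix_components Optional named vector
#'   `c(clone=, site_clone=, plot=, residual=)` (terms matching the model) at
#'   which to hold the variance components fixed; only the fixed effects and
#'   BLUPs are then solved. Used for closed-form checks.
#' @param compute_vcov Compute the asymptotic covariance matrix of the
#'   interior variance components (inverse observed information); needed for
#'   Delta-method standard errors. Default `TRUE`.
#' @param control Optimizer control list from `reml_control()`.
#'
#' @return An object of class `clonal_fit`: a list with `components` (tibble:
#'   term, variance, se, pct, boundary), `vcov`, `fixed` (tibble of fixed
#'   solutions), `blup_clone`, `blup_site_clone` (tibbles), `loglik`,
#'   `converged`, `n_obs`, `trait`, `trait_mean`, `site_means`, and the model
#'   description in `spec`. Methods: [tidy()], [glance()], `print()`.
#' @seealso [fit_site_model()], [lrt_variance_component()],
#'   [genetic_parameters()], [adjusted_genotypic_values()]
#' @export
#' @examples
#' obs <- simulate_clone_trial(sim_config(n_clones = 25, n_blocks = 4), seed = 1)
#' fit <- fit_clonal_model(obs, "TH", compute_vcov = FALSE)
#' tidy(fit)
fit_clonal_model <- function(obs, trait, include_site = TRUE,
                             include_plot = NULL, fix_components = NULL,
                             compute_vcov = TRUE, control = reml_control()) {
  if (!trait %in% names(obs)) {
    abort(paste0("no trait column '", trait, "'"), class = "clonegx_schema_error")
  }
  d <- obs[!is.na(obs[[trait]]), , drop = FALSE]
  n_sites <- length(unique(d$site))
  if (include_site && n_sites < 2) {
    if (!missing(include_site)) {
      abort("site and site:clone terms require >= 2 sites",
            class = "clonegx_model_error")
    }
    include_site <- FALSE
  }
  clone_counts <- table(d$clone)
  if (length(clone_counts) < 2) {
    abort("need >= 2 clones with non-missing response",
          class = "clonegx_model_error")
  }
  if (any(clone_counts < 2)) {
    warn(paste0(sum(clone_counts < 2),
                " clone(s) observed fewer than 2 times for trait ", trait))
  }

  y <- d[[trait]]
  X <- fixed_design(d$site, d$block)

  sites <- sort(unique(d$site))
  clones <- sort(unique(d$clone))
  plot_id <- paste(d$site, d$block, d$clone, sep = ".")
  if (is.null(include_plot)) {
    include_plot <- max(table(plot_id)) > 1
  }

  Zlist <- list(clone = indicator_matrix(factor(d$clone, levels = clones)))
  if (include_site) {
    sc_levels <- as.vector(outer(clones, sites,
                                 function(cl, s) paste(s, cl, sep = ":")))
    Zlist$site_clone <- indicator_matrix(
      factor(paste(d$site, d$clone, sep = ":"), levels = sort(sc_levels))
    )
  }
  if (include_plot) {
    Zlist$plot <- indicator_matrix(factor(plot_id))
  }

  if (!is.null(fix_components)) {
    need <- c(names(Zlist), "residual")
    if (!all(need %in% names(fix_components))) {
      abort(paste0("fix_components must name: ", paste(need, collapse = ", ")),
            class = "clonegx_model_error")
    }
    compute_vcov <- FALSE
  }

  core <- reml_core(y, X, Zlist, fix_components = fix_components,
                    control = control, compute_vcov = compute_vcov)

  se <- rep(NA_real_, length(core$vc))
  names(se) <- names(core$vc)
  if (!is.null(core$vcov)) {
    se[colnames(core$vcov)] <- sqrt(pmax(diag(core$vcov), 0))
  }
  comp <- tibble(
    term = names(core$vc),
    variance = unname(core$vc),
    se = unname(se),
    pct = 100 * unname(core$vc) / sum(core$vc),
    boundary = unname(core$boundary)
  )

  blup_clone <- tibble(clone = clones, blup = core$u$clone)
  blup_sc <- NULL
  if (include_site) {
    sc <- colnames(Zlist$site_clone)
    blup_sc <- tibble(
      site = sub(":.*$", "", sc),
      clone = sub("^[^:]*:", "", sc),
      blup = core$u$site_clone
    )
  }
  site_means <- d |>
    group_by(site = .data$site) |>
    summarise(mean = mean(.data[[trait]]), n = n(), .groups = "drop")

  structure(
    list(
      trait = trait,
      spec = list(include_site = include_site, include_plot = include_plot,
                  sites = sites, n_clones = length(clones),
                  fixed_at = fix_components),
      components = comp,
      vcov = core$vcov,
      fixed = tibble(term = colnames(X), estimate = core$beta),
      blup_clone = blup_clone,
      blup_site_clone = blup_sc,
      loglik = core$loglik,
      converged = core$converged,
      n_obs = length(y),
      trait_mean = mean(y),
      site_means = site_means
    ),
    class = "clonal_fit"
  )
}

#' Fit the single-site reduction of the clonal model
#'
#' Restricts the observations to one site and fits
#' `Y = mu + block + clone + plot + residual` (the multi-site model without
#' the site and site-by-clone terms).
#'
#' @inheritParams fit_clonal_model
#' @param site Site label present in `obs$site`.
#' @return A `clonal_fit` for that site.
#' @export
fit_site_model <- function(obs, trait, site, include_plot = NULL,
                           fix_components = NULL, compute_vcov = TRUE,
                           control = reml_control()) {
  if (!site %in% obs$site) {
    abort(paste0("unknown site '", site, "'"), class = "clonegx_model_error")
  }
  fit <- fit_clonal_model(obs[obs$site == site, , drop = FALSE], trait,
                          include_site = FALSE, include_plot = include_plot,
                          fix_components = fix_components,
                          compute_vcov = compute_vcov, control = control)
  fit$spec$site <- site
  fit
}

#' @export
print.clonal_fit <- function(x, ...) {
  cat(sprintf("<clonal_fit> trait %s: %d obs, %d clones, %s\n",
              x$trait, x$n_obs, x$spec$n_clones,
              if (x$spec$include_site) {
                paste0(length(x$spec$sites), " sites")
              } else "single site"))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-11s %12.4g  %s [%4.1f%%]\n", comp$term[i],
                comp$variance[i],
                if (comp$boundary[i]) "(.)"
                else if (is.na(comp$se[i])) "" else sprintf("(%.4g)", comp$se[i]),
                comp$pct[i]))
  }
  cat(sprintf("  restricted logLik %.3f%s\n", x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' One-tailed likelihood-ratio test for a variance component
#'
#' Tests whether a single variance component is greater than zero by
#' comparing the restricted log-likelihoods of nested fits. Because the null
#' value lies on the boundary of the parameter space, the statistic is
#' referred to the equal mixture `0.5 chi2_0 + 0.5 chi2_1`, i.e.
#' `p = 0.5 P(chi2_1 >= LR)` (and `p = 0.5` when `LR = 0`).
#'
#' @param full,reduced `clonal_fit` objects on the same observations, the
#'   reduced model lacking exactly one random term of the full model.
#' @param alpha Significance threshold recorded in the output. Default 0.05.
#' @return One-row tibble: `term_dropped`, `statistic`, `p_value`,
#'   `significant`.
#' @export
lrt_variance_component <- function(full, reduced, alpha = 0.05) {
  stopifnot(inherits(full, "clonal_fit"), inherits(reduced, "clonal_fit"))
  terms_f <- full$components$term
  terms_r <- reduced$components$term
  dropped <- setdiff(terms_f, terms_r)
  if (length(dropped) != 1 || !all(terms_r %in% terms_f)) {
    abort("`reduced` must nest in `full` by removing exactly one random term",
          class = "clonegx_model_error")
  }
  if (full$n_obs != reduced$n_obs || full$trait != reduced$trait) {
    abort("fits must be on the same observations and trait",
          class = "clonegx_model_error")
  }
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- boundary_lrt_pvalue(lr)
  tibble(term_dropped = dropped, statistic = lr, p_value = p,
         significant = p < alpha)
}

#' Boundary-mixture p-value for a one-tailed variance-component LRT
#'
#' @param statistic Likelihood-ratio statistic(s), floored at zero.
#' @return `0.5 * P(chi2_1 >= statistic)`; 0.5 at zero.
#' @export
#' @examples
#' boundary_lrt_pvalue(qchisq(0.125, 1, lower.tail = FALSE)) # 0.0625
boundary_lrt_pvalue <- function(statistic) {
  0.5 * pchisq(pmax(statistic, 0), df = 1, lower.tail = FALSE)
}
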