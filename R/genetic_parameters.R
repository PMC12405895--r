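#' Variance-component set from explicit values
#'
#' Wraps a named vector of variance components (and optionally their
#' asymptotic covariance matrix) in the same shape as the `components` slot of
#' a [fit_clonal_model()] fit, so that derived genetic parameters can be
#' computed both from fresh fits and from published component tables.
#'
#' @param clone,site_clone,plot,residual Variance components (squared trait
#'   units); `plot` and `site_clone` may be `NA` to mark terms absent from the
#'   model (e.g. single-tree plots), which is different from an estimated 0.
#' @param vcov Optional covariance matrix of the estimates with dimnames among
#'   `c("clone", "site_clone", "plot", "residual")`.
#' @return A `clonal_components` object.
#' @export
#' @examples
#' variance_components(clone = 813.8, site_clone = 246.1,
#'                     plot = 962.6, residual = 4317.4)
variance_components <- function(clone, site_clone = NA, plot = NA, residual,
                                vcov = NULL) {
  v <- c(clone = clone, site_clone = site_clone, plot = plot,
         residual = residual)
  present <- !is.na(v)
  if (any(v[present] < 0)) {
    abort("variance components must be >= 0", class = "clonegx_domain_error")
  }
  structure(list(vc = v[present], vcov = vcov,
                 boundary = setNames(v[present] == 0, names(v[present]))),
            class = "clonal_components")
}

as_components <- function(x) {
  if (inherits(x, "clonal_components")) return(x)
  if (inherits(x, "clonal_fit")) {
    comp <- x$components
    return(structure(
      list(vc = setNames(comp$variance, comp$term), vcov = x$vcov,
           boundary = setNames(comp$boundary, comp$term)),
      class = "clonal_components"
    ))
  }
  abort("expected a clonal_fit or clonal_components object",
        class = "clonegx_domain_error")
}

# Delta-method SE of g(v) given gradient and component vcov; boundary
# components are held at 0 (no uncertainty contribution), mirroring the
# "0 (.)" reporting convention for boundary estimates.
delta_se <- function(grad, comp) {
  if (is.null(comp$vcov)) return(NA_real_)
  keep <- intersect(names(grad)[!comp$boundary[names(grad)]],
                    colnames(comp$vcov))
  if (length(keep) == 0) return(0)
  g <- grad[keep]
  sqrt(max(0, as.numeric(t(g) %*% comp$vcov[keep, keep, drop = FALSE] %*% g)))
}

#' Genotypic coefficient of variation
#'
#' `CVG = 100 * sigma_C / mean`: the clone-level standard deviation expressed
#' as a percentage of the phenotypic trait mean.
#'
#' @param x A `clonal_fit` or [variance_components()] object.
#' @param mean Phenotypic trait mean; defaults to the fit's mean.
#' @return CVG in percent.
#' @export
genotypic_cv <- function(x, mean = NULL) {
  comp <- as_components(x)
  mean <- mean %||% x$trait_mean
  if (is.null(mean) || !is.finite(mean) || mean <= 0) {
    abort("`mean` must be a positive number", class = "clonegx_domain_error")
  }
  100 * sqrt(comp$vc[["clone"]]) / mean
}

#' Clonal repeatability (broad-sense heritability)
#'
#' `H2 = sigma2_C / (sigma2_C + sigma2_SxC + sigma2_plot + sigma2_eps)`, the
#' share of total phenotypic variance attributable to total genetic (clone)
#' effects. Terms absent from the model (e.g. the plot stratum with
#' single-tree plots) are omitted from the denominator. The standard error is
#' obtained by the Delta method from the components' asymptotic covariance,
#' with boundary-zero components treated as constants.
#'
#' @param x A `clonal_fit` or [variance_components()] object.
#' @return One-row tibble: `H2`, `se`.
#' @export
clonal_heritability <- function(x) {
  comp <- as_components(x)
  v <- comp$vc
  tot <- sum(v)
  if (tot <= 0) {
    abort("all variance components are zero", class = "clonegx_domain_error")
  }
  h2 <- v[["clone"]] / tot
  grad <- setNames((tot * (names(v) == "clone") - v[["clone"]]) / tot^2,
                   names(v))
  tibble(H2 = unname(h2), se = delta_se(grad, comp))
}

#' Type-B genotypic correlation
#'
#' `rB = sigma2_C / (sigma2_C + sigma2_SxC)`: the genetic correlation of the
#' same trait expressed in two environments. Values near 1 indicate little
#' genotype-by-environment interaction; the conventional Shelbourne threshold
#' (interaction variance half the clone variance, i.e. `rB = 2/3 ~ 0.67`)
#' marks an interaction strong enough to erode gains from joint selection,
#' and fits at or below it are flagged.
#'
#' @param x A `clonal_fit` or [variance_components()] object (must include the
#'   site-by-clone term).
#' @param threshold Flagging threshold on `rB`. Default 0.67.
#' @return One-row tibble: `rB`, `se`, `below_threshold`.
#' @export
type_b_correlation <- function(x, threshold = 0.67) {
  comp <- as_components(x)
  v <- comp$vc
  if (!"site_clone" %in% names(v)) {
    abort("type-B correlation requires the site_clone component",
          class = "clonegx_domain_error")
  }
  den <- v[["clone"]] + v[["site_clone"]]
  if (den <= 0) {
    abort("clone and site_clone components are both zero",
          class = "clonegx_domain_error")
  }
  rb <- v[["clone"]] / den
  grad <- c(clone = v[["site_clone"]] / den^2,
            site_clone = -v[["clone"]] / den^2)
  tibble(rB = unname(rb), se = delta_se(grad, comp),
         below_threshold = rb <= threshold)
}

#' Interaction-to-clone variance ratio
#'
#' `sigma2_SxC / sigma2_C`, flagged when the interaction variance exceeds
#' half the clone variance (the Shelbourne criterion, equivalent to
#' `rB <= ~0.67`).
#'
#' @param x A `clonal_fit` or [variance_components()] object.
#' @return One-row tibble: `ratio` (NA when `sigma2_C` is 0), `flag`.
#' @export
interaction_ratio <- function(x) {
  comp <- as_components(x)
  v <- comp$vc
  if (!"site_clone" %in% names(v)) {
    abort("interaction ratio requires the site_clone component",
          class = "clonegx_domain_error")
  }
  if (v[["clone"]] <= 0) {
    return(tibble(ratio = NA_real_, flag = NA))
  }
  r <- v[["site_clone"]] / v[["clone"]]
  tibble(ratio = unname(r), flag = r > 0.5)
}

#' Percentage of total phenotypic variance per component
#'
#' @param x A `clonal_fit` or [variance_components()] object.
#' @return Tibble: `term`, `variance`, `pct` (summing to 100).
#' @export
variance_percentages <- function(x) {
  comp <- as_components(x)
  tot <- sum(comp$vc)
  if (tot <= 0) {
    abort("total variance is zero", class = "clonegx_domain_error")
  }
  tibble(term = names(comp$vc), variance = unname(comp$vc),
         pct = 100 * unname(comp$vc) / tot)
}

#' All derived genetic parameters of a univariate fit
#'
#' Convenience wrapper returning CVG, clonal repeatability, type-B
#' correlation and the interaction ratio (when the site-by-clone term is in
#' the model) plus the total phenotypic variance, as one tidy row.
#'
#' @param x A `clonal_fit` (or [variance_components()] plus explicit `mean`).
#' @param mean Phenotypic trait mean for CVG.
#' @return One-row tibble.
#' @export
#' @examples
#' vc <- variance_components(clone = 1159.3, site_clone = 176.5,
#'                           plot = 1232.7, residual = 3439.9)
#' genetic_parameters(vc, mean = 532)
genetic_parameters <- function(x, mean = NULL) {
  comp <- as_components(x)
  h <- clonal_heritability(comp)
  m <- mean %||% x$trait_mean
  out <- tibble(
    sigma2_P = sum(comp$vc),
    CVG = if (is.null(m)) NA_real_ else genotypic_cv(comp, mean = m),
    H2 = h$H2, H2_se = h$se
  )
  if ("site_clone" %in% names(comp$vc)) {
    rb <- type_b_correlation(comp)
    ir <- interaction_ratio(comp)
    out$rB <- rb$rB
    out$rB_se <- rb$se
    out$interaction_ratio <- ir$ratio
  }
  out
}

#' Type-A genotypic correlation between two traits
#'
#' `rA = sigma_C(Y1, Y2) / sqrt(sigma2_C(Y1) sigma2_C(Y2))` from a bivariate
#' fit's clone stratum, with a Delta-method standard error. Estimates outside
#' `[-1, 1]` (possible with near-singular strata) are clamped and flagged.
#'
#' @param bifit A [fit_bivariate_model()] object.
#' @return One-row tibble: `rA`, `se`, `clamped`.
#' @export
genotypic_correlation_A <- function(bifit) {
  stopifnot(inherits(bifit, "clonal_bifit"))
  S <- bifit$strata$clone
  v1 <- S[1, 1]; v2 <- S[2, 2]; cv <- S[1, 2]
  if (v1 <= 0 || v2 <= 0) {
    abort("zero clone variance for one of the traits",
          class = "clonegx_domain_error")
  }
  r <- cv / sqrt(v1 * v2)
  clamped <- abs(r) > 1
  se <- NA_real_
  if (!is.null(bifit$vcov)) {
    g <- c(clone.v1 = -cv / (2 * v1^1.5 * sqrt(v2)),
           clone.cov = 1 / sqrt(v1 * v2),
           clone.v2 = -cv / (2 * v2^1.5 * sqrt(v1)))
    keep <- intersect(names(g), colnames(bifit$vcov))
    se <- sqrt(max(0, as.numeric(
      t(g[keep]) %*% bifit$vcov[keep, keep, drop = FALSE] %*% g[keep]
    )))
  }
  tibble(rA = min(max(r, -1), 1), se = se, clamped = clamped)
}

#' Phenotypic correlation between two traits
#'
#' Three-stratum phenotypic correlation from a bivariate fit:
#' the clone, site-by-clone and residual covariances summed, over the product
#' of the correspondingly summed variances. The plot stratum is absent by
#' construction of the bivariate model.
#'
#' @param bifit A [fit_bivariate_model()] object.
#' @return One-row tibble: `rP`, `se`.
#' @export
phenotypic_correlation <- function(bifit) {
  stopifnot(inherits(bifit, "clonal_bifit"))
  sts <- names(bifit$strata)
  v1 <- sum(vapply(bifit$strata, function(S) S[1, 1], numeric(1)))
  v2 <- sum(vapply(bifit$strata, function(S) S[2, 2], numeric(1)))
  cv <- sum(vapply(bifit$strata, function(S) S[1, 2], numeric(1)))
  if (v1 <= 0 || v2 <= 0) {
    abort("zero total variance for one of the traits",
          class = "clonegx_domain_error")
  }
  r <- cv / sqrt(v1 * v2)
  se <- NA_real_
  if (!is.null(bifit$vcov)) {
    g <- setNames(numeric(3 * length(sts)), colnames(bifit$vcov))
    for (s in sts) {
      g[paste0(s, ".v1")] <- -cv / (2 * v1^1.5 * sqrt(v2))
      g[paste0(s, ".cov")] <- 1 / sqrt(v1 * v2)
      g[paste0(s, ".v2")] <- -cv / (2 * v2^1.5 * sqrt(v1))
    }
    se <- sqrt(max(0, as.numeric(t(g) %*% bifit$vcov %*% g)))
  }
  tibble(rP = min(max(r, -1), 1), se = se)
}
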