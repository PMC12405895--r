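#' Per-site adjusted genotypic values from a multi-site fit
#'
#' Builds the clones-by-sites matrix of adjusted genotypic values used by the
#' BLUP-based stability indexes:
#' `VG_adj[i, j] = site mean j + clone BLUP i + site-by-clone BLUP ij`,
#' all taken from the single multi-site fit (not site-specific refits). The
#' site mean is the phenotypic site mean on the trait scale, so every clone
#' has a value at every site by construction even when some site-by-clone
#' cells carry no surviving ramets (their interaction BLUP is 0).
#'
#' @param fit A multi-site `clonal_fit` (site-by-clone term present).
#' @return A `site_value_matrix`: numeric matrix (clones x sites) with
#'   attributes `site_means` (phenotypic), `trait`.
#' @export
per_site_adjusted_vg <- function(fit) {
  stopifnot(inherits(fit, "clonal_fit"))
  if (!fit$spec$include_site || is.null(fit$blup_site_clone)) {
    abort("per-site genotypic values require a multi-site fit with the site_clone term",
          class = "clonegx_model_error")
  }
  clones <- fit$blup_clone$clone
  sites <- fit$spec$sites
  sm <- setNames(fit$site_means$mean, fit$site_means$site)[sites]
  M <- matrix(NA_real_, length(clones), length(sites),
              dimnames = list(clones, sites))
  sc <- fit$blup_site_clone
  for (j in seq_along(sites)) {
    scj <- sc$blup[sc$site == sites[j]][match(clones,
                                              sc$clone[sc$site == sites[j]])]
    M[, j] <- sm[j] + fit$blup_clone$blup + scj
  }
  structure(M, site_means = sm, trait = fit$trait,
            class = c("site_value_matrix", "matrix", "array"))
}

#' Harmonic mean of relative performance of genotypic values (HMRPGV)
#'
#' For each clone, the harmonic mean over sites of its adjusted genotypic
#' value relative to the site mean:
#' `HMRPGV_i = E / sum_j 1 / (VG_adj[i,j] / Ybar_j)`. High values combine
#' high mean performance with stability across sites (the harmonic mean
#' penalizes site-to-site dips more than the arithmetic mean).
#'
#' @param matrix A [per_site_adjusted_vg()] matrix (or any positive
#'   clones-by-sites matrix).
#' @param site_mean How the site reference mean `Ybar_j` is computed:
#'   `"vg"` (default) the mean of the adjusted genotypic values of all clones
#'   at the site; `"phenotypic"` the phenotypic site mean stored on the
#'   matrix. The two coincide on balanced data.
#' @return Tibble: `clone`, `HMRPGV`, `rank` (descending, ties by clone id).
#' @export
hmrpgv <- function(matrix, site_mean = c("vg", "phenotypic")) {
  site_mean <- match.arg(site_mean)
  M <- unclass(matrix)
  ybar <- switch(site_mean,
                 vg = colMeans(M),
                 phenotypic = attr(matrix, "site_means"))
  if (is.null(ybar)) {
    abort("no phenotypic site means stored on the matrix",
          class = "clonegx_domain_error")
  }
  rel <- sweep(M, 2, ybar, "/")
  if (any(rel <= 0) || any(ybar <= 0)) {
    bad <- which(rel <= 0, arr.ind = TRUE)
    abort(paste0("nonpositive relative performance (clone ",
                 rownames(M)[bad[1, 1]], ", site ", colnames(M)[bad[1, 2]],
                 "); HMRPGV requires positive-valued traits"),
          class = "clonegx_domain_error")
  }
  h <- ncol(M) / rowSums(1 / rel)
  ord <- order(-h, rownames(M))
  tibble(clone = rownames(M), HMRPGV = unname(h)) |>
    mutate(rank = match(.data$clone, rownames(M)[ord]))
}

#' BLUP-based Wricke ecovalence
#'
#' Each clone's contribution to the site-by-clone interaction sum of squares
#' of the per-site adjusted genotypic values:
#' `W_i = sum_j (VG_adj[i,j] - rowmean_i - colmean_j + grandmean)^2` (the
#' standard double-centered Wricke form), plus its share of the total,
#' `W_pct = 100 * W_i / sum(W)`. Low values mark stable clones whose site
#' profile is parallel to the site means.
#'
#' A variant replacing `+ grandmean` with `- grandmean` is available for
#' comparison with reports that print the formula that way; it does not
#' vanish for perfectly stable clones and is not the default.
#'
#' @param matrix A [per_site_adjusted_vg()] matrix.
#' @param site_mean Site reference mean convention, as in [hmrpgv()].
#' @param centering `"double"` (default, standard Wricke) or
#'   `"printed_sign"` (the `- grandmean` variant).
#' @return Tibble: `clone`, `W_raw`, `W_pct`. If all interactions are zero,
#'   `W_pct` is 0 with attribute `"degenerate" = TRUE`.
#' @export
blup_ecovalence <- function(matrix, site_mean = c("vg", "phenotypic"),
                            centering = c("double", "printed_sign")) {
  site_mean <- match.arg(site_mean)
  centering <- match.arg(centering)
  M <- unclass(matrix)
  if (nrow(M) < 2 || ncol(M) < 2) {
    abort("ecovalence requires >= 2 clones and >= 2 sites",
          class = "clonegx_domain_error")
  }
  colm <- switch(site_mean, vg = colMeans(M),
                 phenotypic = attr(matrix, "site_means"))
  rowm <- rowMeans(M)
  grand <- mean(colm)
  D <- M - outer(rowm, rep(1, ncol(M))) -
    outer(rep(1, nrow(M)), colm) +
    (if (centering == "double") grand else -grand)
  W <- rowSums(D^2)
  tot <- sum(W)
  out <- tibble(clone = rownames(M), W_raw = unname(W))
  if (tot <= .Machine$double.eps * nrow(M)) {
    out$W_pct <- 0
    attr(out, "degenerate") <- TRUE
  } else {
    out$W_pct <- 100 * out$W_raw / tot
    attr(out, "degenerate") <- FALSE
  }
  out
}

#' Shukla stability variance and significance from ecovalence
#'
#' Converts per-clone ecovalences to Shukla stability variances by the linear
#' transform
#' `sigma2_i = (n (n - 1) W_i - sum(W)) / ((n - 1) (n - 2) (E - 1))`
#' (`n` clones, `E` environments) and tests each clone's contribution to the
#' interaction with a one-sided approximate F ratio against the pooled
#' interaction mean square `sum(W) / ((n - 1) (E - 1))`, on
#' `(E - 1, (n - 2)(E - 1))` degrees of freedom.
#'
#' With only 2 environments the numerator has a single degree of freedom;
#' the test is then fragile and the returned tibble carries attribute
#' `"numerator_df" = 1` so callers can surface it.
#'
#' @param W Numeric vector of raw ecovalences (or the tibble from
#'   [blup_ecovalence()]).
#' @param n_sites Number of environments `E`.
#' @param alpha Significance level for the `significant` flag. Default 0.05.
#' @return Tibble: `clone` (if available), `shukla_var`, `p_value`,
#'   `significant`.
#' @export
shukla_significance <- function(W, n_sites, alpha = 0.05) {
  clone <- NULL
  if (is.data.frame(W)) {
    clone <- W$clone
    W <- W$W_raw
  }
  n <- length(W)
  E <- n_sites
  if (n < 3) {
    abort("the Shukla transform requires >= 3 clones",
          class = "clonegx_domain_error")
  }
  if (E < 2) {
    abort("need >= 2 environments", class = "clonegx_domain_error")
  }
  sv <- (n * (n - 1) * W - sum(W)) / ((n - 1) * (n - 2) * (E - 1))
  pooled <- sum(W) / ((n - 1) * (E - 1))
  df1 <- E - 1
  df2 <- (n - 2) * (E - 1)
  p <- if (pooled <= 0) rep(1, n) else {
    pf(pmax(sv, 0) / pooled, df1, df2, lower.tail = FALSE)
  }
  out <- tibble(shukla_var = sv, p_value = p, significant = p < alpha)
  if (!is.null(clone)) out <- bind_cols(tibble(clone = clone), out)
  attr(out, "numerator_df") <- df1
  out
}

#' Full per-clone stability report for one trait
#'
#' Convenience pipeline: per-site adjusted genotypic values from a multi-site
#' fit, then HMRPGV, BLUP-ecovalence (raw and percent) and Shukla
#' significance, in one tibble. Rows can be ordered by an external ranking
#' (typically the selection index) for reporting.
#'
#' @param fit A multi-site `clonal_fit`.
#' @param order_by Optional tibble with columns `clone` and `rank` (e.g. the
#'   `si` slot of a [optimize_index_weights()] result); rows are sorted by it.
#' @param site_mean Site reference mean convention, see [hmrpgv()].
#' @param alpha Significance level. Default 0.05.
#' @return A `clonal_stability` tibble: `clone`, `HMRPGV`, `HMRPGV_rank`,
#'   `W_raw`, `W_pct`, `shukla_var`, `p_value`, `significant`, plus
#'   `order_rank` when `order_by` is given.
#' @export
stability_analysis <- function(fit, order_by = NULL,
                               site_mean = c("vg", "phenotypic"),
                               alpha = 0.05) {
  site_mean <- match.arg(site_mean)
  M <- per_site_adjusted_vg(fit)
  h <- hmrpgv(M, site_mean = site_mean) |>
    rename(HMRPGV_rank = "rank")
  w <- blup_ecovalence(M, site_mean = site_mean)
  s <- shukla_significance(w, n_sites = ncol(M), alpha = alpha)
  out <- h |>
    left_join(w, by = "clone") |>
    left_join(s, by = "clone")
  if (!is.null(order_by)) {
    out <- out |>
      left_join(select(order_by, "clone", order_rank = "rank"), by = "clone") |>
      arrange(.data$order_rank)
  }
  attr(out, "trait") <- attr(M, "trait")
  attr(out, "n_sites") <- ncol(M)
  attr(out, "numerator_df") <- attr(s, "numerator_df")
  class(out) <- c("clonal_stability", class(out))
  out
}
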