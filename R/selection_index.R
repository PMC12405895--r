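#' Adjusted genotypic values and clone ranking
#'
#' Extracts the per-clone BLUPs (genotypic values, `VG`, deviations from the
#' population mean) from a fit, adds the phenotypic trait mean to put them on
#' the observation scale (`VG_adj`), and ranks clones by `VG_adj` (descending;
#' ties broken by clone identifier for determinism). The interclonal
#' coefficient of variation `CV_VG_adj = 100 * sd(VG_adj) / mean(VG_adj)`
#' (sample SD across clones) is attached as attribute `"cv_vg_adj"` and also
#' returned by [glance()].
#'
#' @param fit A `clonal_fit`.
#' @param mean Trait mean added to the BLUP deviations; defaults to the fit's
#'   phenotypic mean.
#' @return A `genotypic_values` tibble: `clone`, `VG`, `VG_adj`, `rank`.
#' @seealso [standardize_vg()], [optimize_index_weights()]
#' @export
adjusted_genotypic_values <- function(fit, mean = NULL) {
  stopifnot(inherits(fit, "clonal_fit"))
  if (!fit$converged) {
    abort("fit did not converge", class = "clonegx_model_error")
  }
  mean <- mean %||% fit$trait_mean
  tab <- fit$blup_clone |>
    rename(VG = "blup") |>
    mutate(VG_adj = .data$VG + mean) |>
    arrange(desc(.data$VG_adj), .data$clone) |>
    mutate(rank = row_number()) |>
    arrange(.data$clone)
  cv <- 100 * sd(tab$VG_adj) / base::mean(tab$VG_adj)
  attr(tab, "cv_vg_adj") <- cv
  attr(tab, "trait") <- fit$trait
  attr(tab, "trait_mean") <- mean
  class(tab) <- c("genotypic_values", class(tab))
  tab
}

#' Standardize genotypic values across clones
#'
#' Centers and scales the `VG` column to mean 0 and (sample) SD 1, adding a
#' `VG_std` column. Idempotent on already-standardized values and invariant
#' to rescaling of the trait.
#'
#' @param table A tibble with columns `clone` and `VG` (e.g. from
#'   [adjusted_genotypic_values()]).
#' @return The table with an added `VG_std` column.
#' @export
standardize_vg <- function(table) {
  s <- sd(table$VG)
  if (!is.finite(s) || s == 0) {
    abort("genotypic values have zero spread; cannot standardize",
          class = "clonegx_domain_error")
  }
  mutate(table, VG_std = (.data$VG - base::mean(.data$VG)) / s)
}

top_k_clones <- function(score, clone, k) {
  ord <- order(-score, clone)
  clone[ord][seq_len(k)]
}

#' Two-trait selection index with weight optimization
#'
#' Builds the selection index `SI = w1 * VG1_std + w2 * VG2_std`
#' (`w1 + w2 = 1`) over a grid of weights, reselecting the top `k` clones at
#' every grid point. For each trait the relative genetic gain at `w1` is the
#' expected gain of the selected group for that trait as a percentage of the
#' maximum gain achievable by single-trait selection (so the curve for trait
#' 1 is 100% at `w1 = 1`). The optimal weight is the crossing point of the
#' two gain curves, located by linear interpolation on the grid and then
#' rounded to the nearest `round_to` (5% by default).
#'
#' If the curves do not cross inside (0, 1), the boundary weight closer to
#' equality of gains is returned with a warning. When the two curves coincide
#' everywhere (e.g. duplicated traits), weights 0.5/0.5 are returned by the
#' tie rule.
#'
#' @param vg1,vg2 `genotypic_values` tables for the two traits (same clones).
#' @param k Number of clones selected. Default 10.
#' @param grid_step Weight grid resolution for curve evaluation. Default 0.01.
#' @param round_to Final rounding of the crossing weight. Default 0.05.
#' @return An object of class `selection_index`: list with `weights`
#'   (`w1`, `w2`), `crossing_raw`, `si` (tibble `clone`, `SI`, `rank`),
#'   `top_k`, `curves` (tibble `w1`, `trait`, `gain_pct`), `k`, `traits`.
#' @export
optimize_index_weights <- function(vg1, vg2, k = 10, grid_step = 0.01,
                                   round_to = 0.05) {
  if (!setequal(vg1$clone, vg2$clone)) {
    abort("the two tables must cover the same clone set",
          class = "clonegx_domain_error")
  }
  n <- nrow(vg1)
  if (k >= n) {
    abort("k must be smaller than the number of clones",
          class = "clonegx_domain_error")
  }
  t1 <- attr(vg1, "trait") %||% "trait1"
  t2 <- attr(vg2, "trait") %||% "trait2"
  vg2 <- vg2[match(vg1$clone, vg2$clone), ]
  s1 <- standardize_vg(vg1)$VG_std
  s2 <- standardize_vg(vg2)$VG_std
  clone <- vg1$clone

  best1 <- top_k_clones(vg1$VG, clone, k)
  best2 <- top_k_clones(vg2$VG, clone, k)
  max_gain1 <- mean(vg1$VG[clone %in% best1])
  max_gain2 <- mean(vg2$VG[clone %in% best2])

  grid <- seq(0, 1, by = grid_step)
  gains <- purrr::map(grid, function(w1) {
    sel <- top_k_clones(w1 * s1 + (1 - w1) * s2, clone, k)
    c(g1 = 100 * mean(vg1$VG[clone %in% sel]) / max_gain1,
      g2 = 100 * mean(vg2$VG[clone %in% sel]) / max_gain2)
  })
  g1 <- vapply(gains, `[[`, numeric(1), "g1")
  g2 <- vapply(gains, `[[`, numeric(1), "g2")
  dif <- g1 - g2

  if (all(abs(dif) < 1e-9)) {
    w_raw <- 0.5
  } else if (all(dif >= 0) || all(dif <= 0)) {
    warn("gain curves do not cross inside (0, 1); returning boundary weight")
    w_raw <- grid[which.min(abs(dif))]
  } else {
    # reselection at every grid point makes the curves piecewise constant, so
    # sampling noise can produce several sign changes; the crossing is taken
    # as the mean of all interpolated zero crossings, which reduces to the
    # unique crossing for monotone curves and respects swap symmetry
    cand <- which(dif[-1] * dif[-length(dif)] <= 0)
    wcross <- vapply(cand, function(ix) {
      d0 <- dif[ix]; d1 <- dif[ix + 1]
      if (d1 == d0) grid[ix] else grid[ix] + grid_step * d0 / (d0 - d1)
    }, numeric(1))
    w_raw <- mean(wcross)
  }
  w1 <- round(w_raw / round_to) * round_to
  w2 <- 1 - w1

  si_score <- w1 * s1 + w2 * s2
  ord <- order(-si_score, clone)
  si <- tibble(clone = clone, SI = si_score)[ord, ] |>
    mutate(rank = row_number())
  top <- si$clone[seq_len(k)]

  structure(
    list(
      weights = c(w1 = w1, w2 = w2),
      crossing_raw = w_raw,
      si = arrange(si, .data$clone),
      top_k = top,
      curves = tibble(w1 = rep(grid, 2),
                      trait = rep(c(t1, t2), each = length(grid)),
                      gain_pct = c(g1, g2)),
      k = k,
      traits = c(t1, t2)
    ),
    class = "selection_index"
  )
}

#' @export
print.selection_index <- function(x, ...) {
  cat(sprintf("<selection_index> %s / %s: w = %.2f / %.2f (crossing %.3f), top %d clones\n",
              x$traits[1], x$traits[2], x$weights[1], x$weights[2],
              x$crossing_raw, x$k))
  cat("  ", paste(x$top_k, collapse = ", "), "\n")
  invisible(x)
}

#' Selection differentials of a selected clone group
#'
#' For each trait, the mean genotypic value (BLUP deviation) of the selected
#' clones expressed as a percentage of the trait's overall mean:
#' `S = 100 * mean(VG[selected]) / trait mean`. Applied to the combined-sites
#' genotypic values and, when per-site tables are supplied, to each site's
#' values separately.
#'
#' @param selected Character vector of selected clone ids (e.g. `top_k` of a
#'   [optimize_index_weights()] result).
#' @param vg_tables Named list of `genotypic_values` tables, one per trait
#'   (any traits, not only the index traits).
#' @param means Optional named numeric vector of trait means; defaults to
#'   each table's `"trait_mean"` attribute.
#' @return Tibble: `trait`, `S_pct`.
#' @export
selection_differentials <- function(selected, vg_tables, means = NULL) {
  if (is.null(names(vg_tables)) || any(names(vg_tables) == "")) {
    abort("vg_tables must be a named list (one element per trait)",
          class = "clonegx_domain_error")
  }
  purrr::imap(vg_tables, function(tab, trait) {
    if (!all(selected %in% tab$clone)) {
      abort(paste0("selected clones missing from table '", trait, "'"),
            class = "clonegx_domain_error")
    }
    m <- if (!is.null(means) && trait %in% names(means)) {
      means[[trait]]
    } else {
      attr(tab, "trait_mean")
    }
    if (is.null(m)) {
      abort(paste0("no mean available for trait '", trait, "'"),
            class = "clonegx_domain_error")
    }
    tibble(trait = trait,
           S_pct = 100 * mean(tab$VG[tab$clone %in% selected]) / m)
  }) |>
    list_rbind()
}

#' Agreement between two clone rankings
#'
#' Spearman rank correlation between two sets of per-clone values and the
#' top-`k` coincidence percentage (share of clones common to both top-`k`
#' sets). Used for site-versus-site ranking stability and for comparing
#' selection criteria (e.g. selection index versus HMRPGV).
#'
#' @param vg_a,vg_b Tibbles with `clone` and a value column (`VG` or the
#'   column named by `value`).
#' @param k Top-group size for the coincidence measure. Default 10.
#' @param value Name of the value column. Default `"VG"`.
#' @return One-row tibble: `spearman`, `coincidence_pct`, `n_common`.
#' @export
rank_agreement <- function(vg_a, vg_b, k = 10, value = "VG") {
  common <- intersect(vg_a$clone, vg_b$clone)
  if (length(common) == 0) {
    abort("clone sets are disjoint", class = "clonegx_domain_error")
  }
  a <- vg_a[[value]][match(common, vg_a$clone)]
  b <- vg_b[[value]][match(common, vg_b$clone)]
  top_a <- top_k_clones(a, common, min(k, length(common)))
  top_b <- top_k_clones(b, common, min(k, length(common)))
  tibble(
    spearman = suppressWarnings(cor(a, b, method = "spearman")),
    coincidence_pct = 100 * length(intersect(top_a, top_b)) / min(k, length(common)),
    n_common = length(common)
  )
}
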