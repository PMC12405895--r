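#' Configuration for a simulated clonal trial
#'
#' Builds a validated configuration object describing a multi-site clonal
#' trial: a randomized complete block design at each site with fixed-size
#' plots, every clone present in every block of every site before mortality.
#'
#' The default configuration mirrors a boreal-spruce clone-trial series: 2
#' sites, 10 complete blocks, 2-tree plots, 100 clones from 55 families, with
#' total height (`TH`, cm), Pilodyn penetration (`Dpil`, mm) and acoustic
#' velocity (`Vdir`, km/s) whose variance strata are set to REML estimates
#' typical of such trials. Wood traits are carried by a single ramet per plot
#' (`wood_subsample = TRUE`) and the dynamic MoE is derived per tree from
#' `Dpil` and `Vdir`.
#'
#' Each trait is a list with elements `mean` (grand mean, trait units) and
#' `vc`, a named vector of variance components
#' `c(clone=, site_clone=, plot=, residual=)` (squared trait units; `plot` may
#' be 0). Fixed site shifts default to evenly spread multiples of
#' `site_shift_frac * mean`; fixed block effects are drawn once per
#' (site, block) from `N(0, (block_frac * mean)^2)` as part of the seeded
#' stream.
#'
#' @param n_clones Number of clones (>= 2). Default 100.
#' @param n_families Number of family labels, assigned round-robin; cosmetic
#'   only (family is not a model term). Default 55.
#' @param n_sites,n_blocks,plot_size Design constants. Defaults 2, 10, 2.
#' @param traits Named list of trait specifications (see Details). Defaults
#'   described above.
#' @param site_effects Optional named-by-trait list of length-`n_sites`
#'   numeric vectors of fixed site shifts; default derived from
#'   `site_shift_frac`.
#' @param site_shift_frac,block_frac Fractions of the trait mean used for the
#'   default fixed site shifts and the block-effect SD. Defaults 0.05, 0.02.
#' @param mortality_rate Independent per-ramet death probability in `[0, 1)`.
#'   Default 0.1.
#' @param mortality_clustered If `TRUE`, mortality removes whole plots with
#'   probability `mortality_rate` instead of independent ramets (stress-test
#'   variant emulating clustered drought kill). Default `FALSE`.
#' @param wood_subsample Carry wood traits on exactly one surviving ramet per
#'   plot. Default `TRUE`.
#' @param wood_traits Traits subject to the subsampling rule.
#' @param population Population label stamped on every row.
#'
#' @return An object of class `clonegx_sim_config`.
#' @seealso [simulate_clone_trial()], [simulate_bivariate_trial()]
#' @export
sim_config <- function(n_clones = 100,
                       n_families = 55,
                       n_sites = 2,
                       n_blocks = 10,
                       plot_size = 2,
                       traits = NULL,
                       site_effects = NULL,
                       site_shift_frac = 0.05,
                       block_frac = 0.02,
                       mortality_rate = 0.1,
                       mortality_clustered = FALSE,
                       wood_subsample = TRUE,
                       wood_traits = c("Dpil", "Vdir"),
                       population = "P1") {
  if (is.null(traits)) {
    traits <- list(
      TH = list(mean = 532,
                vc = c(clone = 1159.3, site_clone = 176.5,
                       plot = 1232.7, residual = 3439.9)),
      Dpil = list(mean = 16.1,
                  vc = c(clone = 1.4628, site_clone = 0.1069,
                         plot = 0, residual = 1.5632)),
      Vdir = list(mean = 3.32,
                  vc = c(clone = 0.0637, site_clone = 0.0019,
                         plot = 0, residual = 0.0336))
    )
  }
  stopifnot(n_clones >= 2, n_sites >= 1, n_blocks >= 1, plot_size >= 1,
            n_families >= 1)
  if (mortality_rate < 0 || mortality_rate >= 1) {
    abort("mortality_rate must be in [0, 1)", class = "clonegx_config_error")
  }
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    vc <- tr$vc
    need <- c("clone", "site_clone", "plot", "residual")
    if (!all(need %in% names(vc))) {
      abort(paste0("trait '", tn, "': vc must name ",
                   paste(need, collapse = ", ")),
            class = "clonegx_config_error")
    }
    if (any(vc < 0)) {
      abort(paste0("trait '", tn, "': variance components must be >= 0"),
            class = "clonegx_config_error")
    }
    if (!is.numeric(tr$mean) || tr$mean <= 0) {
      abort(paste0("trait '", tn, "': mean must be positive"),
            class = "clonegx_config_error")
    }
  }
  if (!is.null(site_effects)) {
    ok <- all(vapply(site_effects, length, integer(1)) == n_sites)
    if (!ok) {
      abort("site_effects entries must have length n_sites",
            class = "clonegx_config_error")
    }
  }
  structure(
    list(n_clones = n_clones, n_families = n_families, n_sites = n_sites,
         n_blocks = n_blocks, plot_size = plot_size, traits = traits,
         site_effects = site_effects, site_shift_frac = site_shift_frac,
         block_frac = block_frac, mortality_rate = mortality_rate,
         mortality_clustered = mortality_clustered,
         wood_subsample = wood_subsample, wood_traits = wood_traits,
         population = population),
    class = "clonegx_sim_config"
  )
}

#' @export
print.clonegx_sim_config <- function(x, ...) {
  cat("<clonegx simulation config>\n")
  cat(sprintf("  design : %d site(s) x %d blocks x %d-tree plots, %d clones (%d families)\n",
              x$n_sites, x$n_blocks, x$plot_size, x$n_clones, x$n_families))
  cat(sprintf("  traits : %s\n", paste(names(x$traits), collapse = ", ")))
  cat(sprintf("  mortality %.2f (%s), wood subsample %s [%s]\n",
              x$mortality_rate,
              if (x$mortality_clustered) "by plot" else "independent",
              x$wood_subsample, paste(x$wood_traits, collapse = ", ")))
  invisible(x)
}

sim_labels <- function(prefix, n) {
  if (prefix == "S") return(paste0("S", seq_len(n)))
  sprintf(paste0("%s%0", max(2, nchar(n)), "d"), prefix, seq_len(n))
}

#' Simulate a multi-site clonal trial
#'
#' Draws an observation table under the clonal-trial mixed model
#' `Y = mu + site + block(site) + clone + site:clone + plot + residual`,
#' with the clone, site-by-clone, plot (block-by-clone within site) and
#' within-plot residual strata drawn independently from zero-mean normal
#' distributions with the configured variances. The complete design (every
#' clone in every block of every site) is generated first; mortality then
#' deletes ramets; finally, when wood subsampling is on, wood traits are
#' retained on exactly one surviving ramet per plot.
#'
#' A single pseudo-random stream fully determined by `seed` is used, with
#' stratum draws in a fixed order (block, then per trait: clone, site:clone,
#' plot, residual; then mortality, then subsampling), so equal seeds give
#' byte-identical tables.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @param return_effects If `TRUE`, attach the latent effect draws as
#'   attribute `"effects"` (a list per trait) for calibration checks.
#' @return Observation tibble as from [read_observations()], with derived
#'   `MoE` where both `Dpil` and `Vdir` are present.
#' @export
#' @examples
#' obs <- simulate_clone_trial(sim_config(n_clones = 20, n_blocks = 4), seed = 42)
#' dplyr::count(obs, site)
simulate_clone_trial <- function(config, seed, return_effects = FALSE) {
  stopifnot(inherits(config, "clonegx_sim_config"))
  set.seed(as.integer(seed))
  cf <- config

  sites <- sim_labels("S", cf$n_sites)
  clones <- sim_labels("C", cf$n_clones)
  families <- sim_labels("F", cf$n_families)
  fam_of <- setNames(rep(families, length.out = cf$n_clones), clones)

  design <- tidyr::expand_grid(
    site = sites, block = seq_len(cf$n_blocks), clone = clones,
    ramet = seq_len(cf$plot_size)
  )
  design$population <- cf$population
  design$family <- unname(fam_of[design$clone])
  design$ramet <- paste(design$site, design$block, design$clone, design$ramet,
                        sep = "-")

  # fixed block effects, shared across traits on the relative scale
  block_z <- rnorm(cf$n_sites * cf$n_blocks)
  block_key <- paste(rep(sites, each = cf$n_blocks), seq_len(cf$n_blocks),
                     sep = ".")
  iblock <- match(paste(design$site, design$block, sep = "."), block_key)
  isite <- match(design$site, sites)
  iclone <- match(design$clone, clones)
  isc <- (isite - 1L) * cf$n_clones + iclone
  plot_key <- paste(design$site, design$block, design$clone, sep = ".")
  uplots <- unique(plot_key)
  iplot <- match(plot_key, uplots)

  effects <- list()
  for (tn in names(cf$traits)) {
    tr <- cf$traits[[tn]]
    vc <- tr$vc
    se <- if (!is.null(cf$site_effects[[tn]])) {
      cf$site_effects[[tn]]
    } else if (cf$n_sites == 1) 0 else {
      seq(-1, 1, length.out = cf$n_sites) * cf$site_shift_frac * tr$mean
    }
    be <- block_z * cf$block_frac * tr$mean
    ce <- rnorm(cf$n_clones, 0, sqrt(vc[["clone"]]))
    sce <- rnorm(cf$n_sites * cf$n_clones, 0, sqrt(vc[["site_clone"]]))
    pe <- rnorm(length(uplots), 0, sqrt(vc[["plot"]]))
    ee <- rnorm(nrow(design), 0, sqrt(vc[["residual"]]))
    design[[tn]] <- tr$mean + se[isite] + be[iblock] + ce[iclone] +
      sce[isc] + pe[iplot] + ee
    effects[[tn]] <- list(site = se, block = be, clone = ce,
                          site_clone = matrix(sce, nrow = cf$n_clones,
                                              dimnames = list(clones, sites)),
                          plot = pe)
  }

  # mortality
  if (cf$mortality_rate > 0) {
    if (cf$mortality_clustered) {
      dead_plots <- uplots[rbinom(length(uplots), 1, cf$mortality_rate) == 1]
      keep <- !(plot_key %in% dead_plots)
    } else {
      keep <- rbinom(nrow(design), 1, cf$mortality_rate) == 0
    }
    design <- design[keep, , drop = FALSE]
    iplot <- iplot[keep]
  }

  # wood-trait subsampling: one surviving ramet per plot
  wt <- intersect(cf$wood_traits, names(cf$traits))
  if (cf$wood_subsample && length(wt) > 0 && cf$plot_size > 1) {
    pick <- rep(FALSE, nrow(design))
    split_idx <- split(seq_len(nrow(design)), iplot)
    chosen <- vapply(split_idx, function(ix) ix[sample.int(length(ix), 1)],
                     integer(1))
    pick[chosen] <- TRUE
    for (tn in wt) design[[tn]][!pick] <- NA_real_
  }

  obs <- as_tibble(design[, c("population", "site", "block", "clone", "family",
                              "ramet", names(cf$traits))])
  if (all(c("Dpil", "Vdir") %in% names(obs))) obs <- add_moe(obs)
  attr(obs, "plot_size") <- cf$plot_size
  if (return_effects) attr(obs, "effects") <- effects
  obs
}

#' Simulate a pair of traits with per-stratum correlations
#'
#' Generates two traits on the same trees with correlated clone, site-by-clone
#' and residual effects drawn from bivariate normal distributions, matching
#' the bivariate model used for between-trait correlation estimation: the plot
#' stratum is absent, and both traits are carried by every surviving ramet
#' (no wood subsampling).
#'
#' Marginal variances come from each trait's configured `clone`, `site_clone`
#' and `residual` components; `plot` is ignored.
#'
#' @param config A [sim_config()] object naming at least the two traits.
#' @param pair Character vector of two trait names. Default
#'   `c("TH", "Vdir")`.
#' @param cor_clone,cor_site_clone,cor_residual Per-stratum correlations in
#'   `[-1, 1]`. Defaults 0.3, 0, 0.1.
#' @param seed Integer seed.
#' @param return_effects Attach latent draws as attribute `"effects"`.
#' @return Observation tibble carrying the two traits.
#' @export
simulate_bivariate_trial <- function(config, pair = c("TH", "Vdir"),
                                     cor_clone = 0.3, cor_site_clone = 0,
                                     cor_residual = 0.1, seed,
                                     return_effects = FALSE) {
  stopifnot(inherits(config, "clonegx_sim_config"), length(pair) == 2)
  if (!all(pair %in% names(config$traits))) {
    abort("both traits of `pair` must be present in the config",
          class = "clonegx_config_error")
  }
  for (r in c(cor_clone, cor_site_clone, cor_residual)) {
    if (abs(r) > 1) abort("stratum correlations must lie in [-1, 1]",
                          class = "clonegx_config_error")
  }
  set.seed(as.integer(seed))
  cf <- config
  sites <- sim_labels("S", cf$n_sites)
  clones <- sim_labels("C", cf$n_clones)
  families <- sim_labels("F", cf$n_families)
  fam_of <- setNames(rep(families, length.out = cf$n_clones), clones)

  design <- tidyr::expand_grid(
    site = sites, block = seq_len(cf$n_blocks), clone = clones,
    ramet = seq_len(cf$plot_size)
  )
  design$population <- cf$population
  design$family <- unname(fam_of[design$clone])
  design$ramet <- paste(design$site, design$block, design$clone, design$ramet,
                        sep = "-")
  block_z <- rnorm(cf$n_sites * cf$n_blocks)
  block_key <- paste(rep(sites, each = cf$n_blocks), seq_len(cf$n_blocks),
                     sep = ".")
  iblock <- match(paste(design$site, design$block, sep = "."), block_key)
  isite <- match(design$site, sites)
  iclone <- match(design$clone, clones)
  isc <- (isite - 1L) * cf$n_clones + iclone

  draw2 <- function(n, v1, v2, r) {
    # bivariate normal via Cholesky of the 2x2 covariance
    s12 <- r * sqrt(v1 * v2)
    z1 <- rnorm(n); z2 <- rnorm(n)
    x1 <- sqrt(v1) * z1
    x2 <- if (v2 == 0) rep(0, n) else {
      s12 / max(sqrt(v1), .Machine$double.eps) * z1 +
        sqrt(max(v2 - if (v1 > 0) s12^2 / v1 else 0, 0)) * z2
    }
    cbind(x1, x2)
  }

  t1 <- cf$traits[[pair[1]]]; t2 <- cf$traits[[pair[2]]]
  ce <- draw2(cf$n_clones, t1$vc[["clone"]], t2$vc[["clone"]], cor_clone)
  sce <- draw2(cf$n_sites * cf$n_clones, t1$vc[["site_clone"]],
               t2$vc[["site_clone"]], cor_site_clone)
  ee <- draw2(nrow(design), t1$vc[["residual"]], t2$vc[["residual"]],
              cor_residual)

  for (j in 1:2) {
    tr <- cf$traits[[pair[j]]]
    se <- if (!is.null(cf$site_effects[[pair[j]]])) {
      cf$site_effects[[pair[j]]]
    } else if (cf$n_sites == 1) 0 else {
      seq(-1, 1, length.out = cf$n_sites) * cf$site_shift_frac * tr$mean
    }
    be <- block_z * cf$block_frac * tr$mean
    design[[pair[j]]] <- tr$mean + se[isite] + be[iblock] + ce[iclone, j] +
      sce[isc, j] + ee[, j]
  }

  if (cf$mortality_rate > 0) {
    keep <- rbinom(nrow(design), 1, cf$mortality_rate) == 0
    design <- design[keep, , drop = FALSE]
    iclone <- iclone[keep]
  }
  obs <- as_tibble(design[, c("population", "site", "block", "clone", "family",
                              "ramet", pair)])
  attr(obs, "plot_size") <- cf$plot_size
  if (return_effects) {
    attr(obs, "effects") <- list(clone = ce, site_clone = sce)
  }
  obs
}
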