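make_balanced <- function(n_clones = 12, n_sites = 2, n_blocks = 4,
                          plot_size = 2, vc = c(clone = 100, site_clone = 50,
                                                plot = 80, residual = 200),
                          mean = 500, seed = 42) {
  cf <- sim_config(
    n_clones = n_clones, n_sites = n_sites, n_blocks = n_blocks,
    plot_size = plot_size, mortality_rate = 0,
    traits = list(TH = list(mean = mean, vc = vc)),
    wood_traits = character(0)
  )
  simulate_clone_trial(cf, seed = seed)
}

test_that("clone BLUPs at fixed components equal the closed-form shrinkage", {
  # one site, one-tree plots, balanced: u_k = (n sC2 / (n sC2 + sE2)) (ybar_k - ybar)
  d <- make_balanced(n_clones = 20, n_sites = 1, n_blocks = 6, plot_size = 1,
                     vc = c(clone = 80, site_clone = 0, plot = 0,
                            residual = 150), seed = 11)
  fit <- fit_clonal_model(d, "TH", include_plot = FALSE,
                          fix_components = c(clone = 80, residual = 150))
  n <- 6
  shrink <- n * 80 / (n * 80 + 150)
  cm <- tapply(d$TH, d$clone, mean)
  expected <- shrink * (cm - mean(cm))
  expect_equal(setNames(fit$blup_clone$blup, fit$blup_clone$clone),
               setNames(as.numeric(expected[fit$blup_clone$clone]),
                        fit$blup_clone$clone),
               tolerance = 1e-8)
})

test_that("identical ramets within clones drive the residual to the boundary", {
  clones <- sprintf("C%02d", 1:10)
  vals <- seq(480, 570, by = 10)
  d <- tidyr::expand_grid(block = 1:4, clone = clones) |>
    dplyr::mutate(population = "P", site = "S1",
                  ramet = paste(block, clone), TH = vals[match(clone, clones)])
  fit <- quiet_fit(d, "TH", include_plot = FALSE, compute_vcov = FALSE)
  vc <- setNames(fit$components$variance, fit$components$term)
  expect_lt(vc[["residual"]], 1e-6 * vc[["clone"]])
  expect_equal(vc[["clone"]], var(vals), tolerance = 0.01)
})

test_that("REML equals the EMS/ANOVA oracle on balanced complete data", {
  d <- make_balanced(seed = 42)
  fit <- fit_clonal_model(d, "TH", compute_vcov = FALSE)
  ems <- ems_components(d, "TH")
  vc <- setNames(fit$components$variance, fit$components$term)
  expect_true(all(ems > 0)) # interior case
  for (term in names(ems)) {
    expect_equal(vc[[term]], ems[[term]], tolerance = 1e-6,
                 label = paste("REML", term))
  }
})

test_that("univariate REML agrees with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  cf <- sim_config(n_clones = 40, n_blocks = 5, mortality_rate = 0.12)
  obs <- simulate_clone_trial(cf, seed = 3)
  d <- obs[!is.na(obs$TH), ]
  fit <- fit_clonal_model(obs, "TH")

  d$plf <- paste(d$site, d$block, d$clone, sep = ".")
  d$sc <- paste(d$site, d$clone, sep = ":")
  X <- clonegx:::fixed_design(d$site, d$block)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- cbind(as.data.frame(d), as.data.frame(X))
  form <- stats::as.formula(paste(
    "TH ~ 0 +", paste(colnames(X), collapse = "+"),
    "+ (1|clone) + (1|sc) + (1|plf)"
  ))
  lf <- lme4::lmer(form, data = dat, REML = TRUE)
  vc_lme4 <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc_lme4$vcov, vc_lme4$grp)
  vc <- setNames(fit$components$variance, fit$components$term)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(vc[["clone"]], ref[["clone"]], tolerance = 1e-4)
  expect_equal(vc[["site_clone"]], ref[["sc"]], tolerance = 1e-3)
  expect_equal(vc[["plot"]], ref[["plf"]], tolerance = 1e-4)
  expect_equal(vc[["residual"]], ref[["Residual"]], tolerance = 1e-4)
})

test_that("location shifts move only the intercept; scaling acts quadratically", {
  d <- make_balanced(n_clones = 10, n_blocks = 3, seed = 7)
  f0 <- fit_clonal_model(d, "TH", compute_vcov = FALSE)
  d2 <- dplyr::mutate(d, TH = TH + 250)
  f_shift <- fit_clonal_model(d2, "TH", compute_vcov = FALSE)
  expect_equal(f_shift$fixed$estimate[1], f0$fixed$estimate[1] + 250,
               tolerance = 1e-6)
  expect_equal(f_shift$components$variance, f0$components$variance,
               tolerance = 1e-5)
  expect_equal(f_shift$blup_clone$blup, f0$blup_clone$blup, tolerance = 1e-4)

  s <- 3.5
  d3 <- dplyr::mutate(d, TH = TH * s)
  f_scale <- fit_clonal_model(d3, "TH", compute_vcov = FALSE)
  expect_equal(f_scale$components$variance, f0$components$variance * s^2,
               tolerance = 1e-5)
  expect_equal(f_scale$blup_clone$blup, f0$blup_clone$blup * s,
               tolerance = 1e-4)
})

test_that("fits are invariant to row order and clone relabeling", {
  d <- make_balanced(n_clones = 10, n_blocks = 3, seed = 19)
  f0 <- fit_clonal_model(d, "TH", compute_vcov = FALSE)
  set.seed(1)
  dperm <- d[sample(nrow(d)), ]
  f1 <- fit_clonal_model(dperm, "TH", compute_vcov = FALSE)
  expect_equal(f1$components$variance, f0$components$variance,
               tolerance = 1e-6)
  expect_equal(f1$blup_clone, f0$blup_clone, tolerance = 1e-5)

  relabel <- setNames(sprintf("Z%02d", 10:1), sort(unique(d$clone)))
  drel <- dplyr::mutate(d, clone = unname(relabel[clone]))
  f2 <- fit_clonal_model(drel, "TH", compute_vcov = FALSE)
  expect_equal(setNames(f2$blup_clone$blup, f2$blup_clone$clone)[
                 unname(relabel[f0$blup_clone$clone])],
               setNames(f0$blup_clone$blup,
                        unname(relabel[f0$blup_clone$clone])),
               tolerance = 1e-5)
})

test_that("clone BLUPs sum to approximately zero", {
  d <- make_balanced(n_clones = 15, n_blocks = 4, seed = 23)
  fit <- fit_clonal_model(d, "TH", compute_vcov = FALSE)
  expect_lt(abs(sum(fit$blup_clone$blup)),
            1e-6 * sd(d$TH) * nrow(fit$blup_clone))
})

test_that("site-specific fits reduce the model and recover per-site truth ordering", {
  # two identical sites stacked: per-site clone BLUPs coincide
  d1 <- make_balanced(n_clones = 12, n_sites = 1, n_blocks = 4, seed = 31)
  d2 <- dplyr::mutate(d1, site = "S2", ramet = paste0(ramet, "b"))
  d <- dplyr::bind_rows(d1, d2)
  fa <- fit_site_model(d, "TH", "S1", compute_vcov = FALSE)
  fb <- fit_site_model(d, "TH", "S2", compute_vcov = FALSE)
  expect_equal(fa$blup_clone$blup, fb$blup_clone$blup, tolerance = 1e-8)
  expect_false(fa$spec$include_site)

  expect_error(fit_site_model(d, "TH", "S9"), class = "clonegx_model_error")
  expect_error(fit_clonal_model(d1, "TH", include_site = TRUE),
               class = "clonegx_model_error")

  # site-specific clone variances: site with 4x the clonal variance yields
  # the larger estimate (checked across independent replicates)
  wins <- 0L
  for (r in 1:5) {
    cf <- sim_config(
      n_clones = 60, n_blocks = 6, plot_size = 1, mortality_rate = 0,
      traits = list(TH = list(mean = 500,
                              vc = c(clone = 200, site_clone = 0, plot = 0,
                                     residual = 400))),
      wood_traits = character(0)
    )
    obs <- simulate_clone_trial(cf, seed = 400 + r, return_effects = TRUE)
    # inflate clone effects at site S1 only: site-specific sigma2_C differs
    ef <- attr(obs, "effects")$TH
    extra <- setNames(ef$clone, sort(unique(obs$clone)))
    obs$TH <- obs$TH + ifelse(obs$site == "S1", extra[obs$clone], 0)
    fs1 <- fit_site_model(obs, "TH", "S1", compute_vcov = FALSE)
    fs2 <- fit_site_model(obs, "TH", "S2", compute_vcov = FALSE)
    v1 <- fs1$components$variance[fs1$components$term == "clone"]
    v2 <- fs2$components$variance[fs2$components$term == "clone"]
    wins <- wins + (v1 > v2)
  }
  expect_gte(wins, 4L)
})

test_that("one-tailed boundary LRT has the prescribed mixture behaviour", {
  expect_equal(boundary_lrt_pvalue(0), 0.5)
  lr <- qchisq(0.125, df = 1, lower.tail = FALSE)
  expect_equal(boundary_lrt_pvalue(lr), 0.0625)

  d <- make_balanced(n_clones = 10, n_blocks = 3, seed = 13)
  full <- fit_clonal_model(d, "TH", compute_vcov = FALSE)
  red <- fit_clonal_model(d, "TH", include_plot = FALSE, compute_vcov = FALSE)
  out <- lrt_variance_component(full, red)
  expect_equal(out$term_dropped, "plot")
  expect_gte(out$statistic, 0)
  expect_equal(out$p_value, boundary_lrt_pvalue(out$statistic))
  expect_error(lrt_variance_component(full, full),
               class = "clonegx_model_error")
})

test_that("LRT type-I error under a null interaction is near the mixture level", {
  reps <- 120
  rej <- logical(reps)
  cf <- sim_config(
    n_clones = 30, n_blocks = 3, plot_size = 1, mortality_rate = 0,
    traits = list(TH = list(mean = 100,
                            vc = c(clone = 0.3, site_clone = 0, plot = 0,
                                   residual = 1))),
    wood_traits = character(0)
  )
  for (r in seq_len(reps)) {
    obs <- simulate_clone_trial(cf, seed = 5000 + r)
    full <- fit_clonal_model(obs, "TH", include_plot = FALSE,
                             compute_vcov = FALSE)
    red_core <- clonegx:::reml_core(
      obs$TH, clonegx:::fixed_design(obs$site, obs$block),
      list(clone = clonegx:::indicator_matrix(factor(obs$clone))),
      compute_vcov = FALSE
    )
    lr <- max(0, 2 * (full$loglik - red_core$loglik))
    rej[r] <- boundary_lrt_pvalue(lr) < 0.05
  }
  rate <- mean(rej)
  tol <- 2 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), tol + 1e-9)
})
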