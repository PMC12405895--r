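mk_fit_like <- function(clones, blups, trait, mean) {
  structure(list(
    trait = trait,
    spec = list(include_site = FALSE, include_plot = FALSE, sites = "S1",
                n_clones = length(clones)),
    blup_clone = tibble::tibble(clone = clones, blup = blups),
    converged = TRUE, trait_mean = mean, n_obs = length(clones)
  ), class = "clonal_fit")
}

test_that("adjusted genotypic values rank clones and report their CV", {
  f <- mk_fit_like(c("C1", "C2", "C3"), c(5, 0, -5), "TH", 100)
  tab <- adjusted_genotypic_values(f)
  expect_equal(tab$VG_adj, c(105, 100, 95))
  expect_equal(tab$rank, c(1, 2, 3))
  expect_equal(attr(tab, "cv_vg_adj"), 100 * sd(c(105, 100, 95)) / 100)
  expect_equal(attr(tab, "cv_vg_adj"), 5) # sample-SD convention

  # all BLUPs zero: everything ties at the mean, ranks by clone id
  f0 <- mk_fit_like(c("C1", "C2", "C3"), c(0, 0, 0), "TH", 100)
  t0 <- adjusted_genotypic_values(f0)
  expect_true(all(t0$VG_adj == 100))
  expect_equal(t0$rank, 1:3)
})

test_that("standardization is exact, idempotent and scale free", {
  tab <- tibble::tibble(clone = c("a", "b", "c"), VG = c(-4, 0, 4))
  s <- standardize_vg(tab)
  expect_equal(s$VG_std, c(-1, 0, 1)) # sample-SD convention
  expect_equal(mean(s$VG_std), 0)
  expect_equal(sd(s$VG_std), 1)
  s2 <- standardize_vg(dplyr::mutate(tab, VG = VG * 10))
  expect_equal(s2$VG_std, s$VG_std)
  s3 <- standardize_vg(dplyr::mutate(s, VG = VG_std))
  expect_equal(s3$VG_std, s$VG_std)
  expect_error(standardize_vg(tibble::tibble(clone = "a", VG = 0)),
               class = "clonegx_domain_error")
})

test_that("boundary weights reproduce single-trait rankings", {
  fx <- fixture_12_clones()
  sel <- suppressWarnings(
    optimize_index_weights(fx$TH, fx$Vdir, k = 3, grid_step = 0.05)
  )
  s1 <- standardize_vg(fx$TH)$VG_std
  s2 <- standardize_vg(fx$Vdir)$VG_std
  # w = (1, 0): pure TH ranking; w = (0, 1): pure Vdir ranking
  si_th <- order(-(1 * s1 + 0 * s2), fx$TH$clone)
  expect_equal(fx$TH$clone[si_th], fx$TH$clone[order(-fx$TH$VG, fx$TH$clone)])
  g_th_at_1 <- sel$curves$gain_pct[sel$curves$trait == "TH"][
    which.max(sel$curves$w1[sel$curves$trait == "TH"])]
  expect_equal(g_th_at_1, 100)
  g_vd_at_0 <- sel$curves$gain_pct[sel$curves$trait == "Vdir"][
    which.min(sel$curves$w1[sel$curves$trait == "Vdir"])]
  expect_equal(g_vd_at_0, 100)
})

test_that("duplicated traits and swap-symmetric pairs give equal weights", {
  fx <- fixture_12_clones()
  dup <- optimize_index_weights(fx$TH, fx$TH, k = 3)
  expect_equal(unname(dup$weights), c(0.5, 0.5))

  # swap-symmetric construction: for every clone (x, y) there is a mirror
  # clone (y, x), so the two gain curves are reflections and cross at 0.5
  set.seed(8)
  x <- rnorm(15); y <- rnorm(15)
  t1 <- tibble::tibble(clone = sprintf("M%02d", 1:30), VG = c(x, y))
  t2 <- tibble::tibble(clone = sprintf("M%02d", 1:30), VG = c(y, x))
  attr(t1, "trait") <- "A"; attr(t1, "trait_mean") <- 10
  attr(t2, "trait") <- "B"; attr(t2, "trait_mean") <- 10
  sym <- optimize_index_weights(t1, t2, k = 10)
  expect_equal(unname(sym$weights), c(0.5, 0.5))
})

test_that("crossing point and top sets match brute-force enumeration", {
  fx <- fixture_12_clones()
  k <- 10
  sel <- optimize_index_weights(fx$TH, fx$Vdir, k = k, grid_step = 0.01)
  s1 <- standardize_vg(fx$TH)$VG_std
  s2 <- standardize_vg(fx$Vdir)$VG_std
  clones <- fx$TH$clone
  best_th <- brute_force_top_k(fx$TH$VG, clones, k)
  best_vd <- brute_force_top_k(fx$Vdir$VG, clones, k)
  max1 <- mean(fx$TH$VG[clones %in% best_th])
  max2 <- mean(fx$Vdir$VG[clones %in% best_vd])
  grid <- seq(0, 1, by = 0.01)
  g1 <- g2 <- numeric(length(grid))
  for (i in seq_along(grid)) {
    w <- grid[i]
    sel_i <- brute_force_top_k(w * s1 + (1 - w) * s2, clones, k)
    g1[i] <- 100 * mean(fx$TH$VG[clones %in% sel_i]) / max1
    g2[i] <- 100 * mean(fx$Vdir$VG[clones %in% sel_i]) / max2
  }
  expect_equal(sel$curves$gain_pct, c(g1, g2), tolerance = 1e-9)
  dif <- g1 - g2
  ix <- which(dif[-1] * dif[-length(dif)] <= 0)[1]
  w_cross <- grid[ix] + 0.01 * dif[ix] / (dif[ix] - dif[ix + 1])
  expect_equal(sel$crossing_raw, w_cross, tolerance = 1e-9)
  expect_equal(unname(sel$weights[["w1"]]),
               round(w_cross / 0.05) * 0.05)
  # top set at the chosen weights matches enumeration
  w1 <- sel$weights[["w1"]]
  expect_setequal(sel$top_k,
                  brute_force_top_k(w1 * s1 + (1 - w1) * s2, clones, k))
})

test_that("selection differentials are exact and maximal for own-trait selection", {
  tab <- tibble::tibble(clone = sprintf("C%02d", 1:6),
                        VG = c(10, 20, 30, -10, 0, 5))
  attr(tab, "trait_mean") <- 100
  s <- selection_differentials(c("C01", "C02", "C03"), list(X = tab))
  expect_equal(s$S_pct, 20)

  fx <- fixture_12_clones()
  own <- selection_differentials(
    brute_force_top_k(fx$TH$VG, fx$TH$clone, 4), list(TH = fx$TH))
  cmb <- utils::combn(12, 4)
  all_s <- apply(cmb, 2, function(ix) mean(fx$TH$VG[ix]) / 500 * 100)
  expect_equal(own$S_pct, max(all_s), tolerance = 1e-12)

  expect_error(selection_differentials("C99", list(TH = fx$TH)),
               class = "clonegx_domain_error")
})

test_that("index selection leaves an independent trait's differential near zero", {
  set.seed(99)
  reps <- 40
  s3 <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 60
    clones <- sprintf("C%02d", 1:n)
    t1 <- tibble::tibble(clone = clones, VG = rnorm(n))
    t2 <- tibble::tibble(clone = clones, VG = rnorm(n))
    t3 <- tibble::tibble(clone = clones, VG = rnorm(n))
    attr(t1, "trait") <- "A"; attr(t1, "trait_mean") <- 10
    attr(t2, "trait") <- "B"; attr(t2, "trait_mean") <- 10
    attr(t3, "trait") <- "C"; attr(t3, "trait_mean") <- 10
    sel <- suppressWarnings(optimize_index_weights(t1, t2, k = 10,
                                                   grid_step = 0.05))
    s3[r] <- selection_differentials(sel$top_k, list(C = t3))$S_pct
  }
  # mean VG of 10 standard normals ~ N(0, 1/10); S% scales by 100/10
  expect_lt(abs(mean(s3)), 3 * sqrt(1 / 10) * 10 / sqrt(reps) * 2)
})

test_that("rank agreement metrics behave at the symmetric extremes", {
  n <- 20
  clones <- sprintf("C%02d", 1:n)
  a <- tibble::tibble(clone = clones, VG = seq(20, 1))
  b <- tibble::tibble(clone = clones, VG = seq(20, 1))
  expect_equal(rank_agreement(a, b, k = 10),
               tibble::tibble(spearman = 1, coincidence_pct = 100,
                              n_common = 20L))
  rev_b <- tibble::tibble(clone = clones, VG = seq(1, 20))
  ra <- rank_agreement(a, rev_b, k = 10)
  expect_equal(ra$spearman, -1)
  expect_equal(ra$coincidence_pct, 0)
  expect_error(rank_agreement(a, tibble::tibble(clone = "Z1", VG = 1)),
               class = "clonegx_domain_error")
})

test_that("weaker type-B correlation lowers cross-site rank agreement", {
  mk_cfg <- function(sc_var) sim_config(
    n_clones = 50, n_blocks = 5, plot_size = 1, mortality_rate = 0,
    traits = list(TH = list(mean = 500,
                            vc = c(clone = 400, site_clone = sc_var, plot = 0,
                                   residual = 800))),
    wood_traits = character(0)
  )
  reps <- 12
  rho_hi <- rho_lo <- numeric(reps)
  for (r in seq_len(reps)) {
    for (cfg in c("hi", "lo")) {
      cf <- if (cfg == "hi") mk_cfg(0) else mk_cfg(400) # rB = 1 vs 0.5
      obs <- simulate_clone_trial(cf, seed = 3000 + r)
      fit <- fit_clonal_model(obs, "TH", include_plot = FALSE,
                              compute_vcov = FALSE)
      M <- per_site_adjusted_vg(fit)
      va <- tibble::tibble(clone = rownames(M), VG = M[, 1])
      vb <- tibble::tibble(clone = rownames(M), VG = M[, 2])
      rho <- rank_agreement(va, vb, k = 10)$spearman
      if (cfg == "hi") rho_hi[r] <- rho else rho_lo[r] <- rho
    }
  }
  expect_gt(mean(rho_hi), mean(rho_lo) + 0.1)
})
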