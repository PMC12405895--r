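# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: expected-mean-squares ANOVA estimators for
# balanced designs, dense mixed-model equations for BLUPs, and brute-force
# enumeration for selection problems.

# EMS / ANOVA variance-component estimators for a balanced complete
# multi-site clonal trial (s sites, b blocks per site, c clones, n trees per
# plot, no missing data).
ems_components <- function(d, trait) {
  y <- d[[trait]]
  fs <- factor(d$site)
  fb <- factor(paste(d$site, d$block))
  fc <- factor(d$clone)
  fsc <- factor(paste(d$site, d$clone))
  fp <- factor(paste(d$site, d$block, d$clone))
  s <- nlevels(fs)
  b <- nlevels(fb) / s
  c_ <- nlevels(fc)
  n <- nrow(d) / (s * b * c_)
  stopifnot(n == round(n))
  a <- anova(lm(y ~ fs + fb + fc + fsc + fp))
  ms <- stats::setNames(a[["Mean Sq"]], rownames(a))
  ve <- ms[["Residuals"]]
  vp <- (ms[["fp"]] - ve) / n
  vsc <- (ms[["fsc"]] - ms[["fp"]]) / (n * b)
  vc <- (ms[["fc"]] - ms[["fsc"]]) / (n * b * s)
  c(clone = vc, site_clone = vsc, plot = vp, residual = ve)
}

# Dense mixed-model equations at fixed variance components: returns clone and
# site-by-clone BLUPs. Fixed effects: one dummy per (site, block) cell, which
# spans intercept + site + block-within-site.
mme_blups_dense <- function(d, trait, v_clone, v_sc, v_e) {
  y <- d[[trait]]
  X <- stats::model.matrix(~ factor(paste(d$site, d$block)))
  clones <- sort(unique(d$clone))
  sites <- sort(unique(d$site))
  Zc <- outer(d$clone, clones, `==`) * 1
  scl <- as.vector(outer(clones, sites, function(cl, s) paste(s, cl, sep = ":")))
  scl <- sort(scl)
  Zs <- outer(paste(d$site, d$clone, sep = ":"), scl, `==`) * 1
  W <- cbind(X, Zc, Zs)
  p <- ncol(X)
  Ginv <- diag(c(rep(0, p), rep(v_e / v_clone, ncol(Zc)),
                 rep(v_e / v_sc, ncol(Zs))))
  sol <- solve(crossprod(W) + Ginv, crossprod(W, y))
  u <- drop(sol)[-(1:p)]
  list(clone = stats::setNames(u[seq_along(clones)], clones),
       site_clone = stats::setNames(u[-seq_along(clones)], scl))
}

# Brute-force top-k subset by total score (enumerates all k-subsets).
brute_force_top_k <- function(score, clone, k) {
  cmb <- utils::combn(seq_along(score), k)
  tot <- apply(cmb, 2, function(ix) sum(score[ix]))
  best <- max(tot)
  ties <- which(abs(tot - best) < 1e-12)
  # among ties prefer lexicographically smallest clone set, mirroring the
  # deterministic id tie rule
  sets <- lapply(ties, function(j) sort(clone[cmb[, j]]))
  sets[[order(vapply(sets, paste, "", collapse = "|"))[1]]]
}

# Deterministic 12-clone two-trait fixture with distinct, hand-checkable
# genotypic values (no ties except where constructed).
fixture_12_clones <- function() {
  clones <- sprintf("K%02d", 1:12)
  vg_th <- c(30, 25, 22, 18, 15, 10, 5, 0, -5, -12, -20, -28)
  vg_vd <- c(-0.10, 0.22, -0.02, 0.15, 0.05, 0.18, -0.06, 0.12,
             0.02, 0.08, -0.04, 0.01)
  t1 <- tibble::tibble(clone = clones, VG = vg_th)
  attr(t1, "trait") <- "TH"
  attr(t1, "trait_mean") <- 500
  t2 <- tibble::tibble(clone = clones, VG = vg_vd)
  attr(t2, "trait") <- "Vdir"
  attr(t2, "trait_mean") <- 3.3
  list(TH = t1, Vdir = t2)
}

# Small helper: quiet simulation of a default-ish trial
quiet_fit <- function(...) suppressWarnings(fit_clonal_model(...))
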