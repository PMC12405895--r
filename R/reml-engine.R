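# Internal REML engine: variance-component estimation for Gaussian mixed
# models with independent scalar random-intercept strata, via the profiled
# restricted likelihood evaluated through sparse mixed-model equations (MME).
#
# Parameterization: variance ratios gamma_r = sigma2_r / sigma2_e on the log
# scale; sigma2_e is profiled out analytically. For C* = [X Z]'[X Z] +
# diag(0_p, 1/gamma), the restricted deviance is
#   -2 l_R = (n - p) (1 + log(2 pi ve)) + sum_r q_r log(gamma_r) + log|C*|,
# with ve = y'P*y / (n - p). The q_r log(gamma_r) term and the 1/gamma_r
# diagonal of C* cancel in the limit gamma_r -> 0, so boundary components are
# numerically benign on the log scale.

reml_control <- function(reltol = 1e-9, maxit = 600, boundary_tol = 1e-6,
                         newton_steps = 8L, lg_clamp = 18.5) {
  # lg_clamp bounds log(sigma2_r / sigma2_e): beyond ~exp(18.5) the ratio is
  # numerically indistinguishable from infinity while y'Py remains resolvable
  # in double precision
  list(reltol = reltol, maxit = maxit, boundary_tol = boundary_tol,
       newton_steps = newton_steps, lg_clamp = lg_clamp)
}

reml_core <- function(y, X, Zlist, fix_components = NULL,
                      control = reml_control(), compute_vcov = TRUE) {
  n <- length(y)
  p <- ncol(X)
  k <- length(Zlist)
  stopifnot(k >= 1, nrow(X) == n)
  qs <- vapply(Zlist, ncol, integer(1))
  M <- do.call(cbind, c(list(as(X, "CsparseMatrix")), Zlist))
  MtM <- forceSymmetric(Matrix::crossprod(M))
  Mty <- as.numeric(Matrix::crossprod(M, y))
  yty <- sum(y * y)
  dstrat <- rep.int(seq_len(k), qs)      # stratum of each random column
  ndiag <- p + sum(qs)

  # symbolic factorization reused across evaluations
  C0 <- MtM + Matrix::Diagonal(ndiag, x = c(rep(0, p), rep(1, sum(qs))))
  ch <- Matrix::Cholesky(C0, LDL = FALSE, perm = TRUE, super = FALSE)

  eval_parts <- function(gamma) {
    d <- c(rep(0, p), 1 / gamma[dstrat])
    C <- MtM + Matrix::Diagonal(ndiag, x = d)
    chl <- Matrix::update(ch, C)
    ld <- 2 * as.numeric(Matrix::determinant(chl, logarithm = TRUE,
                                             sqrt = TRUE)$modulus)
    sol <- as.numeric(Matrix::solve(chl, Mty, system = "A"))
    ypy <- yty - sum(Mty * sol)
    list(ld = ld, sol = sol, ypy = max(ypy, 1e-300))
  }

  m2ll_prof <- function(lg) {
    lg <- pmin(pmax(lg, -control$lg_clamp), control$lg_clamp)
    parts <- eval_parts(exp(lg))
    ve <- parts$ypy / (n - p)
    (n - p) * (1 + log(2 * pi * ve)) + sum(qs * lg) + parts$ld
  }

  # unprofiled deviance on the variance scale (for vcov / fixed components)
  m2ll_full <- function(v, ve) {
    parts <- eval_parts(v / ve)
    (n - p) * log(ve) + sum(qs * log(v / ve)) + parts$ld +
      parts$ypy / ve + (n - p) * log(2 * pi)
  }

  if (!is.null(fix_components)) {
    v <- fix_components[names(Zlist)]
    ve <- fix_components[["residual"]]
    gamma <- v / ve
    parts <- eval_parts(gamma)
    loglik <- -0.5 * ((n - p) * log(ve) + sum(qs * log(gamma)) + parts$ld +
                        parts$ypy / ve + (n - p) * log(2 * pi))
    return(finish_fit(parts, v, ve, NULL, rep(FALSE, k), loglik, TRUE, 0L,
                      p, qs, names(Zlist)))
  }

  # starting values: equal split of a crude total
  start_lg <- rep(log(0.2), k)
  opt <- if (k == 1) {
    optim(start_lg, m2ll_prof, method = "Brent",
          lower = -control$lg_clamp, upper = control$lg_clamp,
          control = list(reltol = control$reltol, maxit = control$maxit))
  } else {
    optim(start_lg, m2ll_prof, method = "Nelder-Mead",
          control = list(reltol = control$reltol, maxit = control$maxit))
  }
  lg <- pmin(pmax(opt$par, -control$lg_clamp), control$lg_clamp)
  boundary <- exp(lg) < control$boundary_tol
  f0 <- opt$value

  # Newton polish on interior coordinates (numerical derivatives); sharpens
  # the optimum well beyond Nelder-Mead's resolution on smooth problems.
  free <- which(!boundary)
  if (length(free) > 0 && control$newton_steps > 0) {
    fn_free <- function(lf) {
      full <- lg; full[free] <- lf
      m2ll_prof(full)
    }
    lf <- lg[free]
    for (it in seq_len(control$newton_steps)) {
      g <- num_grad(fn_free, lf)
      if (max(abs(g)) < 1e-7) break
      H <- num_hess(fn_free, lf)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- lf - step
      damp <- 1
      while (fn_free(cand) > fn_free(lf) - 1e-12 && damp > 1 / 64) {
        damp <- damp / 2
        cand <- lf - damp * step
      }
      if (fn_free(cand) >= fn_free(lf)) break
      lf <- cand
    }
    lg[free] <- lf
  }
  gamma <- exp(pmin(pmax(lg, -control$lg_clamp), control$lg_clamp))
  boundary <- gamma < control$boundary_tol
  parts <- eval_parts(gamma)
  ve <- parts$ypy / (n - p)
  v <- gamma * ve
  v[boundary] <- 0
  loglik <- -0.5 * m2ll_prof(lg)
  converged <- is.finite(loglik) && (opt$convergence == 0 || length(free) > 0)

  res_boundary <- FALSE
  vy <- var(y)
  if (is.finite(vy) && vy > 0 && any(lg >= control$lg_clamp - 0.05)) {
    # Residual variance collapsed to (numerical) zero: the restricted
    # likelihood is unbounded and the ratio parameterization degenerates.
    # Pin the residual at a negligible floor and re-estimate the remaining
    # components at that fixed value, which recovers the natural limit
    # (e.g. the between-clone variance when all ramets of a clone agree).
    ve_fix <- 1e-8 * vy
    obj2 <- function(lv) m2ll_full(exp(lv), ve_fix)
    lv0 <- log(pmax(v, 1e-8 * vy))
    opt2 <- if (k == 1) {
      optim(lv0, obj2, method = "Brent", lower = log(vy) - 25,
            upper = log(vy) + 25)
    } else {
      optim(lv0, obj2, method = "Nelder-Mead",
            control = list(reltol = control$reltol, maxit = control$maxit))
    }
    v <- exp(opt2$par)
    boundary <- v < control$boundary_tol * vy
    v[boundary] <- 0
    parts <- eval_parts(pmax(v, 1e-12 * vy) / ve_fix)
    ve <- 0
    res_boundary <- TRUE
    loglik <- NA_real_
    converged <- TRUE
    compute_vcov <- FALSE
  }

  vcov <- NULL
  if (compute_vcov) {
    ipar <- c(v[!boundary], residual = ve)
    hfun <- function(th) {
      vv <- v
      vv[!boundary] <- th[seq_len(sum(!boundary))]
      vv[boundary] <- 1e-12 * ve
      m2ll_full(vv, th[length(th)])
    }
    H <- tryCatch(num_hess(hfun, ipar, h = pmax(0.02 * abs(ipar), 1e-10)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        nm <- c(names(Zlist)[!boundary], "residual")
        dimnames(vc) <- list(nm, nm)
        vcov <- vc
      }
    }
  }

  finish_fit(parts, v, ve, vcov, boundary, loglik, converged,
             opt$counts[["function"]], p, qs, names(Zlist), res_boundary)
}

finish_fit <- function(parts, v, ve, vcov, boundary, loglik, converged,
                       neval, p, qs, znames, res_boundary = FALSE) {
  sol <- parts$sol
  beta <- sol[seq_len(p)]
  u <- vector("list", length(qs))
  off <- p
  for (r in seq_along(qs)) {
    u[[r]] <- sol[off + seq_len(qs[r])]
    if (boundary[r]) u[[r]][] <- 0
    off <- off + qs[r]
  }
  names(u) <- znames
  list(
    vc = c(setNames(v, znames), residual = ve),
    vcov = vcov,
    boundary = c(setNames(boundary, znames), residual = res_boundary),
    beta = beta, u = u, loglik = loglik, converged = converged,
    neval = neval
  )
}

# central-difference gradient / Hessian (small, smooth problems only)
num_grad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hess <- function(f, x, h = 1e-3) {
  # h: scalar step or per-coordinate steps (use steps proportional to the
  # parameter scale for variance components, whose curvature is shallow)
  k <- length(x)
  if (length(h) == 1) h <- rep(h, k)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- rep(0, k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- rep(0, k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# sum-to-zero fixed-effect design for intercept + site + block-within-site
fixed_design <- function(site, block) {
  n <- length(site)
  sites <- sort(unique(site))
  cols <- list(`(Intercept)` = rep(1, n))
  if (length(sites) > 1) {
    for (s in sites[-length(sites)]) {
      cols[[paste0("site_", s)]] <-
        (site == s) - (site == sites[length(sites)])
    }
  }
  for (s in sites) {
    bl <- sort(unique(block[site == s]))
    if (length(bl) > 1) {
      last <- bl[length(bl)]
      for (b in bl[-length(bl)]) {
        cols[[paste0("block_", s, ".", b)]] <-
          (site == s) * ((block == b) - (block == last))
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

indicator_matrix <- function(f) {
  f <- droplevels_keep(f)
  Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f)), dimnames = list(NULL, levels(f))
  )
}

# factor() keeping an explicitly supplied full level set
droplevels_keep <- function(f) if (is.factor(f)) f else factor(f)
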