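#' Fit the bivariate clonal model for a trait pair
#'
#' Joint REML fit of two traits measured on (partly) the same trees, with
#' trait-specific fixed effects (intercept, site, block-within-site) and
#' unstructured 2x2 covariance matrices for three random strata: clone,
#' site-by-clone, and the residual. The residual covariance applies only
#' between the two measurements of the same tree; trees carrying a single
#' trait contribute through that trait's residual variance alone. The plot
#' stratum is deliberately absent so that the same model serves every trait
#' pair, including wood traits measured on one ramet per plot.
#'
#' Each stratum covariance is parameterized by its Cholesky factor
#' (log-diagonal), which keeps the matrices positive semi-definite; stratum
#' correlations that converge to |r| > 0.999 are flagged as clamped and the
#' asymptotic covariance of the estimates (used for Delta-method standard
#' errors of derived correlations) is not computed.
#'
#' @param obs Observation tibble carrying both trait columns.
#' @param pair Character vector of two trait names.
#' @param compute_vcov Compute the asymptotic covariance of the nine
#'   (co)variance parameters at convergence. Default `TRUE`.
#' @param control Optimizer control from `reml_control()`.
#' @return An object of class `clonal_bifit`: list with `strata` (named list
#'   of 2x2 covariance matrices `clone`, `site_clone`, `residual`),
#'   `correlations` (tibble per stratum), `vcov` (9x9 or `NULL`), `loglik`,
#'   `converged`, `n_trees`, `n_complete`, `pair`, `clamped`.
#' @seealso [genotypic_correlation_A()], [phenotypic_correlation()]
#' @export
fit_bivariate_model <- function(obs, pair, compute_vcov = TRUE,
                                control = reml_control()) {
  stopifnot(length(pair) == 2)
  if (!all(pair %in% names(obs))) {
    abort("both traits of `pair` must be columns of `obs`",
          class = "clonegx_schema_error")
  }
  y1 <- obs[[pair[1]]]
  y2 <- obs[[pair[2]]]
  keep <- !(is.na(y1) & is.na(y2))
  d <- obs[keep, , drop = FALSE]
  y1 <- y1[keep]; y2 <- y2[keep]
  if (!any(!is.na(y1) & !is.na(y2))) {
    abort("no tree carries both traits", class = "clonegx_model_error")
  }

  sites <- sort(unique(d$site))
  clones <- sort(unique(d$clone))
  multi_site <- length(sites) > 1

  Xuni <- fixed_design(d$site, d$block)
  Zc <- indicator_matrix(factor(d$clone, levels = clones))
  Zs <- NULL
  if (multi_site) {
    sc_levels <- sort(as.vector(outer(clones, sites,
                                      function(cl, s) paste(s, cl, sep = ":"))))
    Zs <- indicator_matrix(factor(paste(d$site, d$clone, sep = ":"),
                                  levels = sc_levels))
  }

  # stacked design: trait-1 rows then trait-2 rows (per measured value);
  # random-effect columns interleaved (group x trait) so G^-1 = I (x) Sigma^-1
  has1 <- !is.na(y1); has2 <- !is.na(y2)
  expand_Z <- function(Z) {
    q <- ncol(Z)
    T1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1, 2))
    Zt <- function(Zr, t) {
      # map group j -> column 2(j-1)+t
      sm <- methods::as(Zr, "TsparseMatrix")
      Matrix::sparseMatrix(i = sm@i + 1L, j = 2L * sm@j + t, x = sm@x,
                           dims = c(nrow(Zr), 2L * q))
    }
    rbind(Zt(Z[has1, , drop = FALSE], 1L), Zt(Z[has2, , drop = FALSE], 2L))
  }
  pad <- function(A, side) {
    z <- Matrix::Matrix(0, nrow(A), ncol(A), sparse = TRUE)
    if (side == 1) cbind(A, z) else cbind(z, A)
  }
  X <- rbind(pad(as(Xuni[has1, , drop = FALSE], "CsparseMatrix"), 1),
             pad(as(Xuni[has2, , drop = FALSE], "CsparseMatrix"), 2))
  Zlist <- list(clone = expand_Z(Zc))
  if (multi_site) Zlist$site_clone <- expand_Z(Zs)
  M <- do.call(cbind, c(list(X), Zlist))
  p <- ncol(X)
  qg <- c(clone = length(clones),
          if (multi_site) c(site_clone = length(clones) * length(sites)))
  yst <- c(y1[has1], y2[has2])
  nst <- length(yst)

  # residual bookkeeping: complete trees vs singletons, in stacked row order
  comp <- has1 & has2
  idx1 <- which(has1)          # stacked rows 1..n1 ~ idx1
  idx2 <- which(has2)
  n1 <- length(idx1)
  r1_of <- match(seq_along(y1), idx1)          # original row -> stacked row (trait 1)
  r2_of <- n1 + match(seq_along(y2), idx2)
  rows1c <- r1_of[comp]; rows2c <- r2_of[comp]
  rows1s <- r1_of[has1 & !has2]; rows2s <- r2_of[has2 & !has1]

  M1c <- M[rows1c, , drop = FALSE]; M2c <- M[rows2c, , drop = FALSE]
  y1c <- yst[rows1c]; y2c <- yst[rows2c]
  A11 <- Matrix::crossprod(M1c); A22 <- Matrix::crossprod(M2c)
  A12 <- Matrix::crossprod(M1c, M2c)
  c11 <- as.numeric(Matrix::crossprod(M1c, y1c))
  c12 <- as.numeric(Matrix::crossprod(M1c, y2c))
  c21 <- as.numeric(Matrix::crossprod(M2c, y1c))
  c22 <- as.numeric(Matrix::crossprod(M2c, y2c))
  yy11 <- sum(y1c^2); yy12 <- sum(y1c * y2c); yy22 <- sum(y2c^2)
  B1 <- NULL; B2 <- NULL; b1 <- 0; b2 <- 0; yys1 <- 0; yys2 <- 0
  if (length(rows1s) > 0) {
    M1s <- M[rows1s, , drop = FALSE]
    B1 <- Matrix::crossprod(M1s)
    b1 <- as.numeric(Matrix::crossprod(M1s, yst[rows1s]))
    yys1 <- sum(yst[rows1s]^2)
  }
  if (length(rows2s) > 0) {
    M2s <- M[rows2s, , drop = FALSE]
    B2 <- Matrix::crossprod(M2s)
    b2 <- as.numeric(Matrix::crossprod(M2s, yst[rows2s]))
    yys2 <- sum(yst[rows2s]^2)
  }
  n_comp <- sum(comp)

  chol2cov <- function(th) {
    L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    L %*% t(L)
  }
  strat_names <- c(names(qg), "residual")
  n_strat <- length(strat_names)
  N <- p + sum(2 * qg)

  # Pattern-stable assembly of the MME coefficient matrix: every candidate
  # nonzero (data cross-products, G^-1 blocks, full diagonal) is present in a
  # fixed template whose numeric values are overwritten each evaluation, so
  # one symbolic Cholesky factorization is reused throughout.
  upper_t <- function(A) {
    A <- methods::as(methods::as(forceSymmetric(A, "U"), "generalMatrix"),
                     "TsparseMatrix")
    keep <- A@i <= A@j
    list(i = A@i[keep], j = A@j[keep], x = A@x[keep])
  }
  parts <- list(A11 = upper_t(A11), A22 = upper_t(A22),
                A12s = upper_t(A12 + Matrix::t(A12)))
  if (!is.null(B1)) parts$B1 <- upper_t(B1)
  if (!is.null(B2)) parts$B2 <- upper_t(B2)
  gidx <- list()
  for (r in seq_len(n_strat - 1)) {
    off <- p + if (r == 1) 0L else sum(2 * qg[seq_len(r - 1)])
    first <- off + 2L * (seq_len(qg[r]) - 1L)      # 0-based col of trait-1 effect
    gidx[[r]] <- list(
      i = c(first, first, first + 1L),
      j = c(first, first + 1L, first + 1L),
      slot = rep(1:3, each = qg[r])                # (1,1), (1,2), (2,2) of Sigma^-1
    )
  }
  all_i <- c(unlist(lapply(parts, `[[`, "i")),
             unlist(lapply(gidx, `[[`, "i")), 0:(N - 1))
  all_j <- c(unlist(lapply(parts, `[[`, "j")),
             unlist(lapply(gidx, `[[`, "j")), 0:(N - 1))
  key <- all_i + N * all_j
  ukey <- sort(unique(key))
  nnz <- length(ukey)
  templ <- Matrix::sparseMatrix(
    i = ukey %% N + 1L, j = ukey %/% N + 1L, x = rep(1, nnz),
    dims = c(N, N), symmetric = TRUE
  )
  # slot order of a dsCMatrix built from these triplets: column-major upper,
  # i.e. ordered by key; map every contribution to its slot
  slot_of <- function(i, j) match(i + N * j, ukey)
  part_slots <- lapply(parts, function(pp) slot_of(pp$i, pp$j))
  g_slots <- lapply(gidx, function(gg) slot_of(gg$i, gg$j))
  diag_slots <- slot_of(0:(N - 1), 0:(N - 1))
  Ctempl <- methods::as(templ, "CsparseMatrix")
  stopifnot(length(Ctempl@x) == nnz)
  ch0 <- NULL   # symbolic factor cached at the first valid evaluation

  inv2 <- function(S, det) {
    matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / det
  }

  deviance_cov <- function(covs) {
    SE <- covs[[n_strat]]
    detE <- SE[1, 1] * SE[2, 2] - SE[1, 2]^2
    if (any(diag(SE) <= 0) || detE <= 1e-12 * SE[1, 1] * SE[2, 2]) {
      return(1e12)
    }
    iE <- inv2(SE, detE)
    xs <- numeric(nnz)
    xs[part_slots$A11] <- xs[part_slots$A11] + iE[1, 1] * parts$A11$x
    xs[part_slots$A22] <- xs[part_slots$A22] + iE[2, 2] * parts$A22$x
    xs[part_slots$A12s] <- xs[part_slots$A12s] + iE[1, 2] * parts$A12s$x
    rhs <- iE[1, 1] * c11 + iE[1, 2] * (c12 + c21) + iE[2, 2] * c22
    yry <- iE[1, 1] * yy11 + 2 * iE[1, 2] * yy12 + iE[2, 2] * yy22
    ldR <- n_comp * log(detE)
    if (!is.null(B1)) {
      xs[part_slots$B1] <- xs[part_slots$B1] + parts$B1$x / SE[1, 1]
      rhs <- rhs + b1 / SE[1, 1]
      yry <- yry + yys1 / SE[1, 1]
      ldR <- ldR + length(rows1s) * log(SE[1, 1])
    }
    if (!is.null(B2)) {
      xs[part_slots$B2] <- xs[part_slots$B2] + parts$B2$x / SE[2, 2]
      rhs <- rhs + b2 / SE[2, 2]
      yry <- yry + yys2 / SE[2, 2]
      ldR <- ldR + length(rows2s) * log(SE[2, 2])
    }
    ldG <- 0
    for (r in seq_len(n_strat - 1)) {
      Sr <- covs[[r]]
      detr <- Sr[1, 1] * Sr[2, 2] - Sr[1, 2]^2
      if (any(diag(Sr) <= 0) || detr <= 1e-12 * Sr[1, 1] * Sr[2, 2]) {
        return(1e12)
      }
      ldG <- ldG + qg[r] * log(detr)
      iS <- inv2(Sr, detr)
      vals <- c(iS[1, 1], iS[1, 2], iS[2, 2])[gidx[[r]]$slot]
      xs[g_slots[[r]]] <- xs[g_slots[[r]]] + vals
    }
    Cmat <- Ctempl
    Cmat@x <- xs
    chl <- if (is.null(ch0)) {
      tryCatch({
        ch0 <<- Matrix::Cholesky(Cmat, LDL = FALSE, perm = TRUE)
        ch0
      }, error = function(e) NULL)
    } else {
      tryCatch(Matrix::update(ch0, Cmat), error = function(e) NULL)
    }
    if (is.null(chl)) return(1e12)
    ld <- 2 * as.numeric(Matrix::determinant(chl, logarithm = TRUE,
                                             sqrt = TRUE)$modulus)
    sol <- as.numeric(Matrix::solve(chl, rhs, system = "A"))
    ypy <- yry - sum(rhs * sol)
    out <- ldR + ldG + ld + ypy + (nst - p) * log(2 * pi)
    attr(out, "sol") <- sol
    out
  }

  dev_theta <- function(th) {
    covs <- lapply(seq_len(n_strat), function(r) chol2cov(th[3 * r - 2:0]))
    as.numeric(deviance_cov(covs))
  }

  # starting values from phenotypic moments of the complete trees
  s1 <- var(y1c); s2 <- var(y2c); r0 <- suppressWarnings(cor(y1c, y2c))
  if (!is.finite(r0)) r0 <- 0
  start_cov <- function(f) {
    S <- matrix(c(s1 * f, r0 * f * sqrt(s1 * s2) * 0.5,
                  r0 * f * sqrt(s1 * s2) * 0.5, s2 * f), 2, 2)
    L <- t(chol(S))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  th0 <- c(start_cov(0.25),
           if (multi_site) start_cov(0.05),
           start_cov(0.6))

  opt <- optim(th0, dev_theta, method = "Nelder-Mead",
               control = list(reltol = control$reltol,
                              maxit = max(control$maxit, 1500)))
  th <- opt$par
  # Newton polish
  for (it in seq_len(control$newton_steps)) {
    g <- num_grad(dev_theta, th, h = 1e-4)
    if (max(abs(g)) < 1e-5) break
    H <- num_hess(dev_theta, th, h = 1e-3)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- th - step
    damp <- 1
    while (dev_theta(cand) > dev_theta(th) - 1e-12 && damp > 1 / 64) {
      damp <- damp / 2
      cand <- th - damp * step
    }
    if (dev_theta(cand) >= dev_theta(th)) break
    th <- cand
  }

  gfin <- num_grad(dev_theta, th, h = 1e-4)
  covs <- lapply(seq_len(n_strat), function(r) chol2cov(th[3 * r - 2:0]))
  names(covs) <- strat_names
  for (r in seq_along(covs)) {
    dimnames(covs[[r]]) <- list(pair, pair)
  }
  dev_final <- deviance_cov(covs)
  loglik <- -0.5 * as.numeric(dev_final)
  sol <- attr(dev_final, "sol")

  corr_of <- function(S) S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  cors <- vapply(covs, corr_of, numeric(1))
  clamped <- abs(cors) > 0.999
  cors_cl <- pmin(pmax(cors, -1), 1)

  vcov <- NULL
  if (compute_vcov && !any(clamped)) {
    par_of <- function(covs) {
      unlist(lapply(covs, function(S) c(S[1, 1], S[1, 2], S[2, 2])))
    }
    covs_of_par <- function(pr) {
      lapply(seq_len(n_strat), function(r) {
        v <- pr[3 * r - 2:0]
        matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
      })
    }
    pr0 <- par_of(covs)
    H <- tryCatch(
      num_hess(function(pr) as.numeric(deviance_cov(covs_of_par(pr))),
               pr0, h = pmax(0.02 * abs(pr0), 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(H)) {
      vcov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vcov)) {
        nm <- as.vector(t(outer(strat_names, c("v1", "cov", "v2"), paste,
                                sep = ".")))
        dimnames(vcov) <- list(nm, nm)
      }
    }
  }

  blup_clone <- NULL
  if (!is.null(sol)) {
    uc <- sol[p + seq_len(2 * length(clones))]
    blup_clone <- tibble(
      clone = rep(clones, each = 2),
      trait = rep(pair, times = length(clones)),
      blup = uc
    )
  }

  structure(
    list(
      pair = pair,
      strata = covs,
      correlations = tibble(stratum = strat_names,
                            correlation = unname(cors_cl),
                            clamped = unname(clamped)),
      vcov = vcov,
      blup_clone = blup_clone,
      loglik = loglik,
      converged = is.finite(loglik) &&
        (opt$convergence == 0 || max(abs(gfin)) < 0.05),
      n_trees = nrow(d),
      n_complete = n_comp
    ),
    class = "clonal_bifit"
  )
}

#' @export
print.clonal_bifit <- function(x, ...) {
  cat(sprintf("<clonal_bifit> %s ~ %s: %d trees (%d with both traits)\n",
              x$pair[1], x$pair[2], x$n_trees, x$n_complete))
  for (s in names(x$strata)) {
    S <- x$strata[[s]]
    cat(sprintf("  %-11s var1 %.5g  cov %.5g  var2 %.5g  (r = %.3f%s)\n",
                s, S[1, 1], S[1, 2], S[2, 2],
                x$correlations$correlation[x$correlations$stratum == s],
                if (x$correlations$clamped[x$correlations$stratum == s]) {
                  ", clamped"
                } else ""))
  }
  cat(sprintf("  restricted logLik %.3f%s\n", x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
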