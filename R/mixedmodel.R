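# Multivariate mixed-model engine with Kronecker covariance
#
# Model: observations y_{kji} (trait k, environment j, genotype i) with
# fixed trait/environment means and optional fixed marker effects, random
# breeding values g ~ N(0, G0 x A) and errors e ~ N(0, R0 x I), where G0 and
# R0 are t x t (co)variance matrices. A is eigendecomposed once
# (A = U D U'); rotating every trait-environment cell by U' makes the
# likelihood separate into n independent m-vectors (m = number of cells),
# inside which G0 x A contributes a low-rank term d_i * T G0 T'. Each
# likelihood evaluation is then O(n m^2) after an m x m eigen step, so full
# (RE)ML scans over thousands of markers or grid points are feasible.

.theta_chol <- function(v, t) {
  L <- matrix(0, t, t)
  L[lower.tri(L, diag = TRUE)] <- v
  diag(L) <- exp(pmin(pmax(diag(L), -20), 20))
  L
}

.theta_to_cov <- function(theta, t) {
  nc <- t * (t + 1) / 2
  Lg <- .theta_chol(theta[seq_len(nc)], t)
  Lr <- .theta_chol(theta[nc + seq_len(nc)], t)
  list(G0 = tcrossprod(Lg), R0 = tcrossprod(Lr))
}

# Pack starting values from per-trait sample variances.
.theta_init <- function(varY, t, adiag = 2) {
  g <- pmax(varY, 1e-6) * 0.5 / adiag
  r <- pmax(varY, 1e-6) * 0.5
  nc <- t * (t + 1) / 2
  th <- numeric(2 * nc)
  di <- which(diag(t)[lower.tri(diag(t), diag = TRUE)] == 1)  # diagonal slots
  th[di] <- 0.5 * log(g)
  th[nc + di] <- 0.5 * log(r)
  th
}

# Core negative log-likelihood for the rotated, cell-structured model.
# prep carries: Yrot (n x m), Vrot (n x K), P (m x p), cov_index (p),
# trait_of_cell, env_of_cell, d (eigenvalues of A), t, method.
.mt_nll_factory <- function(prep) {
  n <- nrow(prep$Yrot); m <- ncol(prep$Yrot); p <- ncol(prep$P)
  tt <- prep$t
  same_env <- outer(prep$env_of_cell, prep$env_of_cell, "==")
  Gidx <- matrix(prep$trait_of_cell[rep(seq_len(m), m)], m, m)
  tpair_row <- matrix(prep$trait_of_cell, m, m)
  tpair_col <- t(tpair_row)
  N <- n * m
  z_big <- NULL

  function(theta, want = "nll") {
    cv <- .theta_to_cov(theta, tt)
    MG <- cv$G0[cbind(as.vector(tpair_row), as.vector(tpair_col))]
    MG <- matrix(MG, m, m)
    MR <- matrix(cv$R0[cbind(as.vector(tpair_row), as.vector(tpair_col))],
                 m, m) * same_env
    ch <- tryCatch(chol(MR), error = function(e) NULL)
    if (is.null(ch)) return(if (want == "nll") 1e10 else NULL)
    L <- t(ch)
    Linv <- forwardsolve(L, diag(m))
    W0 <- Linv %*% MG %*% t(Linv)
    eg <- eigen((W0 + t(W0)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    S <- t(eg$vectors) %*% Linv
    Z <- prep$Yrot %*% t(S)
    w <- 1 / (1 + outer(prep$d, lam))
    SP <- S %*% prep$P
    B <- matrix(0, N, p)
    for (j in seq_len(p))
      B[, j] <- as.vector(tcrossprod(prep$Vrot[, prep$cov_index[j]], SP[, j]))
    wv <- as.vector(w)
    z <- as.vector(Z)
    Bw <- B * wv
    XtWX <- crossprod(B, Bw)
    cx <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cx)) return(if (want == "nll") 1e10 else NULL)
    beta <- backsolve(cx, forwardsolve(t(cx), crossprod(Bw, z)))
    resid <- z - B %*% beta
    q <- sum(wv * resid^2)
    logdetV <- 2 * n * sum(log(diag(L))) + sum(log1p(outer(prep$d, lam)))
    ll <- if (prep$method == "REML")
      -0.5 * ((N - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(cx))) + q)
    else
      -0.5 * (N * log(2 * pi) + logdetV + q)
    if (want == "nll") {
      if (!is.finite(ll)) return(1e10)
      return(-ll)
    }
    vb <- backsolve(cx, backsolve(cx, diag(p), transpose = TRUE))
    list(logLik = ll, beta = drop(beta), vbeta = vb, G0 = cv$G0, R0 = cv$R0,
         q = q)
  }
}

# Base preparation: cell layout, complete genotypes, eigen-rotation of A
# and of the data. Marker design columns are added separately by
# .mt_design() so genome scans pay the O(n^3) eigen step only once.
.mt_prepare_base <- function(phenos, traits, A, method = "REML") {
  stopifnot(inherits(phenos, "trait_dataset"))
  stage <- attr(phenos, "stage")
  df <- as.data.frame(phenos)
  if (stage == "stage2") df$environment <- "."
  df <- df[df$trait %in% traits, c("genotype", "environment", "trait",
                                   "value")]
  tt <- length(traits)

  # cells = trait x environment combinations actually observed
  cells <- unique(df[, c("trait", "environment")])
  cells <- cells[order(match(cells$trait, traits), cells$environment), ]
  m <- nrow(cells)

  # genotypes complete across all cells (row deletion otherwise)
  wide <- vector("list", m)
  ids <- NULL
  for (c_i in seq_len(m)) {
    sub <- df[df$trait == cells$trait[c_i] &
                df$environment == cells$environment[c_i], ]
    sub <- sub[!is.na(sub$value), ]
    wide[[c_i]] <- stats::setNames(sub$value, sub$genotype)
    ids <- if (is.null(ids)) sub$genotype else intersect(ids, sub$genotype)
  }
  Amat <- if (inherits(A, "kinship_matrix")) A$A else as.matrix(A)
  if (!is.null(rownames(Amat))) ids <- intersect(ids, rownames(Amat))
  n_all <- length(unique(df$genotype))
  if (length(ids) < n_all)
    message("dropping ", n_all - length(ids),
            " genotype(s) with incomplete records")
  if (length(ids) < 10) stop("fewer than 10 complete genotypes")
  Y <- vapply(wide, function(v) unname(v[ids]), numeric(length(ids)))
  Amat <- if (!is.null(rownames(Amat))) Amat[ids, ids] else Amat
  ea <- eigen((Amat + t(Amat)) / 2, symmetric = TRUE)
  d <- pmax(ea$values, 0)
  U <- ea$vectors
  n <- length(ids)
  list(Yrot = crossprod(U, Y), U = U, urot = drop(crossprod(U, rep(1, n))),
       traits = traits, trait_of_cell = match(cells$trait, traits),
       env_of_cell = cells$environment, d = d, t = tt, method = method,
       n = n, ids = ids, cells = cells,
       varY = vapply(seq_len(tt), function(k)
         mean(apply(Y[, match(cells$trait, traits) == k, drop = FALSE], 2,
                    stats::var)), numeric(1)),
       adiag = mean(diag(Amat)))
}

# Attach the fixed-effect design: cell means, then per-trait marker main
# effects, then marker x environment contrasts (first environment of each
# trait as reference). `markers` may be NULL, a dosage vector (shared by
# all traits) or a per-trait list; vectors may be raw (named by genotype,
# rotated here) or already rotated (rotated = TRUE).
.mt_design <- function(prep, markers = NULL, marker_by_env = FALSE,
                       rotated = FALSE) {
  tt <- prep$t
  traits <- prep$traits
  cells <- prep$cells
  m <- nrow(cells)
  n <- prep$n
  mk <- vector("list", tt)
  if (!is.null(markers)) {
    if (is.numeric(markers)) mk <- rep(list(markers), tt)
    else {
      stopifnot(is.list(markers), length(markers) == tt)
      mk <- markers
    }
    if (!rotated)
      mk <- lapply(mk, function(v) {
        if (is.null(v)) return(NULL)
        if (!is.null(names(v))) v <- v[prep$ids]
        stopifnot(length(v) == n, !anyNA(v))
        drop(crossprod(prep$U, unname(v)))
      })
  }
  P <- diag(m)
  cov_index <- rep(1L, m)
  labels <- sprintf("mu[%s:%s]", cells$trait, cells$environment)
  Vrot <- matrix(prep$urot, n, 1)
  for (k in seq_len(tt)) {
    if (is.null(mk[[k]])) next
    Vrot <- cbind(Vrot, mk[[k]])
    ci <- ncol(Vrot)
    P <- cbind(P, as.numeric(cells$trait == traits[k]))
    cov_index <- c(cov_index, ci)
    labels <- c(labels, sprintf("alpha[%s]", traits[k]))
    if (marker_by_env) {
      envs_k <- cells$environment[cells$trait == traits[k]]
      if (length(envs_k) > 1) for (e in envs_k[-1]) {
        P <- cbind(P, as.numeric(cells$trait == traits[k] &
                                   cells$environment == e))
        cov_index <- c(cov_index, ci)
        labels <- c(labels, sprintf("alphaE[%s:%s]", traits[k], e))
      }
    }
  }
  prep$Vrot <- Vrot
  prep$P <- P
  prep$cov_index <- cov_index
  prep$labels <- labels
  prep
}

.mt_prepare <- function(phenos, traits, A, markers = NULL,
                        marker_by_env = FALSE, method = "REML") {
  prep <- .mt_prepare_base(phenos, traits, A, method)
  .mt_design(prep, markers, marker_by_env)
}

#' Fit a multivariate mixed model with G0 x A genetic covariance
#'
#' Restricted maximum likelihood (or ML) fit of the multi-trait model with
#' fixed trait-by-environment means, optional fixed marker effects (shared
#' or trait-specific) and optional marker-by-environment interactions;
#' random breeding values with covariance `G0 (x) A` and errors `R0 (x) I`.
#' Trait pairs with unequal environment sets are handled by restricting the
#' error structure to the observed trait-environment cells; genotypes with
#' incomplete records are removed (row deletion).
#'
#' @param phenos a stage-1 (per-environment BLUEs) or stage-2
#'   (across-environment BLUEs) [trait_dataset].
#' @param traits character vector of 1-3 trait names to model jointly.
#' @param A a [kinship_matrix] or relationship matrix (rownames = genotype
#'   ids).
#' @param markers `NULL`, a named dosage vector applied to every trait, or a
#'   list with one dosage vector (or `NULL`) per trait.
#' @param marker_by_env add fixed marker-by-environment interaction
#'   contrasts (reference = first environment of each trait).
#' @param method `"REML"` (default) or `"ML"`; ML must be used when
#'   comparing models that differ in fixed effects.
#' @param constrain_rg for two traits: force the genetic covariance to zero
#'   (the constrained model of the genetic-correlation LR test).
#' @param theta0 optional starting values (log-diagonal Cholesky of G0 then
#'   R0).
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return object of class `mt_fit` with elements `G0`, `R0`, `beta`,
#'   `vbeta`, `logLik`, `method`, `converged`, `n_iter`, `traits`, `n`.
#' @export
fit_multitrait <- function(phenos, traits, A, markers = NULL,
                           marker_by_env = FALSE,
                           method = c("REML", "ML"), constrain_rg = FALSE,
                           theta0 = NULL, control = list()) {
  method <- match.arg(method)
  prep <- .mt_prepare(phenos, traits, A, markers, marker_by_env, method)
  .mt_optim(prep, traits, constrain_rg, theta0, control)
}

.mt_optim <- function(prep, traits, constrain_rg = FALSE, theta0 = NULL,
                      control = list()) {
  tt <- prep$t
  nll <- .mt_nll_factory(prep)
  nc <- tt * (tt + 1) / 2
  th0 <- if (!is.null(theta0)) theta0
  else .theta_init(prep$varY, tt, prep$adiag)
  free <- rep(TRUE, 2 * nc)
  if (constrain_rg) {
    if (tt != 2) stop("constrain_rg requires exactly 2 traits")
    free[2] <- FALSE  # Cholesky off-diagonal of G0
    th0[2] <- 0
  }
  wrap <- function(par) {
    th <- th0
    th[free] <- par
    nll(th)
  }
  ctrl <- utils::modifyList(list(maxit = max(2000, 500 * sum(free)),
                                 reltol = 1e-10), control)
  opt <- stats::optim(th0[free], wrap, method = "Nelder-Mead", control = ctrl)
  # one polishing restart guards against premature simplex collapse
  opt2 <- stats::optim(opt$par, wrap, method = "Nelder-Mead", control = ctrl)
  if (opt2$value < opt$value) opt <- opt2
  th <- th0
  th[free] <- opt$par
  full <- nll(th, want = "full")
  if (is.null(full)) stop("mixed-model fit failed at the optimum")
  names(full$beta) <- prep$labels
  dimnames(full$vbeta) <- list(prep$labels, prep$labels)
  dimnames(full$G0) <- dimnames(full$R0) <- list(traits, traits)
  rg <- if (tt == 2)
    full$G0[1, 2] / sqrt(full$G0[1, 1] * full$G0[2, 2]) else NA_real_
  structure(list(G0 = full$G0, R0 = full$R0, beta = full$beta,
                 vbeta = full$vbeta, logLik = full$logLik,
                 method = prep$method, converged = opt$convergence == 0,
                 n_iter = opt$counts[1], theta = th, traits = traits,
                 n = prep$n, constrained = constrain_rg,
                 boundary = tt == 2 && is.finite(rg) && abs(rg) > 0.999,
                 prep = prep),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat("mt_fit (", x$method, "): ", length(x$traits), " trait(s), n = ", x$n,
      ", logLik = ", format(x$logLik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  cat("G0:\n"); print(signif(x$G0, 4))
  cat("R0:\n"); print(signif(x$R0, 4))
  invisible(x)
}

#' @export
logLik.mt_fit <- function(object, ...) object$logLik

#' Genetic correlation and its likelihood-ratio test
#'
#' For a bivariate fit, `r_g = s_12 / sqrt(s_11 s_22)` from G0. Significance
#' is assessed by refitting the model with `s_12 = 0` and comparing
#' likelihoods: `LR = 2 (logL_full - logL_constrained)` (floored at zero)
#' against a chi-square with 1 df.
#'
#' @param fit a converged two-trait [fit_multitrait()] result.
#' @return list with `r_g`, `LR`, `p_value`, and the constrained fit's
#'   log-likelihood.
#' @export
genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "mt_fit"), length(fit$traits) == 2)
  if (!fit$converged) stop("refusing a non-converged fit")
  s11 <- fit$G0[1, 1]; s22 <- fit$G0[2, 2]; s12 <- fit$G0[1, 2]
  if (s11 <= 1e-10 || s22 <= 1e-10) {
    warning("zero genetic variance: correlation undefined")
    return(list(r_g = NA_real_, LR = NA_real_, p_value = NA_real_,
                logLik_constrained = NA_real_))
  }
  r_g <- s12 / sqrt(s11 * s22)
  con <- .mt_optim(fit$prep, fit$traits, constrain_rg = TRUE,
                   theta0 = {th <- fit$theta; th[2] <- 0; th})
  LR <- max(0, 2 * (fit$logLik - con$logLik))
  list(r_g = r_g, LR = LR, p_value = stats::pchisq(LR, 1, lower.tail = FALSE),
       logLik_constrained = con$logLik)
}

# Symmetric pseudo-inverse with rank, for singular Wald covariances.
.pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  inv <- e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  list(inv = inv, rank = sum(pos))
}

#' Wald test of fixed effects
#'
#' Computes `W = theta' Var(theta)^-1 theta` for a subset of estimated fixed
#' effects, where Var(theta) is the corresponding submatrix of the inverse
#' coefficient matrix (the C11 block), and compares W to a chi-square with
#' df = number of tested effects. A singular Var(theta) is handled by a
#' generalized inverse with rank-adjusted df (with a warning).
#'
#' @param fit an [fit_multitrait()] result (or any list with `beta`,
#'   `vbeta`).
#' @param effects character names (or integer indices) of the effects to
#'   test jointly.
#' @return list of class `wald_result`: `theta_hat`, `var_theta`,
#'   `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, effects) {
  b <- fit$beta
  idx <- if (is.character(effects)) match(effects, names(b)) else effects
  if (anyNA(idx)) stop("unknown effect(s): ",
                       paste(effects[is.na(idx)], collapse = ", "))
  th <- b[idx]
  V <- fit$vbeta[idx, idx, drop = FALSE]
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) {
    warning("singular Var(theta): using generalized inverse")
    pi <- .pinv_sym(V)
    W <- drop(t(th) %*% pi$inv %*% th)
    df <- pi$rank
  } else {
    W <- drop(crossprod(forwardsolve(t(cv), th)))
    df <- length(th)
  }
  W <- max(0, W)
  structure(list(theta_hat = th, var_theta = V, statistic = W, df = df,
                 p_value = stats::pchisq(W, df, lower.tail = FALSE)),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald chi-square = %.4g, df = %d, p = %.4g\n", x$statistic,
              x$df, x$p_value))
  invisible(x)
}
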