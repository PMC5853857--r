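#' Stage-1 BLUEs: per-environment alpha-lattice analysis
#'
#' For one trait in one environment, fits the model
#' `value ~ genotype (fixed) + replicate (random) + block-in-replicate
#' (random) + error` by REML and returns the genotype BLUEs together with
#' the environment's residual (plot error) variance. Environments with a
#' single replicate bypass the model: the raw plot values are passed on as
#' BLUEs with `replicated = FALSE` and no error variance.
#'
#' @param plots plot-level [trait_dataset].
#' @param trait trait name.
#' @param environment environment id.
#' @return list with `blues` (named per-genotype vector), `sigma2_e`,
#'   `replicated`, `n_rep`.
#' @export
stage1_blues <- function(plots, trait, environment) {
  stopifnot(attr(plots, "stage") == "plot")
  df <- as.data.frame(plots)
  df <- df[df$trait == trait & df$environment == environment &
             !is.na(df$value), ]
  if (!nrow(df)) stop("no data for ", trait, " in ", environment)
  if (length(unique(df$genotype)) < 2) stop("need at least 2 genotypes")
  n_rep <- length(unique(df$replicate))
  if (n_rep == 1) {
    b <- stats::setNames(df$value, df$genotype)
    return(list(blues = b, sigma2_e = NA_real_, replicated = FALSE,
                n_rep = 1L))
  }
  df$genotype <- factor(df$genotype)
  df$replicate <- factor(df$replicate)
  df$blk <- factor(paste(df$replicate, df$block, sep = ":"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 0 + genotype + (1 | replicate) + (1 | blk),
               data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  b <- lme4::fixef(fit)
  names(b) <- sub("^genotype", "", names(b))
  miss <- setdiff(levels(df$genotype), names(b))
  if (length(miss)) message("unestimable genotype(s): ",
                            paste(miss, collapse = ", "))
  list(blues = b, sigma2_e = stats::sigma(fit)^2, replicated = TRUE,
       n_rep = n_rep)
}

#' Run stage 1 over every environment of a trait
#'
#' @inheritParams stage1_blues
#' @return list with `blues` (stage-1 [trait_dataset]), `sigma2_e` (named
#'   per environment), `n_rep` per environment.
#' @export
stage1_all <- function(plots, trait) {
  envs <- sort(unique(as.data.frame(plots)$environment[
    as.data.frame(plots)$trait == trait]))
  res <- lapply(envs, function(e) stage1_blues(plots, trait, e))
  names(res) <- envs
  tab <- do.call(rbind, lapply(envs, function(e)
    data.frame(genotype = names(res[[e]]$blues), environment = e,
               trait = trait, value = unname(res[[e]]$blues),
               stringsAsFactors = FALSE)))
  list(blues = trait_dataset(tab, stage = "stage1"),
       sigma2_e = vapply(res, `[[`, numeric(1), "sigma2_e"),
       n_rep = vapply(res, `[[`, integer(1), "n_rep"))
}

#' Stage-2 BLUEs and variance components
#'
#' Combines stage-1 per-environment BLUEs across environments with the
#' model `value ~ genotype (fixed) + environment (random) + error`, and
#' estimates variance components from the parallel random-genotype fit.
#' The stage-2 residual variance mixes genotype-by-environment interaction
#' with the carry-over error of the stage-1 means, so sigma2_GxE is
#' obtained by subtracting the average stage-1 error variance expressed on
#' the entry-mean basis (sigma2_e,j / n_rep,j, averaged over replicated
#' environments); a negative difference is floored at zero with a warning.
#' sigma2_Error (plot basis, for h2) is the plain average of the stage-1
#' residual variances of replicated environments.
#'
#' @param stage1 stage-1 [trait_dataset] (single trait).
#' @param trait trait name.
#' @param sigma2_e named per-environment stage-1 residual variances (as
#'   from [stage1_all()]); `NA` for unreplicated environments.
#' @param n_rep named per-environment replicate counts.
#' @return list with `blues` (stage-2 [trait_dataset]) and `vc` (class
#'   `variance_components`): sigma2_G, sigma2_GxE, sigma2_Error,
#'   sigma2_e_stage2, n_env, n_rep, h2_plot, h2_entry.
#' @export
stage2_blues <- function(stage1, trait, sigma2_e = NULL, n_rep = NULL) {
  stopifnot(attr(stage1, "stage") == "stage1")
  df <- as.data.frame(stage1)
  df <- df[df$trait == trait & !is.na(df$value), ]
  envs <- unique(df$environment)
  n_env <- length(envs)
  df$genotype <- factor(df$genotype)
  df$environment <- factor(df$environment)
  if (n_env < 2) {
    warning("single environment: sigma2_GxE undefined")
    b <- stats::setNames(df$value, as.character(df$genotype))
    vc <- .variance_components(NA, NA, mean(sigma2_e, na.rm = TRUE), NA,
                               1L, round(mean(n_rep)))
    tab <- data.frame(genotype = names(b), trait = trait, value = unname(b))
    return(list(blues = trait_dataset(tab, stage = "stage2"), vc = vc))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 0 + genotype + (1 | environment), data = df,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  b <- lme4::fixef(fit)
  names(b) <- sub("^genotype", "", names(b))
  rfit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ (1 | genotype) + (1 | environment), data = df,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vcs <- as.data.frame(lme4::VarCorr(rfit))
  s2G <- vcs$vcov[vcs$grp == "genotype"]
  s2e2 <- stats::sigma(rfit)^2
  rep_envs <- names(sigma2_e)[!is.na(sigma2_e)]
  s2Err <- if (length(rep_envs)) mean(sigma2_e[rep_envs]) else NA_real_
  blue_err <- if (length(rep_envs))
    mean(sigma2_e[rep_envs] / n_rep[rep_envs]) else 0
  s2GxE <- s2e2 - blue_err
  if (is.finite(s2GxE) && s2GxE < 0) {
    warning("negative GxE estimate floored at 0")
    s2GxE <- 0
  }
  nrep_eff <- if (length(rep_envs)) round(mean(n_rep[rep_envs])) else 1L
  vc <- .variance_components(s2G, s2GxE, s2Err, s2e2, n_env, nrep_eff)
  tab <- data.frame(genotype = names(b), trait = trait, value = unname(b),
                    stringsAsFactors = FALSE)
  list(blues = trait_dataset(tab, stage = "stage2"), vc = vc)
}

.variance_components <- function(s2G, s2GxE, s2Err, s2e2, n_env, n_rep) {
  h2 <- tryCatch(heritabilities(s2G, s2GxE, s2Err, n_env, n_rep),
                 error = function(e) list(h2_plot = NA_real_,
                                          h2_entry = NA_real_))
  structure(list(sigma2_G = s2G, sigma2_GxE = s2GxE, sigma2_Error = s2Err,
                 sigma2_e_stage2 = s2e2, n_env = n_env, n_rep = n_rep,
                 h2_plot = h2$h2_plot, h2_entry = h2$h2_entry),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "sigma2_G = %.4g, sigma2_GxE = %.4g, sigma2_Error = %.4g\n",
    x$sigma2_G, x$sigma2_GxE, x$sigma2_Error))
  cat(sprintf("h2_plot = %.3f, h2_entry = %.3f (%d env, %d rep)\n",
              x$h2_plot, x$h2_entry, x$n_env, x$n_rep))
  invisible(x)
}

#' Plot-basis and entry-mean heritabilities
#'
#' `h2_plot = s2G / (s2G + s2GxE + s2Error)` and
#' `h2_entry = s2G / (s2G + s2GxE / n_env + s2Error / (n_rep * n_env))`.
#'
#' @param s2G,s2GxE,s2Error variance components (>= 0).
#' @param n_env,n_rep numbers of environments and replicates.
#' @return list with `h2_plot` and `h2_entry`, both in \[0, 1\].
#' @examples
#' heritabilities(1, 1, 1, 2, 2)  # h2_plot = 1/3, h2_entry = 0.5714
#' @export
heritabilities <- function(s2G, s2GxE, s2Error, n_env, n_rep) {
  stopifnot(s2G >= 0, s2GxE >= 0, s2Error >= 0, n_env >= 1, n_rep >= 1)
  dplot <- s2G + s2GxE + s2Error
  dentry <- s2G + s2GxE / n_env + s2Error / (n_rep * n_env)
  if (dplot == 0) stop("all variance components are zero")
  list(h2_plot = s2G / dplot, h2_entry = s2G / dentry)
}

#' Run the complete two-stage analysis for one trait
#'
#' @inheritParams stage1_blues
#' @return list with `stage1` (per-environment BLUEs), `stage2`
#'   (across-environment BLUEs), `vc` (variance components).
#' @export
two_stage <- function(plots, trait) {
  s1 <- stage1_all(plots, trait)
  s2 <- stage2_blues(s1$blues, trait, sigma2_e = s1$sigma2_e,
                     n_rep = s1$n_rep)
  list(stage1 = s1$blues, stage2 = s2$blues, vc = s2$vc,
       sigma2_e_stage1 = s1$sigma2_e)
}

#' Phenotypic correlations among across-environment BLUEs
#'
#' Pearson product-moment correlations between genotype BLUEs of trait
#' pairs, with two-sided p-values from `t = r sqrt((n - 2) / (1 - r^2))` on
#' n - 2 df. Constant traits yield `NA` with a warning.
#'
#' @param blues stage-2 [trait_dataset] covering >= 2 traits.
#' @return list with matrices `r`, `p_value`, `n`.
#' @export
phenotypic_correlations <- function(blues) {
  stopifnot(attr(blues, "stage") == "stage2")
  df <- as.data.frame(blues)
  traits <- unique(df$trait)
  wide <- stats::reshape(df[, c("genotype", "trait", "value")],
                         idvar = "genotype", timevar = "trait",
                         direction = "wide")
  X <- as.matrix(wide[, -1, drop = FALSE])
  colnames(X) <- sub("^value\\.", "", colnames(X))
  X <- X[, traits, drop = FALSE]
  t_n <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, t_n, t_n,
                           dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(t_n)) for (j in seq_len(t_n)) {
    if (i >= j) next
    ok <- stats::complete.cases(X[, c(i, j)])
    n <- sum(ok)
    if (n < 3) next
    if (stats::var(X[ok, i]) == 0 || stats::var(X[ok, j]) == 0) {
      warning("constant trait: correlation undefined for ", traits[i],
              "-", traits[j])
      next
    }
    rij <- stats::cor(X[ok, i], X[ok, j])
    tstat <- rij * sqrt((n - 2) / (1 - rij^2))
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), n - 2)
    nmat[i, j] <- nmat[j, i] <- n
  }
  list(r = r, p_value = p, n = nmat)
}
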