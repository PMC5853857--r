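#' Bivariate genome-wide association scan
#'
#' Fits, for every polymorphic marker, the bivariate mixed model with fixed
#' trait-by-environment means, fixed marker main effects per trait, fixed
#' marker-by-environment interactions, random breeding values `G0 (x) A`
#' and errors `R0 (x) I` on stage-1 per-environment BLUEs, and performs the
#' Wald test hierarchy: a global test of the two marker main effects
#' (df 2), one individual test per trait (df 1), a global test of all
#' marker-by-environment interactions and one per trait. A marker is
#' declared potentially pleiotropic only when the global test passes the
#' chosen genome-wide correction and both individual tests pass the
#' post-hoc level.
#'
#' @param geno a [genotype_matrix].
#' @param phenos stage-1 [trait_dataset] with both traits.
#' @param A a [kinship_matrix] or relationship matrix.
#' @param trait_pair character vector of two trait names.
#' @param markers marker ids to scan (default: all polymorphic markers).
#' @param alpha genome-wide level for the global test.
#' @param posthoc_alpha nominal level of the two individual tests.
#' @param correction one of `"FDR"`, `"Bonferroni"`, `"Meff"` used for the
#'   `significant` flag (all three flags are returned).
#' @param M_eff effective number of independent markers (required for the
#'   Meff flag; see [m_eff_genome()]).
#' @param marker_by_env include marker-by-environment fixed effects.
#' @return data.frame of class `mtgwas_scan`, one row per tested marker:
#'   effects `alpha_1`, `alpha_2`, Wald statistics and p-values for the
#'   global, per-trait and interaction tests, BH q-values, per-correction
#'   significance flags, and `covariation_sign`.
#' @export
scan_bivariate <- function(geno, phenos, A, trait_pair, markers = NULL,
                           alpha = 0.05, posthoc_alpha = 0.05,
                           correction = c("FDR", "Bonferroni", "Meff"),
                           M_eff = NULL, marker_by_env = TRUE) {
  correction <- match.arg(correction)
  stopifnot(inherits(geno, "genotype_matrix"), length(trait_pair) == 2)
  if (is.null(markers)) markers <- colnames(geno$dosages)
  df <- as.data.frame(phenos)
  if (all(tapply(df$value, df$trait, stats::var, na.rm = TRUE) < 1e-12))
    stop("degenerate fit: phenotypes are constant")
  prep0 <- .mt_prepare_base(phenos, trait_pair, A, method = "REML")
  ids <- prep0$ids
  # null-model variance components warm-start every per-marker fit
  null_fit <- .mt_optim(.mt_design(prep0), trait_pair)
  rows <- vector("list", length(markers))
  for (mi in seq_along(markers)) {
    mvec <- geno$dosages[ids, markers[mi]]
    if (anyNA(mvec) || stats::var(mvec) == 0) {
      message("skipping monomorphic/missing marker ", markers[mi])
      next
    }
    mrot <- drop(crossprod(prep0$U, mvec))
    fit <- tryCatch(
      .mt_optim(.mt_design(prep0, markers = mrot, rotated = TRUE,
                           marker_by_env = marker_by_env),
                trait_pair, theta0 = null_fit$theta),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      message("fit failed for marker ", markers[mi])
      next
    }
    an <- sprintf("alpha[%s]", trait_pair)
    wg <- wald_test(fit, an)
    w1 <- wald_test(fit, an[1])
    w2 <- wald_test(fit, an[2])
    inames <- grep("^alphaE\\[", names(fit$beta), value = TRUE)
    wie <- wi1 <- wi2 <- NULL
    if (length(inames)) {
      wie <- wald_test(fit, inames)
      i1 <- grep(sprintf("^alphaE\\[%s:", trait_pair[1]), names(fit$beta),
                 value = TRUE)
      i2 <- grep(sprintf("^alphaE\\[%s:", trait_pair[2]), names(fit$beta),
                 value = TRUE)
      if (length(i1)) wi1 <- wald_test(fit, i1)
      if (length(i2)) wi2 <- wald_test(fit, i2)
    }
    rows[[mi]] <- data.frame(
      marker = markers[mi],
      alpha_1 = unname(fit$beta[an[1]]), alpha_2 = unname(fit$beta[an[2]]),
      wald_global = wg$statistic, p_global = wg$p_value,
      wald_1 = w1$statistic, p_1 = w1$p_value,
      wald_2 = w2$statistic, p_2 = w2$p_value,
      wald_mxe = if (is.null(wie)) NA_real_ else wie$statistic,
      p_mxe = if (is.null(wie)) NA_real_ else wie$p_value,
      p_mxe_1 = if (is.null(wi1)) NA_real_ else wi1$p_value,
      p_mxe_2 = if (is.null(wi2)) NA_real_ else wi2$p_value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable markers")
  m <- nrow(res)
  res$q_fdr <- correct_multiplicity(res$p_global, method = "FDR")
  bonf_thr <- correct_multiplicity(res$p_global, method = "Bonferroni",
                                   alpha = alpha)
  posthoc_ok <- res$p_1 < posthoc_alpha & res$p_2 < posthoc_alpha
  res$sig_fdr <- res$q_fdr < alpha & posthoc_ok
  res$sig_bonferroni <- res$p_global < bonf_thr & posthoc_ok
  if (!is.null(M_eff)) {
    meff_thr <- correct_multiplicity(res$p_global, method = "Meff",
                                     alpha = alpha, M_eff = M_eff)
    res$sig_meff <- res$p_global < meff_thr & posthoc_ok
  } else res$sig_meff <- NA
  res$significant <- switch(correction, FDR = res$sig_fdr,
                            Bonferroni = res$sig_bonferroni,
                            Meff = res$sig_meff)
  res$covariation_sign <- ifelse(res$alpha_1 * res$alpha_2 >= 0, "+", "-")
  attr(res, "trait_pair") <- trait_pair
  class(res) <- c("mtgwas_scan", "data.frame")
  res
}

#' Multiple-testing corrections for association scans
#'
#' `FDR` returns Benjamini-Hochberg step-up q-values; `Bonferroni` and
#' `Meff` return the per-test significance threshold `alpha / m` and
#' `alpha / M_eff` respectively (Meff replaces the raw marker count by the
#' effective number of independent markers).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param method `"FDR"`, `"Bonferroni"` or `"Meff"`.
#' @param alpha nominal level (threshold methods).
#' @param M_eff effective number of independent markers (Meff method).
#' @return q-values (FDR) or a single threshold (Bonferroni/Meff).
#' @examples
#' correct_multiplicity(c(0.01, 0.02, 0.03, 0.04), "FDR")  # all 0.04
#' @export
correct_multiplicity <- function(p_values, method = c("FDR", "Bonferroni",
                                                      "Meff"),
                                 alpha = 0.05, M_eff = NULL) {
  method <- match.arg(method)
  if (!length(p_values)) stop("empty p-value vector")
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  switch(method,
         FDR = stats::p.adjust(p_values, method = "BH"),
         Bonferroni = alpha / length(p_values),
         Meff = {
           if (is.null(M_eff)) stop("M_eff required for the Meff method")
           alpha / M_eff
         })
}

#' Effective number of bivariate associations
#'
#' Applies the eigenvalue principle of [m_eff()] to the r^2 matrix of the
#' significant markers of a trait pair: markers in strong mutual LD
#' collapse into one effective association.
#'
#' @param markers ids of the significant markers (>= 1).
#' @param geno a [genotype_matrix].
#' @param variance_threshold passed to [m_eff()].
#' @return integer count.
#' @export
effective_association_count <- function(markers, geno,
                                        variance_threshold = 0.95) {
  stopifnot(length(markers) >= 1)
  if (length(markers) == 1) return(1L)
  M <- geno$dosages[, markers, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  m_eff(r2, variance_threshold)
}

#' Sequential variance partition over significant markers
#'
#' Fits, per trait, a multiple regression of the across-environment BLUEs
#' on the significant markers in the given order (lowest global Wald
#' p-value first) and reports sequential (Type-I) R-squared per marker,
#' cumulative totals, and the genetic-variance share R^2 / h2_entry.
#'
#' @param blues stage-2 [trait_dataset].
#' @param geno a [genotype_matrix].
#' @param markers marker ids, ordered by entry priority.
#' @param traits trait names to partition.
#' @param h2_entry named per-trait entry-mean heritabilities (> 0).
#' @return data.frame with columns `marker`, `trait`, `R2`, `R2_cum`,
#'   `genetic_share`, `genetic_share_cum`.
#' @export
variance_partition <- function(blues, geno, markers, traits, h2_entry) {
  stopifnot(attr(blues, "stage") == "stage2", all(h2_entry > 0))
  df <- as.data.frame(blues)
  out <- list()
  for (tr in traits) {
    sub <- df[df$trait == tr & !is.na(df$value), ]
    ids <- intersect(sub$genotype, rownames(geno$dosages))
    y <- sub$value[match(ids, sub$genotype)]
    X <- geno$dosages[ids, markers, drop = FALSE]
    tss <- sum((y - mean(y))^2)
    dat <- data.frame(y = y, X, check.names = FALSE)
    fml <- stats::as.formula(paste("y ~", paste0("`", markers, "`",
                                                 collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    an <- stats::anova(fit)
    ss <- an[markers2 <- rownames(an)[rownames(an) != "Residuals"], "Sum Sq"]
    names(ss) <- gsub("`", "", markers2)
    ss[is.na(ss)] <- 0
    aliased <- setdiff(markers, names(ss))
    if (length(aliased)) {
      warning("collinear marker(s) add zero R^2: ",
              paste(aliased, collapse = ", "))
      ss[aliased] <- 0
    }
    ss <- ss[markers]
    r2 <- ss / tss
    h2 <- h2_entry[[tr]]
    out[[tr]] <- data.frame(marker = markers, trait = tr, R2 = unname(r2),
                            R2_cum = cumsum(unname(r2)),
                            genetic_share = unname(r2) / h2,
                            genetic_share_cum = cumsum(unname(r2)) / h2,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Higher-order (three-trait) association test
#'
#' Extends the bivariate association model to three traits for markers
#' already significant in more than one trait pair. The marker is declared
#' simultaneously associated with all three traits only if every per-trait
#' Wald test passes the corrected level (`alpha / M_eff` or Bonferroni
#' `alpha / n_markers`).
#'
#' @param geno a [genotype_matrix].
#' @param phenos stage-1 [trait_dataset] with the three traits.
#' @param A relationship matrix.
#' @param marker marker id.
#' @param traits character vector of three trait names.
#' @param alpha nominal level before correction (default 0.1).
#' @param M_eff effective number of independent markers; if `NULL`,
#'   `n_markers` must be given for a Bonferroni correction.
#' @param n_markers raw marker count (Bonferroni fallback).
#' @param marker_by_env include marker-by-environment effects.
#' @return list with the fitted effects, per-trait Wald results, the
#'   corrected threshold and `declared` (logical).
#' @export
higher_order_test <- function(geno, phenos, A, marker, traits, alpha = 0.1,
                              M_eff = NULL, n_markers = NULL,
                              marker_by_env = TRUE) {
  stopifnot(length(traits) == 3)
  thr <- if (!is.null(M_eff)) alpha / M_eff
  else if (!is.null(n_markers)) alpha / n_markers
  else stop("provide M_eff or n_markers")
  prep0 <- .mt_prepare(phenos, traits, A, markers = NULL, method = "REML")
  mvec <- geno$dosages[prep0$ids, marker]
  fit <- fit_multitrait(phenos, traits, A, markers = mvec,
                        marker_by_env = marker_by_env, method = "REML")
  if (!fit$converged) stop("three-trait covariance fit did not converge")
  an <- sprintf("alpha[%s]", traits)
  wt <- lapply(an, function(a) wald_test(fit, a))
  names(wt) <- traits
  pvals <- vapply(wt, `[[`, numeric(1), "p_value")
  list(marker = marker, traits = traits,
       effects = stats::setNames(fit$beta[an], traits), wald = wt,
       p_values = pvals, threshold = thr,
       declared = all(pvals < thr), fit = fit)
}

#' Environmental-stability ratio of marker effects
#'
#' Univariate multiple regression of per-environment BLUEs on environment
#' main effects, marker main effects, and marker-by-environment
#' interactions (entered sequentially in that order). The ratio of the
#' variance explained by marker main effects to that explained by the
#' interactions measures how stable the marker effects are across
#' environments.
#'
#' @param blues stage-1 [trait_dataset] for one trait.
#' @param geno a [genotype_matrix].
#' @param markers significant marker ids.
#' @param trait trait name.
#' @return list with `ratio` (+Inf when the interaction term explains
#'   nothing, flagged), `ss_markers`, `ss_interaction`, `flag`.
#' @export
stability_ratio <- function(blues, geno, markers, trait) {
  stopifnot(attr(blues, "stage") == "stage1")
  df <- as.data.frame(blues)
  df <- df[df$trait == trait & !is.na(df$value), ]
  if (length(unique(df$environment)) < 2)
    stop("need at least 2 environments")
  ids <- intersect(df$genotype, rownames(geno$dosages))
  df <- df[df$genotype %in% ids, ]
  X <- geno$dosages[df$genotype, markers, drop = FALSE]
  colnames(X) <- paste0("mk", seq_along(markers))
  dat <- data.frame(y = df$value, env = factor(df$environment), X)
  mks <- colnames(X)
  fml <- stats::as.formula(paste(
    "y ~ env +", paste(mks, collapse = " + "), "+",
    paste(paste0("env:", mks), collapse = " + ")))
  an <- suppressWarnings(stats::anova(stats::lm(fml, data = dat)))
  ss_m <- sum(an[mks, "Sum Sq"], na.rm = TRUE)
  ss_i <- sum(an[paste0("env:", mks), "Sum Sq"], na.rm = TRUE)
  flag <- NULL
  tot <- sum(an[, "Sum Sq"], na.rm = TRUE)
  if (!is.finite(tot) || tot < 1e-10 ||
      (ss_m / tot < 1e-8 && ss_i / tot < 1e-8)) {
    flag <- "no marker-related variance: ratio undefined"
    warning(flag)
    return(list(ratio = NA_real_, ss_markers = ss_m, ss_interaction = ss_i,
                flag = flag))
  }
  if (ss_i / tot < 1e-12) {
    flag <- "zero interaction variance: ratio infinite"
    warning(flag)
    return(list(ratio = Inf, ss_markers = ss_m, ss_interaction = ss_i,
                flag = flag))
  }
  list(ratio = ss_m / ss_i, ss_markers = ss_m, ss_interaction = ss_i,
       flag = flag)
}
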