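#' Additive effect for a target QTL size
#'
#' Scales an additive allele-substitution effect so that the QTL explains
#' `pct` percent of the trait's total genetic variance: for inbred 0/2
#' coding the dosage variance is `4 p (1 - p)`, so
#' `alpha = sqrt(pct/100 * total_genetic_variance / (4 p (1 - p)))`.
#'
#' @param pct QTL size, percent of genetic variance in (0, 100\].
#' @param maf minor allele frequency in (0, 0.5\].
#' @param total_genetic_variance trait genetic variance.
#' @return additive effect per dosage unit.
#' @examples
#' effect_size_from_variance(100, 0.5, 1)  # 1
#' @export
effect_size_from_variance <- function(pct, maf, total_genetic_variance = 1) {
  stopifnot(pct >= 0, pct <= 100, maf > 0, maf <= 0.5,
            total_genetic_variance >= 0)
  sqrt(pct / 100 * total_genetic_variance / (4 * maf * (1 - maf)))
}

#' Trait configuration of the simulation study
#'
#' Variance magnitudes of the two simulated traits: total genetic variance
#' 1 per trait (the polygenic share is reduced by the simulated QTL sizes)
#' and a residual set so the trait's heritability matches the plot-basis
#' heritability of a moderately heritable yield trait (~0.44) and of a
#' more heritable syndrome trait (~0.60):
#' `resid = var_G (1 - h2) / h2`. Background genetic and residual
#' correlations are zero: the traits are linked only through the simulated
#' QTL(s).
#'
#' @param var_G total genetic variances (length 2).
#' @param h2_plot per-trait heritabilities fixing the signal-to-noise of
#'   the simulated data.
#' @return list used by [run_scenario()].
#' @export
powersim_traits <- function(var_G = c(1, 1), h2_plot = c(0.44, 0.60)) {
  stopifnot(all(h2_plot > 0 & h2_plot <= 1), length(var_G) == 2)
  list(var_G = var_G, resid = var_G * (1 - h2_plot) / h2_plot,
       h2_plot = h2_plot)
}

#' One cell of the power / Type I error simulation
#'
#' Per replicate: a causal configuration is drawn -- in `pleiotropy` mode
#' one marker at the requested MAF affecting both traits, with two linked
#' window markers engineered at r^2 ~0.70 and ~0.55 around it; in
#' `linkage` mode a marker pair at the requested MAF and r^2, the first
#' affecting trait 1 and the second trait 2. Effects are scaled so each
#' QTL explains `qtl_size_pct` percent of its trait's genetic variance;
#' polygenic values with covariance proportional to A (share reduced by
#' the QTL) and BLUE-level residual noise are added. The two-dimensional
#' ML scan is then run on the candidate positions and a rejection of
#' pleiotropy at `alpha` recorded.
#'
#' @param mode `"pleiotropy"` or `"linkage"`.
#' @param maf minor allele frequency of the causal marker(s).
#' @param qtl_size_pct percent of genetic variance per trait QTL.
#' @param r2 r^2 between the two causal positions (linkage mode).
#' @param A_eig list with `d`, `U` (eigen of the panel kinship) -- see
#'   [run_grid()]; alternatively a [kinship_matrix].
#' @param traits a [powersim_traits()] configuration.
#' @param n_replicates simulation replicates.
#' @param seed integer seed.
#' @param alpha nominal level of the chi-square(1) LR test.
#' @param fast passed to the grid fits (profile approximation).
#' @param window_r2 neighbour r^2 levels of the pleiotropy-mode window.
#' @return list with `rejections`, `n_done`, `proportion`, `se`
#'   (binomial), `n_failed`.
#' @export
run_scenario <- function(mode = c("pleiotropy", "linkage"), maf,
                         qtl_size_pct, r2 = NULL, A_eig, traits =
                           powersim_traits(), n_replicates = 100, seed = 1,
                         alpha = 0.05, fast = FALSE,
                         window_r2 = c(0.70, 0.55)) {
  mode <- match.arg(mode)
  if (mode == "linkage") {
    stopifnot(!is.null(r2))
    bound <- r2_max(maf, maf)
    if (r2 > bound$r2_max + 1e-9)
      stop(sprintf("infeasible cell: r^2 %.3g > max %.3g", r2,
                   bound$r2_max))
  }
  if (inherits(A_eig, "kinship_matrix")) {
    ea <- eigen((A_eig$A + t(A_eig$A)) / 2, symmetric = TRUE)
    A_eig <- list(d = pmax(ea$values, 0), U = ea$vectors)
  }
  d <- A_eig$d; U <- A_eig$U
  n <- length(d)
  urot <- drop(crossprod(U, rep(1, n)))
  # scale polygenic draws so their expected sample variance is var_G:
  # E[sample var] = sigma^2 (tr(A) - 1'A1/n) / (n - 1)
  adiag <- (sum(d) - sum(d * urot^2) / n) / (n - 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  rej <- logical(0)
  fails <- 0
  for (r_i in seq_len(n_replicates)) {
    res <- tryCatch(
      .powersim_one(mode, maf, qtl_size_pct, r2, d, U, urot, adiag, n,
                    traits, rep_seeds[r_i], alpha, fast, window_r2),
      error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1 else rej <- c(rej, res)
  }
  if (fails > 0.2 * n_replicates)
    warning(sprintf("cell unreliable: %d/%d replicates failed", fails,
                    n_replicates))
  prop <- mean(rej)
  list(rejections = sum(rej), n_done = length(rej), proportion = prop,
       se = sqrt(prop * (1 - prop) / max(length(rej), 1)),
       n_failed = fails)
}

.powersim_one <- function(mode, maf, pct, r2, d, U, urot, adiag, n, traits,
                          seed, alpha, fast, window_r2) {
  if (mode == "linkage") {
    pr <- simulate_marker_pair(maf, maf, r2, n, seed = seed)
    mks <- cbind(pr$m1, pr$m2)
    eff1 <- c(effect_size_from_variance(pct, pr$maf1, traits$var_G[1]), 0)
    eff2 <- c(0, effect_size_from_variance(pct, pr$maf2, traits$var_G[2]))
    target_idx <- 1L
  } else {
    set.seed(seed)
    base_seed <- sample.int(.Machine$integer.max - 1, 3)
    pr <- simulate_marker_pair(maf, maf, 1, n, seed = base_seed[1])
    m0 <- pr$m1
    nb <- lapply(seq_along(window_r2), function(i)
      simulate_linked_marker(m0, maf, window_r2[i], seed = base_seed[1 + i]))
    mks <- cbind(m0, do.call(cbind, nb))
    f0 <- mean(m0) / 2
    a1 <- effect_size_from_variance(pct, min(f0, 1 - f0), traits$var_G[1])
    a2 <- effect_size_from_variance(pct, min(f0, 1 - f0), traits$var_G[2])
    eff1 <- c(a1, rep(0, length(window_r2)))
    eff2 <- c(a2, rep(0, length(window_r2)))
    target_idx <- 1L
  }
  set.seed(seed + 1)
  poly_var <- traits$var_G * (1 - pct / 100)
  g1 <- U %*% (sqrt(d * poly_var[1] / adiag) * stats::rnorm(n))
  g2 <- U %*% (sqrt(d * poly_var[2] / adiag) * stats::rnorm(n))
  y1 <- drop(mks %*% eff1 + g1 + stats::rnorm(n, sd = sqrt(traits$resid[1])))
  y2 <- drop(mks %*% eff2 + g2 + stats::rnorm(n, sd = sqrt(traits$resid[2])))
  cand <- paste0("S", seq_len(ncol(mks)))
  Mrot <- crossprod(U, mks)
  colnames(Mrot) <- cand
  res <- .scan_2d_core(cand, cand[target_idx], Mrot, urot,
                       drop(crossprod(U, y1)), drop(crossprod(U, y2)), d,
                       alpha, fast = fast)
  res$p_value < alpha
}

#' Scenario grid of the simulation study
#'
#' @param maf_levels minor allele frequencies (defaults ~0.06, 0.13, 0.22,
#'   0.46).
#' @param qtl_sizes_pct QTL sizes in percent of genetic variance.
#' @param r2_levels r^2 between causal positions (linkage mode only).
#' @param mode `"linkage"` or `"pleiotropy"`.
#' @param n_replicates replicates per cell.
#' @param seed integer seed.
#' @return list of class `scenario_grid`.
#' @export
scenario_grid <- function(maf_levels = c(0.06, 0.13, 0.22, 0.46),
                          qtl_sizes_pct = c(5, 10, 15),
                          r2_levels = c(0.55, 0.70, 0.91),
                          mode = c("linkage", "pleiotropy"),
                          n_replicates = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(qtl_sizes_pct > 0 & qtl_sizes_pct < 100),
            all(maf_levels > 0 & maf_levels <= 0.5))
  if (mode == "linkage")
    for (p in maf_levels) for (r in r2_levels)
      if (r > r2_max(p, p)$r2_max + 1e-9)
        stop(sprintf("r^2 = %.3g infeasible at MAF %.3g", r, p))
  structure(list(maf_levels = maf_levels, qtl_sizes_pct = qtl_sizes_pct,
                 r2_levels = if (mode == "linkage") r2_levels else NA,
                 mode = mode, n_replicates = n_replicates, seed = seed),
            class = "scenario_grid")
}

#' Run a full simulation grid
#'
#' Evaluates [run_scenario()] on every cell of the grid with independent
#' sub-seeds derived from the grid seed; fully reproducible from
#' `(grid, panel seed)`.
#'
#' @param grid a [scenario_grid()].
#' @param A_eig kinship eigen-structure (or [kinship_matrix]); by default a
#'   synthetic panel of 372 inbreds is generated from `panel_spec`.
#' @param traits a [powersim_traits()] configuration.
#' @param panel_spec [sim_population_spec()] used when `A_eig` is missing.
#' @param alpha nominal test level.
#' @param fast profile approximation in the grid fits.
#' @param verbose print per-cell progress.
#' @return list of class `power_table`: `cells` (data.frame with maf,
#'   qtl_size_pct, r2, proportion, se, n), `mode`, and for pleiotropy mode
#'   `grand_mean` and `sd` of the cell-level Type I errors.
#' @export
run_grid <- function(grid, A_eig = NULL, traits = powersim_traits(),
                     panel_spec = NULL, alpha = 0.05, fast = FALSE,
                     verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (is.null(A_eig)) {
    if (is.null(panel_spec))
      panel_spec <- sim_population_spec(n_genotypes = 372,
                                        n_markers_per_chrom = 40,
                                        n_chromosomes = 21,
                                        seed = grid$seed + 101)
    geno <- simulate_genotypes(panel_spec)
    A_eig <- kinship_matrix(geno)
  }
  if (inherits(A_eig, "kinship_matrix")) {
    ea <- eigen((A_eig$A + t(A_eig$A)) / 2, symmetric = TRUE)
    A_eig <- list(d = pmax(ea$values, 0), U = ea$vectors)
  }
  cells <- if (grid$mode == "linkage")
    expand.grid(maf = grid$maf_levels, qtl_size_pct = grid$qtl_sizes_pct,
                r2 = grid$r2_levels)
  else expand.grid(maf = grid$maf_levels,
                   qtl_size_pct = grid$qtl_sizes_pct, r2 = NA_real_)
  set.seed(grid$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1, nrow(cells))
  cells$proportion <- cells$se <- cells$n <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    res <- run_scenario(mode = grid$mode, maf = cells$maf[ci],
                        qtl_size_pct = cells$qtl_size_pct[ci],
                        r2 = if (grid$mode == "linkage") cells$r2[ci],
                        A_eig = A_eig, traits = traits,
                        n_replicates = grid$n_replicates,
                        seed = cell_seeds[ci], alpha = alpha, fast = fast)
    cells$proportion[ci] <- res$proportion
    cells$se[ci] <- res$se
    cells$n[ci] <- res$n_done
    if (verbose)
      message(sprintf("cell %d/%d (maf %.2f, size %g, r2 %s): %.2f",
                      ci, nrow(cells), cells$maf[ci],
                      cells$qtl_size_pct[ci],
                      format(cells$r2[ci]), res$proportion))
  }
  out <- list(cells = cells, mode = grid$mode,
              n_replicates = grid$n_replicates)
  if (grid$mode == "pleiotropy") {
    out$grand_mean <- mean(cells$proportion)
    out$sd <- stats::sd(cells$proportion)
  }
  class(out) <- "power_table"
  out
}

#' @export
print.power_table <- function(x, ...) {
  cat("power_table (", x$mode, " mode, ", x$n_replicates,
      " replicates/cell)\n", sep = "")
  print(power_table_layout(x))
  if (!is.null(x$grand_mean))
    cat(sprintf("grand mean Type I error = %.3f (SD %.3f)\n",
                x$grand_mean, x$sd))
  invisible(x)
}

#' Rejection proportions in the classical table layout
#'
#' MAF rows x QTL-size sub-rows, with one column per r^2 level (linkage
#' mode) or a single proportion column (pleiotropy mode).
#'
#' @param x a `power_table` from [run_grid()].
#' @return data.frame.
#' @export
power_table_layout <- function(x) {
  cells <- x$cells
  if (x$mode == "pleiotropy") {
    out <- cells[order(cells$maf, -cells$qtl_size_pct),
                 c("maf", "qtl_size_pct", "proportion", "se")]
    rownames(out) <- NULL
    return(out)
  }
  r2s <- sort(unique(cells$r2))
  base <- unique(cells[, c("maf", "qtl_size_pct")])
  base <- base[order(base$maf, -base$qtl_size_pct), ]
  for (r in r2s)
    base[[sprintf("r2_%.2f", r)]] <- cells$proportion[
      match(paste(base$maf, base$qtl_size_pct, r),
            paste(cells$maf, cells$qtl_size_pct, cells$r2))]
  rownames(base) <- NULL
  base
}
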