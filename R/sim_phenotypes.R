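#' Specification of simulated multi-environment trait data
#'
#' Variance components and QTL effects for [simulate_phenotypes()]. `var_G`
#' is the polygenic genetic variance per trait; QTL effects listed in
#' `qtl_effects` add their own variance on top, so the total genetic
#' variance of a trait is `var_G + sum of QTL variances`. The polygenic
#' values are drawn with covariance `G0 x A` where
#' `G0 = diag(sqrt(var_G)) %*% genetic_corr %*% diag(sqrt(var_G))` divided
#' by the variance-effective norm of A, `(tr(A) - sum(A)/n) / (n - 1)`, so
#' the expected sample variance of the polygenic values among lines equals
#' `var_G` even for panels with a high relatedness baseline.
#'
#' @param trait_names character vector.
#' @param var_G,var_GxE,var_Error per-trait variances (recycled).
#' @param genetic_corr trait x trait correlation matrix of the polygenic
#'   values (symmetric, unit diagonal, positive semidefinite).
#' @param n_environments,n_replicates design counts.
#' @param qtl_effects data.frame with columns `marker`, `trait`, `effect`
#'   (additive effect per dosage unit); may be `NULL`.
#' @param var_rep,var_block variances of the random replicate and
#'   incomplete-block effects (default a quarter of `var_Error`).
#' @param block_size plots per incomplete block within a replicate.
#' @param means per-trait intercepts.
#' @return list of class `sim_trait_spec`.
#' @export
sim_trait_spec <- function(trait_names, var_G = 1, var_GxE = 0.5,
                           var_Error = 1, genetic_corr = NULL,
                           n_environments = 2, n_replicates = 2,
                           qtl_effects = NULL, var_rep = NULL,
                           var_block = NULL, block_size = 10, means = 0) {
  t <- length(trait_names)
  var_G <- rep_len(var_G, t); var_GxE <- rep_len(var_GxE, t)
  var_Error <- rep_len(var_Error, t); means <- rep_len(means, t)
  if (is.null(genetic_corr)) genetic_corr <- diag(t)
  genetic_corr <- as.matrix(genetic_corr)
  stopifnot(nrow(genetic_corr) == t, ncol(genetic_corr) == t,
            isSymmetric(unname(genetic_corr), tol = 1e-8),
            all(abs(diag(genetic_corr) - 1) < 1e-8),
            all(var_G >= 0), all(var_GxE >= 0), all(var_Error >= 0),
            n_environments >= 1, n_replicates >= 1)
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("genetic_corr is not positive semidefinite")
  if (is.null(var_rep)) var_rep <- var_Error / 4
  if (is.null(var_block)) var_block <- var_Error / 4
  var_rep <- rep_len(var_rep, t); var_block <- rep_len(var_block, t)
  if (!is.null(qtl_effects))
    stopifnot(all(c("marker", "trait", "effect") %in% names(qtl_effects)),
              all(qtl_effects$trait %in% trait_names))
  structure(list(trait_names = trait_names, var_G = var_G,
                 var_GxE = var_GxE, var_Error = var_Error,
                 genetic_corr = genetic_corr,
                 n_environments = n_environments,
                 n_replicates = n_replicates, qtl_effects = qtl_effects,
                 var_rep = var_rep, var_block = var_block,
                 block_size = block_size, means = means),
            class = "sim_trait_spec")
}

#' Simulate plot-level alpha-lattice phenotypes
#'
#' Generates plot records `genotype x environment x replicate` for each
#' trait: polygenic breeding values with covariance `G0 x A`, additive QTL
#' contributions `effect * dosage`, iid genotype-by-environment deviations,
#' random replicate effects, random incomplete-block effects (blocks of
#' `block_size` plots nested in replicates), and plot error.
#'
#' @param geno a [genotype_matrix] (used for QTL dosages and ids).
#' @param A a [kinship_matrix] or an n x n relationship matrix.
#' @param spec a [sim_trait_spec].
#' @param seed integer seed.
#' @return a plot-level [trait_dataset]; attribute `true_values` holds the
#'   simulated total genetic values (n x traits).
#' @export
simulate_phenotypes <- function(geno, A, spec, seed = 1) {
  stopifnot(inherits(spec, "sim_trait_spec"))
  Amat <- if (inherits(A, "kinship_matrix")) A$A else as.matrix(A)
  ids <- rownames(geno$dosages)
  n <- length(ids)
  stopifnot(nrow(Amat) == n)
  t <- length(spec$trait_names)
  set.seed(seed)

  # polygenic values: vec(g) ~ N(0, G0 (x) A), with G0 scaled so that the
  # expected sample variance of g among lines equals var_G (the baseline
  # relatedness of a variety panel would otherwise deflate it)
  norm_A <- (sum(diag(Amat)) - sum(Amat) / n) / (n - 1)
  sdG <- sqrt(spec$var_G)
  G0 <- diag(sdG, t) %*% spec$genetic_corr %*% diag(sdG, t) / norm_A
  ec <- eigen(spec$genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (t > 1 && min(ec) < 1e-10)
    stop("singular genetic_corr: polygenic covariance not identifiable")
  eg <- eigen(G0, symmetric = TRUE)
  LG <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t)
  ea <- eigen(Amat, symmetric = TRUE)
  LA <- ea$vectors %*% diag(sqrt(pmax(ea$values, 0)), n)
  g <- LA %*% matrix(stats::rnorm(n * t), n, t) %*% t(LG)

  # QTL contributions
  qtl <- matrix(0, n, t)
  if (!is.null(spec$qtl_effects)) {
    qe <- spec$qtl_effects
    if (!all(qe$marker %in% colnames(geno$dosages)))
      stop("qtl_effects reference unknown markers")
    for (r in seq_len(nrow(qe))) {
      k <- match(qe$trait[r], spec$trait_names)
      qtl[, k] <- qtl[, k] + qe$effect[r] * geno$dosages[, qe$marker[r]]
    }
  }
  total_gen <- g + qtl

  J <- spec$n_environments; R <- spec$n_replicates
  envs <- sprintf("E%02d", seq_len(J))
  out <- vector("list", t * J * R)
  idx <- 0
  for (k in seq_len(t)) {
    ge <- matrix(stats::rnorm(n * J, sd = sqrt(spec$var_GxE[k])), n, J)
    for (j in seq_len(J)) {
      for (r in seq_len(R)) {
        rep_eff <- stats::rnorm(1, sd = sqrt(spec$var_rep[k]))
        ord <- sample.int(n)
        blk <- integer(n)
        blk[ord] <- (seq_len(n) - 1) %/% spec$block_size + 1
        nblk <- max(blk)
        blk_eff <- stats::rnorm(nblk, sd = sqrt(spec$var_block[k]))
        err <- stats::rnorm(n, sd = sqrt(spec$var_Error[k]))
        idx <- idx + 1
        out[[idx]] <- data.frame(
          genotype = ids, environment = envs[j], replicate = r,
          block = sprintf("B%02d", blk), trait = spec$trait_names[k],
          value = spec$means[k] + total_gen[, k] + ge[, j] + rep_eff +
            blk_eff[blk] + err,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- trait_dataset(do.call(rbind, out), stage = "plot")
  dimnames(total_gen) <- list(ids, spec$trait_names)
  attr(res, "true_values") <- total_gen
  res
}
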