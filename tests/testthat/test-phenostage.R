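make_plots <- function(n = 80, n_env = 2, n_rep = 2, var_G = 1,
                       var_GxE = 0.3, var_Error = 0.5, var_rep = 0.2,
                       var_block = 0.2, seed = 1, panel_seed = 23) {
  pn <- small_panel(n = n, seed = panel_seed)
  ts <- sim_trait_spec("T1", var_G = var_G, var_GxE = var_GxE,
                       var_Error = var_Error, n_environments = n_env,
                       n_replicates = n_rep, var_rep = var_rep,
                       var_block = var_block)
  ph <- simulate_phenotypes(pn$geno, pn$K, ts, seed = seed)
  list(plots = ph, truth = attr(ph, "true_values"))
}

test_that("BLUEs equal genotype means when design variances vanish", {
  fx <- make_plots(var_rep = 0, var_block = 0, var_Error = 0.4)
  s1 <- stage1_blues(fx$plots, "T1", "E01")
  df <- as.data.frame(fx$plots)
  df <- df[df$environment == "E01", ]
  means <- c(tapply(df$value, df$genotype, mean))
  expect_equal(s1$blues[names(means)], means, tolerance = 0.02)
})

test_that("a constant added to one replicate leaves BLUE contrasts intact", {
  fx <- make_plots()
  df <- as.data.frame(fx$plots)
  df2 <- df
  sel <- df2$environment == "E01" & df2$replicate == 2
  df2$value[sel] <- df2$value[sel] + 50
  b1 <- stage1_blues(fx$plots, "T1", "E01")$blues
  b2 <- stage1_blues(trait_dataset(df2, "plot"), "T1", "E01")$blues
  shift <- b2[names(b1)] - b1
  expect_lt(stats::sd(shift), 0.01)  # uniform shift, contrasts preserved
  expect_gt(mean(shift), 1)         # the constant itself is partly carried
})

test_that("stage-1 BLUEs agree with a generalized-least-squares oracle", {
  fx <- make_plots(n = 60, var_rep = 0.3, var_block = 0.4, var_Error = 0.5)
  df <- as.data.frame(fx$plots)
  df <- df[df$environment == "E01", ]
  ours <- stage1_blues(fx$plots, "T1", "E01")$blues
  # oracle: GLS with the true variance components
  gf <- factor(df$genotype); rf <- factor(df$replicate)
  bf <- factor(paste(df$replicate, df$block))
  X <- stats::model.matrix(~ 0 + gf)
  Zr <- stats::model.matrix(~ 0 + rf)
  Zb <- stats::model.matrix(~ 0 + bf)
  V <- 0.3 * tcrossprod(Zr) + 0.4 * tcrossprod(Zb) + 0.5 * diag(nrow(df))
  Vi <- solve(V)
  gls <- drop(solve(crossprod(X, Vi %*% X),
                    crossprod(X, Vi %*% df$value)))
  names(gls) <- sub("^gf", "", colnames(X))
  expect_equal(ours[names(gls)], gls, tolerance = 0.05)
  # and the BLUEs track the simulated true genotype values
  se <- sqrt(mean(diag(solve(crossprod(X, Vi %*% X)))))
  truth <- fx$truth[names(gls), "T1"]
  covered <- mean(abs(ours[names(gls)] - mean(ours) -
                        (truth - mean(truth))) < 2 * se)
  expect_gte(covered, 0.85)
})

test_that("single-replicate environments bypass to raw values", {
  fx <- make_plots()
  df <- as.data.frame(fx$plots)
  df <- df[!(df$environment == "E02" & df$replicate == 2), ]
  s1 <- stage1_blues(trait_dataset(df, "plot"), "T1", "E02")
  expect_false(s1$replicated)
  expect_equal(unname(s1$blues),
               df$value[df$environment == "E02"])
})

test_that("balanced stage-2 BLUEs are the means of stage-1 BLUEs", {
  fx <- make_plots(n_env = 3)
  s1 <- stage1_all(fx$plots, "T1")
  s2 <- stage2_blues(s1$blues, "T1", s1$sigma2_e, s1$n_rep)
  df <- as.data.frame(s1$blues)
  means <- c(tapply(df$value, df$genotype, mean))
  b <- stats::setNames(s2$blues$value, s2$blues$genotype)
  expect_equal(b[names(means)], means, tolerance = 1e-6)
})

test_that("two-stage variance components match a single-stage REML oracle", {
  skip_if_not_installed("lme4")
  recov <- matrix(NA_real_, 4, 3)
  for (s in 1:4) {
    fx <- make_plots(n = 150, n_env = 4, var_G = 1, var_GxE = 0.5,
                     var_Error = 1, var_rep = 0.1, var_block = 0.1,
                     seed = 40 + s, panel_seed = 29)
    vc <- two_stage(fx$plots, "T1")$vc
    recov[s, ] <- c(vc$sigma2_G, vc$sigma2_GxE, vc$sigma2_Error)
  }
  est <- colMeans(recov)
  expect_lt(abs(est[1] - 1), 0.2)
  expect_lt(abs(est[2] - 0.5), 0.2)
  expect_lt(abs(est[3] - 1), 0.15)
  # single-stage oracle on the last dataset
  df <- as.data.frame(fx$plots)
  df$er <- paste(df$environment, df$replicate)
  df$erb <- paste(df$er, df$block)
  fit <- suppressMessages(lme4::lmer(
    value ~ environment + (1 | genotype) + (1 | genotype:environment) +
      (1 | er) + (1 | erb), data = df))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  oracle_G <- vcs$vcov[vcs$grp == "genotype"]
  oracle_GxE <- vcs$vcov[vcs$grp == "genotype:environment"]
  expect_lt(abs(recov[4, 1] - oracle_G), 0.15)
  expect_lt(abs(recov[4, 2] - oracle_GxE), 0.2)
})

test_that("heritability formulas and limits are exact", {
  h <- heritabilities(1, 1, 1, 2, 2)
  expect_equal(h$h2_plot, 1 / 3)
  expect_equal(h$h2_entry, 1 / (1 + 0.5 + 0.25), tolerance = 1e-12)
  expect_equal(h$h2_entry, 0.5714, tolerance = 1e-4)
  h0 <- heritabilities(2, 0, 0, 3, 2)
  expect_equal(h0$h2_plot, 1)
  expect_equal(h0$h2_entry, 1)
  hs <- vapply(c(1, 2, 4, 8, 1000), function(J)
    heritabilities(1, 1, 1, J, J)$h2_entry, numeric(1))
  expect_false(is.unsorted(hs))
  expect_gt(hs[5], 0.99)
  expect_error(heritabilities(0, 0, 0, 2, 2), "zero")
})

test_that("entry-mean heritability dominates plot heritability", {
  set.seed(3)
  for (i in 1:20) {
    v <- runif(3, 0.01, 2)
    h <- heritabilities(v[1], v[2], v[3], sample(2:8, 1), sample(2:3, 1))
    expect_gte(h$h2_entry, h$h2_plot)
  }
})

test_that("phenotypic correlations use the closed-form t-test", {
  set.seed(5)
  n <- 27
  # construct a pair with exact sample correlation 0.5
  x <- scale(rnorm(n))[, 1]
  e <- scale(stats::resid(stats::lm(rnorm(n) ~ x)))[, 1]
  y <- 0.5 * x + sqrt(1 - 0.25) * e
  df <- rbind(data.frame(genotype = paste0("g", 1:n), trait = "A", value = x),
              data.frame(genotype = paste0("g", 1:n), trait = "B", value = y))
  pc <- phenotypic_correlations(trait_dataset(df, "stage2"))
  expect_equal(pc$r["A", "B"], 0.5, tolerance = 1e-10)
  tstat <- 0.5 * sqrt((n - 2) / (1 - 0.25))
  expect_equal(tstat, 2.886, tolerance = 1e-3)
  expect_equal(pc$p_value["A", "B"], 2 * stats::pt(-tstat, n - 2))
  expect_equal(pc$p_value["A", "B"],
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(pc$r["A", "A"], 1)
})

test_that("independent simulated traits rarely show |r| > 0.2 at panel size", {
  pn <- small_panel(n = 372, seed = 31, mpc = 20, chrom = 2, kinship = 0)
  hits <- 0
  for (i in 1:6) {
    st2 <- stage1_to_stage2_means(sim_stage1(pn, rg = 0, n_env = 2,
                                             seed = 200 + i))
    pc <- phenotypic_correlations(st2)
    if (abs(pc$r["T1", "T2"]) >= 0.2) hits <- hits + 1
  }
  expect_lte(hits, 1)
  # flagged degenerate case
  df <- rbind(data.frame(genotype = paste0("g", 1:5), trait = "A",
                         value = 1),
              data.frame(genotype = paste0("g", 1:5), trait = "B",
                         value = rnorm(5)))
  expect_warning(phenotypic_correlations(trait_dataset(df, "stage2")),
                 "constant trait")
})
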