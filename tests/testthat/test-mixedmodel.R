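test_that("Wald statistics match closed forms", {
  fake <- list(beta = c(a = 2), vbeta = matrix(1, 1, 1,
                                               dimnames = list("a", "a")))
  w <- wald_test(fake, "a")
  expect_equal(w$statistic, 4)
  expect_equal(w$df, 1)
  expect_equal(w$p_value, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(w$p_value, 0.0455, tolerance = 1e-3)

  fake2 <- list(beta = c(a = 0, b = 0), vbeta = diag(2) |>
                  `dimnames<-`(list(c("a", "b"), c("a", "b"))))
  w2 <- wald_test(fake2, c("a", "b"))
  expect_equal(w2$statistic, 0)
  expect_equal(w2$p_value, 1)

  # orthogonal effects: joint statistic = sum of individual statistics
  fake3 <- list(beta = c(a = 1.3, b = -0.7),
                vbeta = diag(c(0.25, 0.5)) |>
                  `dimnames<-`(list(c("a", "b"), c("a", "b"))))
  wj <- wald_test(fake3, c("a", "b"))
  expect_equal(wj$statistic,
               wald_test(fake3, "a")$statistic +
                 wald_test(fake3, "b")$statistic)

  # singular covariance falls back to a generalized inverse
  V <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  fake4 <- list(beta = c(a = 1, b = 1), vbeta = V)
  expect_warning(ws <- wald_test(fake4, c("a", "b")), "generalized")
  expect_equal(ws$df, 1)
})

test_that("general engine and specialized bivariate path agree", {
  pn <- small_panel(n = 100, seed = 51)
  st2 <- stage1_to_stage2_means(sim_stage1(pn, rg = 0.5, n_env = 2,
                                           seed = 7))
  mk <- pn$geno$dosages[, 10]
  fit <- fit_multitrait(st2, c("T1", "T2"), pn$K, markers = mk,
                        method = "ML", control = list(reltol = 1e-12))
  eg <- eig_of(pn$K)
  ids <- fit$prep$ids
  df <- as.data.frame(st2)
  y1 <- df$value[df$trait == "T1"][match(ids,
                                         df$genotype[df$trait == "T1"])]
  y2 <- df$value[df$trait == "T2"][match(ids,
                                         df$genotype[df$trait == "T2"])]
  U <- eg$U
  u <- drop(crossprod(U, rep(1, length(ids))))
  mr <- drop(crossprod(U, mk[ids]))
  f2 <- wheatmt:::.biv_fit2_rot(drop(crossprod(U, y1)),
                                drop(crossprod(U, y2)), u, mr, mr, eg$d,
                                reltol = 1e-12)
  expect_equal(fit$logLik, f2$logLik, tolerance = 1e-4)
  expect_equal(sort(unname(fit$beta)), sort(unname(f2$beta)),
               tolerance = 1e-3)
})

test_that("bivariate ML marginals track the univariate fit", {
  # with independent traits the bivariate marginals approach the
  # univariate estimates (exact only as the cross-covariances vanish)
  pn <- small_panel(n = 80, seed = 53)
  st1 <- sim_stage1(pn, rg = 0, n_env = 2, seed = 9)
  biv <- fit_multitrait(st1, c("T1", "T2"), pn$K, method = "ML",
                        control = list(reltol = 1e-13))
  uni <- fit_multitrait(st1, "T1", pn$K, method = "ML",
                        control = list(reltol = 1e-13))
  expect_lt(abs(biv$G0[1, 1] - uni$G0[1, 1]) / uni$G0[1, 1], 0.1)
  expect_lt(abs(biv$R0[1, 1] - uni$R0[1, 1]) / uni$R0[1, 1], 0.1)
})

test_that("likelihood is invariant to genotype reordering", {
  pn <- small_panel(n = 60, seed = 57)
  st1 <- sim_stage1(pn, rg = 0.4, n_env = 2, seed = 3)
  fit <- fit_multitrait(st1, c("T1", "T2"), pn$K)
  df <- as.data.frame(st1)
  set.seed(1)
  df2 <- df[sample.int(nrow(df)), ]
  fit2 <- fit_multitrait(trait_dataset(df2, "stage1"), c("T1", "T2"),
                         pn$K)
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-5)
  expect_equal(fit$G0, fit2$G0, tolerance = 1e-3)
})

test_that("genetic correlation is recovered and tested by LR", {
  pn <- small_panel(n = 150, seed = 59, mpc = 25, chrom = 3)
  rgs <- numeric(8)
  for (s in 1:8) {
    st1 <- sim_stage1(pn, rg = 0.6, n_env = 2, seed = 300 + s)
    fit <- fit_multitrait(st1, c("T1", "T2"), pn$K)
    rgs[s] <- genetic_correlation(fit)$r_g
  }
  expect_lt(abs(mean(rgs) - 0.6), 0.15)

  # exact-zero covariance: LR floored at 0, p = 1 (constrained = full)
  st1 <- sim_stage1(pn, rg = 0, n_env = 2, seed = 77)
  fit0 <- fit_multitrait(st1, c("T1", "T2"), pn$K, constrain_rg = TRUE)
  expect_equal(fit0$G0[1, 2], 0)
  gc0 <- genetic_correlation(fit0)
  expect_equal(gc0$LR, 0, tolerance = 1e-6)
  expect_gt(gc0$p_value, 0.99)
})

test_that("r_g formula and degenerate flags behave", {
  fit <- structure(list(G0 = matrix(c(1, 1, 1, 1), 2), R0 = diag(2),
                        traits = c("a", "b"), converged = TRUE),
                   class = "mt_fit")
  expect_equal(fit$G0[1, 2] / sqrt(fit$G0[1, 1] * fit$G0[2, 2]), 1)
  fitz <- structure(list(G0 = matrix(0, 2, 2), traits = c("a", "b"),
                         converged = TRUE), class = "mt_fit")
  expect_warning(res <- genetic_correlation(fitz), "zero genetic variance")
  expect_true(is.na(res$r_g))
  fitn <- structure(list(G0 = diag(2), traits = c("a", "b"),
                         converged = FALSE), class = "mt_fit")
  expect_error(genetic_correlation(fitn), "non-converged")
})

test_that("uncorrelated traits under identity kinship give near-zero r_g", {
  pn <- small_panel(n = 120, seed = 61)
  ids <- rownames(pn$geno$dosages)
  I_k <- structure(list(A = diag(2, length(ids)) |>
                          `dimnames<-`(list(ids, ids)),
                        RD = NULL, bending = 0), class = "kinship_matrix")
  vals <- numeric(6)
  for (s in 1:6) {
    st1 <- sim_stage1(pn, rg = 0, n_env = 2, seed = 400 + s)
    fit <- fit_multitrait(st1, c("T1", "T2"), I_k)
    vals[s] <- abs(genetic_correlation(fit)$r_g)
  }
  expect_lt(mean(vals, na.rm = TRUE), 0.25)
})

test_that("row deletion drops genotypes with incomplete records", {
  pn <- small_panel(n = 60, seed = 57)
  st1 <- sim_stage1(pn, rg = 0.3, n_env = 2, seed = 5)
  df <- as.data.frame(st1)
  df <- df[-c(1, 5), ]  # remove two cells of one genotype set
  expect_message(fit <- fit_multitrait(trait_dataset(df, "stage1"),
                                       c("T1", "T2"), pn$K),
                 "dropping")
  expect_lt(fit$n, 60)
})
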