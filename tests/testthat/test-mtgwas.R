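test_that("BH q-values follow the step-up formula; thresholds are exact", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- correct_multiplicity(p, "FDR")
  expect_equal(q, rep(0.04, 4))
  # independent step-up oracle
  stepup <- function(p) {
    m <- length(p); o <- order(p); ro <- order(o)
    q <- pmin(1, cummin((p[o] * m / seq_len(m))[m:1])[m:1])
    q[ro]
  }
  set.seed(2)
  for (i in 1:5) {
    pr <- runif(sample(3:40, 1))
    expect_equal(correct_multiplicity(pr, "FDR"), stepup(pr))
  }
  expect_equal(correct_multiplicity(0.007, "FDR"), 0.007)
  expect_equal(correct_multiplicity(runif(18856), "Bonferroni",
                                    alpha = 0.05),
               2.652e-6, tolerance = 1e-3)
  expect_equal(correct_multiplicity(runif(10), "Meff", alpha = 0.05,
                                    M_eff = 3257), 0.05 / 3257)
  expect_error(correct_multiplicity(numeric(0)), "empty")
  expect_error(correct_multiplicity(c(0.1), "Meff"), "M_eff")
})

test_that("significance sets are nested: Bonferroni within Meff within FDR", {
  set.seed(8)
  for (i in 1:10) {
    m <- 200
    p <- c(runif(20, 0, 1e-4), runif(m - 20))
    meff <- sample(20:m, 1)
    alpha <- 0.05
    sig_b <- p < alpha / m
    sig_m <- p < alpha / meff
    sig_f <- correct_multiplicity(p, "FDR") < alpha
    expect_true(all(!sig_b | sig_m))
    expect_true(all(!sig_m | sig_f))
  }
})

# Causal markers are engineered outside the kinship panel so the planted
# signal is not absorbed by A (no proximal contamination in the fixture).
scan_fixture <- function() {
  cached("scan_fixture", {
    pn <- small_panel(n = 120, seed = 71, mpc = 25, chrom = 2)
    n <- nrow(pn$geno$dosages)
    q1 <- simulate_marker_pair(0.4, 0.4, 1, n, seed = 301)$m1
    q2 <- simulate_marker_pair(0.35, 0.35, 1, n, seed = 302)$m1
    M <- cbind(pn$geno$dosages, Q1 = q1, Q2 = q2)
    map <- rbind(pn$geno$map,
                 data.frame(marker = c("Q1", "Q2"),
                            chromosome = c("C1", "C2"),
                            position_cM = c(300, 300)))
    geno <- genotype_matrix(M, map)
    panel <- list(geno = geno, K = pn$K)
    qtl <- data.frame(marker = c("Q1", "Q1", "Q2", "Q2"),
                      trait = c("T1", "T2", "T1", "T2"),
                      effect = c(0.7, 0.7, 0.7, -0.7))
    st1 <- sim_stage1(panel, rg = 0, n_env = 2, var_G = 1, var_GxE = 0.4,
                      qtl = qtl, seed = 13)
    mks <- colnames(pn$geno$dosages)
    scan <- suppressMessages(
      scan_bivariate(geno, st1, pn$K, c("T1", "T2"),
                     markers = c(mks[c(1:20, 26:45)], "Q1", "Q2"),
                     M_eff = 35))
    list(pn = panel, st1 = st1, scan = scan, causal = c("Q1", "Q2"))
  })
}

test_that("the bivariate scan finds planted QTLs with designed signs", {
  fx <- scan_fixture()
  scan <- fx$scan
  expect_s3_class(scan, "mtgwas_scan")
  cz <- scan[scan$marker %in% fx$causal, ]
  expect_true(all(cz$p_global < 1e-4))
  expect_equal(cz$covariation_sign, c("+", "-"))
  expect_true(all(cz$sig_fdr))
})

test_that("declared-pleiotropic markers pass global and both individual tests", {
  fx <- scan_fixture()
  scan <- fx$scan
  for (flag in c("sig_fdr", "sig_bonferroni", "sig_meff")) {
    sig <- scan[which(scan[[flag]]), ]
    if (nrow(sig))
      expect_true(all(sig$p_1 < 0.05 & sig$p_2 < 0.05))
  }
  expect_equal(scan$covariation_sign,
               ifelse(scan$alpha_1 * scan$alpha_2 >= 0, "+", "-"))
})

test_that("null markers give roughly uniform global p-values", {
  fx <- scan_fixture()
  nullp <- fx$scan$p_global[!fx$scan$marker %in% fx$causal]
  # remove markers linked to the causals
  linked <- vapply(fx$scan$marker[!fx$scan$marker %in% fx$causal],
                   function(m) max(ld_r2(fx$pn$geno$dosages[, m],
                                         fx$pn$geno$dosages[, fx$causal[1]]),
                                   ld_r2(fx$pn$geno$dosages[, m],
                                         fx$pn$geno$dosages[, fx$causal[2]])),
                   numeric(1))
  nullp <- nullp[linked < 0.2]
  expect_gt(suppressWarnings(stats::ks.test(nullp, "punif")$p.value), 0.01)
})

test_that("degenerate inputs are refused or skipped", {
  fx <- scan_fixture()
  df <- as.data.frame(fx$st1)
  df$value <- 1
  expect_error(scan_bivariate(fx$pn$geno, trait_dataset(df, "stage1"),
                              fx$pn$K, c("T1", "T2")),
               "degenerate")
  # monomorphic marker is skipped with a message
  g2 <- fx$pn$geno
  g2$dosages[, 1] <- 2
  expect_message(
    s <- scan_bivariate(g2, fx$st1, fx$pn$K, c("T1", "T2"),
                        markers = colnames(g2$dosages)[1:3]),
    "monomorphic")
  expect_false(colnames(g2$dosages)[1] %in% s$marker)
})

test_that("effective association counts collapse LD blocks", {
  set.seed(91)
  n <- 400
  base <- matrix(sample(c(0, 2), n * 8, replace = TRUE), n, 8)
  sizes <- c(4, 3, 3, 2, 2, 2, 1, 1)  # 18 markers in 8 blocks
  M <- do.call(cbind, lapply(seq_along(sizes), function(b)
    base[, rep(b, sizes[b])]))
  colnames(M) <- paste0("m", seq_len(ncol(M)))
  g <- genotype_matrix(M, data.frame(marker = colnames(M), chromosome = "1",
                                     position_cM = seq_len(ncol(M))))
  expect_equal(effective_association_count(colnames(M), g), 8L)
  expect_equal(effective_association_count(colnames(M)[1:4], g), 1L)
  ind <- genotype_matrix(base |> `colnames<-`(paste0("i", 1:8)),
                         data.frame(marker = paste0("i", 1:8),
                                    chromosome = "1", position_cM = 1:8))
  expect_equal(effective_association_count(paste0("i", 1:8), ind),
               as.integer(ceiling(0.95 * 8)))
  expect_equal(effective_association_count("m1", g), 1L)
})

test_that("sequential variance partition and genetic shares are exact", {
  set.seed(17)
  n <- 100
  m1 <- sample(c(0, 2), n, replace = TRUE)
  M <- cbind(m1 = m1, m2 = m1, m3 = sample(c(0, 2), n, replace = TRUE))
  g <- genotype_matrix(M, data.frame(marker = colnames(M), chromosome = "1",
                                     position_cM = 1:3))
  ids <- rownames(g$dosages)
  df <- data.frame(genotype = ids, trait = "T1", value = m1 * 0.5)
  vp <- suppressWarnings(
    variance_partition(trait_dataset(df, "stage2"), g,
                       c("m1", "m2", "m3"), "T1", c(T1 = 1)))
  expect_equal(vp$R2[1], 1)
  expect_equal(vp$R2[2], 0)  # duplicate adds nothing
  expect_equal(vp$R2_cum[3], 1)
  vp2 <- suppressWarnings(
    variance_partition(trait_dataset(df, "stage2"), g, c("m1", "m2"),
                       "T1", c(T1 = 0.5)))
  expect_equal(vp2$genetic_share[1], 2)  # R2 / h2_entry
})

test_that("three-trait extension declares only jointly associated markers", {
  pn <- small_panel(n = 150, seed = 73, mpc = 20, chrom = 2)
  n <- nrow(pn$geno$dosages)
  q <- simulate_marker_pair(0.35, 0.35, 1, n, seed = 311)$m1
  geno <- genotype_matrix(
    cbind(pn$geno$dosages, Q = q),
    rbind(pn$geno$map, data.frame(marker = "Q", chromosome = "C1",
                                  position_cM = 300)))
  panel <- list(geno = geno, K = pn$K)
  qtl3 <- data.frame(marker = "Q", trait = c("T1", "T2", "T3"),
                     effect = c(0.6, 0.6, 0.6))
  st1 <- sim_stage1(panel, traits = c("T1", "T2", "T3"), rg = 0,
                    n_env = 2, var_GxE = 0.3, qtl = qtl3, seed = 21)
  hot <- higher_order_test(geno, st1, pn$K, "Q", c("T1", "T2", "T3"),
                           alpha = 0.1, M_eff = 10)
  expect_true(hot$declared)
  expect_true(all(hot$p_values < hot$threshold))
  # marker affecting one trait only is not declared
  qtl1 <- data.frame(marker = "Q", trait = "T1", effect = 0.6)
  st1b <- sim_stage1(panel, traits = c("T1", "T2", "T3"), rg = 0,
                     n_env = 2, var_GxE = 0.3, qtl = qtl1, seed = 22)
  hot1 <- higher_order_test(geno, st1b, pn$K, "Q", c("T1", "T2", "T3"),
                            alpha = 0.1, M_eff = 10)
  expect_false(hot1$declared)
})

test_that("two-trait reduction of the multi-trait fit matches the scan", {
  fx <- scan_fixture()
  mk <- fx$causal[1]
  prep <- wheatmt:::.mt_prepare_base(fx$st1, c("T1", "T2"), fx$pn$K)
  fit <- fit_multitrait(fx$st1, c("T1", "T2"), fx$pn$K,
                        markers = fx$pn$geno$dosages[prep$ids, mk],
                        marker_by_env = TRUE)
  wg <- wald_test(fit, c("alpha[T1]", "alpha[T2]"))
  row <- fx$scan[fx$scan$marker == mk, ]
  expect_equal(wg$statistic, row$wald_global, tolerance = 0.02)
  expect_equal(unname(fit$beta["alpha[T1]"]), row$alpha_1,
               tolerance = 0.01)
})

test_that("stability ratio separates stable from environment-specific effects", {
  pn <- small_panel(n = 120, seed = 75)
  mk <- colnames(pn$geno$dosages)[7]
  ids <- rownames(pn$geno$dosages)
  dos <- pn$geno$dosages[, mk]
  envs <- c("E1", "E2", "E3")
  set.seed(33)
  stable <- do.call(rbind, lapply(envs, function(e)
    data.frame(genotype = ids, environment = e, trait = "T1",
               value = 0.8 * dos + rnorm(length(ids), sd = 0.3))))
  r_st <- stability_ratio(trait_dataset(stable, "stage1"), pn$geno, mk,
                          "T1")
  expect_gt(r_st$ratio, 10)
  wobble <- do.call(rbind, lapply(envs, function(e)
    data.frame(genotype = ids, environment = e, trait = "T1",
               value = rnorm(1, sd = 1.2) * dos +
                 rnorm(length(ids), sd = 0.3))))
  r_w <- stability_ratio(trait_dataset(wobble, "stage1"), pn$geno, mk,
                         "T1")
  expect_lt(r_w$ratio, r_st$ratio)
  nothing <- do.call(rbind, lapply(envs, function(e)
    data.frame(genotype = ids, environment = e, trait = "T1",
               value = rep(1, length(ids)))))
  expect_warning(r_0 <- stability_ratio(trait_dataset(nothing, "stage1"),
                                        pn$geno, mk, "T1"),
                 "undefined|infinite")
  expect_true(is.na(r_0$ratio) || is.infinite(r_0$ratio))
})
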