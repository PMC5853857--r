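# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_panel <- function(n = 120, seed = 42, mpc = 30, chrom = 3,
                        kinship = 0.3) {
  cached(sprintf("panel_%d_%d_%d_%d_%s", n, seed, mpc, chrom, kinship), {
    spec <- sim_population_spec(n_genotypes = n, n_markers_per_chrom = mpc,
                                n_chromosomes = chrom,
                                kinship_strength = kinship, seed = seed)
    g <- simulate_genotypes(spec)
    list(geno = g, K = kinship_matrix(g))
  })
}

# genotype-by-environment trait values without the plot stage: replicate-free,
# error-free simulation collapses to stage-1 style records directly
sim_stage1 <- function(panel, traits = c("T1", "T2"), rg = 0, n_env = 2,
                       var_G = 1, var_GxE = 0.4, qtl = NULL, seed = 1) {
  t <- length(traits)
  C <- matrix(rg, t, t); diag(C) <- 1
  ts <- sim_trait_spec(traits, var_G = var_G, var_GxE = var_GxE,
                       var_Error = 0, genetic_corr = C,
                       n_environments = n_env, n_replicates = 1,
                       qtl_effects = qtl, var_rep = 0, var_block = 0)
  ph <- simulate_phenotypes(panel$geno, panel$K, ts, seed = seed)
  df <- as.data.frame(ph)[, c("genotype", "environment", "trait", "value")]
  st <- trait_dataset(df, "stage1")
  attr(st, "true_values") <- attr(ph, "true_values")
  st
}

stage1_to_stage2_means <- function(st1) {
  df <- as.data.frame(st1)
  agg <- stats::aggregate(value ~ genotype + trait, df, mean)
  trait_dataset(agg, "stage2")
}

eig_of <- function(K) {
  ea <- eigen((K$A + t(K$A)) / 2, symmetric = TRUE)
  list(d = pmax(ea$values, 0), U = ea$vectors)
}
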