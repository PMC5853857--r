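#' Specification of a simulated inbred panel
#'
#' Describes the panel emulated by [simulate_genotypes()]: ~372 inbred
#' varieties genotyped with mapped bi-allelic markers showing a realistic
#' minor-allele-frequency spectrum, intrachromosomal LD decaying with map
#' distance, and family-induced kinship. Genotypes are built as mosaics of
#' founder haplotypes: each line walks along every chromosome switching
#' founders with probability `1 - exp(-d / ld_decay_cM)` per map step of
#' `d` cM, the founder alleles themselves form a Markov chain along the
#' chromosome at the same distance scale (contiguous founder haplotypes),
#' and `kinship_strength` is the probability of drawing founders from a
#' family-specific pool rather than from all founders, which creates
#' blocks of related lines and hence an informative A matrix.
#'
#' @param n_genotypes number of inbred lines (default 372).
#' @param n_markers_per_chrom markers per chromosome.
#' @param n_chromosomes number of chromosomes (<= 21).
#' @param maf_range admissible range for realized minor allele frequencies.
#' @param ld_decay_cM map-distance scale of LD decay (larger = longer LD).
#' @param kinship_strength founder-sharing mixing weight in \[0, 1).
#' @param chrom_length_cM chromosome length.
#' @param n_founders number of founder haplotypes.
#' @param n_families number of line families.
#' @param het_rate probability that a line is heterozygous at a marker
#'   (default 0: fully inbred).
#' @param seed integer seed.
#' @return list of class `sim_population_spec`.
#' @export
sim_population_spec <- function(n_genotypes = 372, n_markers_per_chrom = 100,
                                n_chromosomes = 21,
                                maf_range = c(0.05, 0.5),
                                ld_decay_cM = 3, kinship_strength = 0.3,
                                chrom_length_cM = 150, n_founders = 32,
                                n_families = 10, het_rate = 0, seed = 1) {
  stopifnot(n_genotypes >= 2, n_markers_per_chrom >= 1,
            n_chromosomes >= 1, n_chromosomes <= 21,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_decay_cM > 0, kinship_strength >= 0, kinship_strength < 1,
            het_rate >= 0, het_rate <= 1)
  structure(as.list(environment()), class = "sim_population_spec")
}

#' Simulate an inbred genotype panel
#'
#' @param spec a [sim_population_spec].
#' @return a [genotype_matrix] of `n_genotypes` x
#'   `n_chromosomes * n_markers_per_chrom` dosages with a genetic map.
#'   Realized minor allele frequencies fall inside `spec$maf_range`; r^2
#'   between markers decays with cM distance at scale `ld_decay_cM`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_population_spec"))
  set.seed(spec$seed)
  n <- spec$n_genotypes
  nf <- spec$n_founders
  # family-specific founder pools (overlapping subsets)
  fam <- sample(rep_len(seq_len(spec$n_families), n))
  pool_size <- max(2L, ceiling(nf / 4))
  pools <- lapply(seq_len(spec$n_families), function(f)
    sample.int(nf, pool_size))

  draw_founder <- function(who) {
    # vectorized founder draw: family pool w.p. kinship_strength, else global
    use_pool <- stats::runif(length(who)) < spec$kinship_strength
    out <- sample.int(nf, length(who), replace = TRUE)
    if (any(use_pool)) {
      idx <- which(use_pool)
      out[idx] <- vapply(fam[who[idx]], function(f)
        pools[[f]][sample.int(pool_size, 1)], integer(1))
    }
    out
  }

  chrs <- paste0("C", seq_len(spec$n_chromosomes))
  dos_all <- vector("list", spec$n_chromosomes)
  map_all <- vector("list", spec$n_chromosomes)
  n_paths <- if (spec$het_rate > 0) 2L else 1L
  for (c_i in seq_len(spec$n_chromosomes)) {
    M <- spec$n_markers_per_chrom
    pos <- sort(stats::runif(M, 0, spec$chrom_length_cM))
    # founder mosaic paths (one per haplotype copy)
    paths <- array(0L, dim = c(n, M, n_paths))
    for (h in seq_len(n_paths)) {
      cur <- draw_founder(seq_len(n))
      paths[, 1, h] <- cur
      if (M > 1) for (m in 2:M) {
        d <- pos[m] - pos[m - 1]
        sw <- stats::runif(n) < (1 - exp(-d / spec$ld_decay_cM))
        if (any(sw)) cur[sw] <- draw_founder(which(sw))
        paths[, m, h] <- cur
      }
    }
    # founder alleles form a Markov chain along the chromosome: at map
    # step d each founder keeps its previous allele with probability
    # exp(-d / ld_decay_cM), else redraws at the marker's frequency. The
    # combination of contiguous founder haplotypes and mosaic inheritance
    # is what produces r^2 that decays with distance and can exceed 0.5
    # between close markers. Alleles are redrawn (non-copied entries
    # first, then with relaxed copying) until the realized MAF is in
    # range.
    dos <- matrix(0, n, M)
    al_prev <- NULL
    for (m in seq_len(M)) {
      cpy <- if (m == 1) rep(FALSE, nf)
      else stats::runif(nf) < exp(-(pos[m] - pos[m - 1]) /
                                    spec$ld_decay_cM)
      ok <- FALSE
      d <- NULL
      for (try in 1:60) {
        p <- stats::runif(1, spec$maf_range[1], spec$maf_range[2])
        al <- stats::rbinom(nf, 1, p)
        if (any(cpy)) al[cpy] <- al_prev[cpy]
        d <- al[paths[, m, 1]] + al[paths[, m, n_paths]]
        f <- mean(d) / 2
        maf <- min(f, 1 - f)
        if (maf >= spec$maf_range[1] && maf <= spec$maf_range[2]) {
          ok <- TRUE
          break
        }
        if (try > 30) cpy <- cpy & stats::runif(nf) < 0.7
      }
      if (!ok) {  # fall back to iid line draws at a mid-range frequency
        p <- mean(spec$maf_range)
        for (try in 1:200) {
          a <- stats::rbinom(n, 1, p)
          d <- 2 * a
          f <- mean(d) / 2
          maf <- min(f, 1 - f)
          if (maf >= spec$maf_range[1] && maf <= spec$maf_range[2]) break
        }
        if (maf < spec$maf_range[1] || maf > spec$maf_range[2])
          stop("could not realize a MAF inside maf_range")
        al <- stats::rbinom(nf, 1, p)
      }
      # code dosage as copies of the minor allele
      if (mean(d) / 2 > 0.5) {
        d <- 2 - d
        al <- 1 - al
      }
      dos[, m] <- d
      al_prev <- al
    }
    if (spec$het_rate > 0 && n_paths == 1L) {
      het <- matrix(stats::runif(n * M) < spec$het_rate, n, M)
      dos[het & dos == 0] <- 1
      dos[het & dos == 2] <- 1
    }
    colnames(dos) <- sprintf("%s_M%03d", chrs[c_i], seq_len(M))
    dos_all[[c_i]] <- dos
    map_all[[c_i]] <- data.frame(marker = colnames(dos),
                                 chromosome = chrs[c_i], position_cM = pos,
                                 stringsAsFactors = FALSE)
  }
  dosages <- do.call(cbind, dos_all)
  rownames(dosages) <- sprintf("V%03d", seq_len(n))
  genotype_matrix(dosages, map = do.call(rbind, map_all))
}

#' Maximum attainable r^2 between two bi-allelic loci
#'
#' For minor allele frequencies `p` and `q`, the gametic disequilibrium D is
#' bounded by the haplotype-frequency constraints; r^2 = D^2 / (p(1-p)q(1-q))
#' is maximized at one of the two D bounds.
#'
#' @param p,q allele frequencies in (0, 1).
#' @return list with `r2_max`, and the bound-achieving `D`.
#' @export
r2_max <- function(p, q) {
  d_pos <- min(p * (1 - q), q * (1 - p))
  d_neg <- -min(p * q, (1 - p) * (1 - q))
  denom <- p * (1 - p) * q * (1 - q)
  r2p <- d_pos^2 / denom
  r2n <- d_neg^2 / denom
  if (r2p >= r2n) list(r2_max = r2p, D = d_pos)
  else list(r2_max = r2n, D = d_neg)
}

#' Simulate a pair of linked markers with target MAF and r^2
#'
#' Haplotypes for `n` inbred lines are drawn from the two-locus haplotype
#' frequencies implied by (maf1, maf2, target r^2); draws are rejected until
#' realized MAFs are within `maf_tol` of the request and realized r^2 within
#' `r2_tol` of the target, or an error is thrown after `max_attempts`.
#' Infeasible (MAF, r^2) combinations are refused up front with the
#' attainable r^2 bound in the message.
#'
#' @param maf1,maf2 target minor allele frequencies in (0, 0.5\].
#' @param target_r2 target squared correlation in \[0, 1\].
#' @param n number of inbred lines.
#' @param seed integer seed.
#' @param maf_tol,r2_tol acceptance tolerances on realized values.
#' @param max_attempts bounded rejection-sampling retries.
#' @return list with dosage vectors `m1`, `m2` (0/2 coding) and realized
#'   `maf1`, `maf2`, `r2`.
#' @export
simulate_marker_pair <- function(maf1, maf2, target_r2, n, seed = 1,
                                 maf_tol = 0.02, r2_tol = 0.03,
                                 max_attempts = 200) {
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            target_r2 >= 0, target_r2 <= 1, n >= 10)
  bound <- r2_max(maf1, maf2)
  if (target_r2 > bound$r2_max + 1e-9)
    stop(sprintf(
      "infeasible: r^2 = %.3g unreachable for MAF (%.3g, %.3g); max r^2 = %.4g",
      target_r2, maf1, maf2, bound$r2_max))
  p <- maf1; q <- maf2
  denom <- p * (1 - p) * q * (1 - q)
  D <- sqrt(target_r2 * denom)
  if (D > min(p * (1 - q), q * (1 - p)) + 1e-12) D <- -D  # use negative branch
  f <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D,
         (1 - p) * (1 - q) + D)  # haplotypes 11, 10, 01, 00
  f <- pmax(f, 0); f <- f / sum(f)
  set.seed(seed)
  for (att in seq_len(max_attempts)) {
    h <- sample.int(4, n, replace = TRUE, prob = f)
    m1 <- ifelse(h %in% c(1, 2), 2, 0)
    m2 <- ifelse(h %in% c(1, 3), 2, 0)
    f1 <- mean(m1) / 2; f2 <- mean(m2) / 2
    if (abs(min(f1, 1 - f1) - maf1) > maf_tol ||
        abs(min(f2, 1 - f2) - maf2) > maf_tol) next
    if (stats::var(m1) == 0 || stats::var(m2) == 0) next
    r2 <- stats::cor(m1, m2)^2
    if (target_r2 >= 1 - 1e-12) {
      if (r2 > 1 - 1e-9)
        return(list(m1 = m1, m2 = m2, maf1 = min(f1, 1 - f1),
                    maf2 = min(f2, 1 - f2), r2 = r2))
      next
    }
    if (abs(r2 - target_r2) <= r2_tol)
      return(list(m1 = m1, m2 = m2, maf1 = min(f1, 1 - f1),
                  maf2 = min(f2, 1 - f2), r2 = r2))
  }
  stop(sprintf(
    "failed to realize (MAF %.3g/%.3g, r^2 %.3g) in %d attempts",
    maf1, maf2, target_r2, max_attempts))
}

#' Simulate a marker linked at a target r^2 to an existing marker
#'
#' Generates a new inbred 0/2 dosage vector whose squared correlation with
#' `m` is close to `target_r2`, by drawing the second locus from the
#' conditional two-locus haplotype probabilities. Used to build LD windows
#' around simulated causal markers.
#'
#' @param m existing 0/2 dosage vector.
#' @param maf target minor allele frequency of the new marker.
#' @param target_r2 target r^2 to `m`.
#' @inheritParams simulate_marker_pair
#' @return dosage vector of the same length as `m`.
#' @export
simulate_linked_marker <- function(m, maf, target_r2, seed = 1,
                                   maf_tol = 0.02, r2_tol = 0.03,
                                   max_attempts = 200) {
  stopifnot(all(m %in% c(0, 2)), maf > 0, maf <= 0.5)
  p <- mean(m) / 2
  q <- maf
  bound <- r2_max(p, q)
  if (target_r2 > bound$r2_max + 1e-9)
    stop(sprintf("infeasible: max r^2 = %.4g for these frequencies",
                 bound$r2_max))
  denom <- p * (1 - p) * q * (1 - q)
  D <- sqrt(target_r2 * denom)
  if (D > min(p * (1 - q), q * (1 - p)) + 1e-12) D <- -D
  p1 <- (p * q + D) / p            # P(allele at new locus | m = 2)
  p0 <- ((1 - p) * q - D) / (1 - p)
  p1 <- min(max(p1, 0), 1); p0 <- min(max(p0, 0), 1)
  set.seed(seed)
  for (att in seq_len(max_attempts)) {
    a <- ifelse(m == 2, stats::rbinom(length(m), 1, p1),
                stats::rbinom(length(m), 1, p0))
    v <- 2 * a
    fq <- mean(v) / 2
    if (abs(min(fq, 1 - fq) - maf) > maf_tol) next
    if (stats::var(v) == 0) next
    r2 <- stats::cor(m, v)^2
    if (abs(r2 - target_r2) <= r2_tol)
      return(v)
  }
  stop(sprintf("failed to realize linked marker (MAF %.3g, r^2 %.3g)",
               maf, target_r2))
}
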