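#' Minor allele frequency
#'
#' Frequency of the less common allele, computed from allele counts with
#' missing genotypes excluded from the denominator.
#'
#' @param dosage numeric vector of 0/1/2 dosages, `NA` allowed.
#' @return scalar in \[0, 0.5\].
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2))  # 0.375
#' @export
minor_allele_frequency <- function(dosage) {
  ok <- !is.na(dosage)
  if (sum(ok) < 2) stop("need at least 2 non-missing genotypes")
  p <- sum(dosage[ok]) / (2 * sum(ok))  # frequency of the coded allele
  min(p, 1 - p)
}

#' Rogers' distances and the kinship matrix A = 2(J - RD)
#'
#' Per-locus Rogers' distance between two individuals reduces, for dosage
#' data, to |d1 - d2| / 2 (heterozygote vs homozygote contributes 0.5,
#' opposite homozygotes contribute 1); the distance between two lines is the
#' average over their pairwise-complete loci. The relationship matrix is
#' A = 2 (J - RD), so identical inbred lines have A = 2 and fully opposite
#' lines have A = 0. Because 2(J - RD) is not guaranteed positive
#' semidefinite, `kinship_matrix()` applies minimum-eigenvalue bending
#' (adding -lambda_min + eps to the diagonal when lambda_min < 0) so the
#' result can serve as a covariance in REML.
#'
#' @param geno a [genotype_matrix] or a dosage matrix.
#' @return `rogers_distance()`: an n x n distance matrix in \[0, 1\];
#'   `kinship_matrix()`: a list of class `kinship_matrix` with elements `A`
#'   (bent), `RD`, and `bending` (the diagonal shift applied, 0 if none).
#' @export
rogers_distance <- function(geno) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  n <- nrow(M)
  obs <- !is.na(M)
  npair <- tcrossprod(obs * 1)
  if (any(npair == 0))
    stop("genotype pair(s) share no non-missing markers")
  # sum over loci of |d1 - d2| via dosage-class indicators
  X0 <- (M == 0) & obs; X1 <- (M == 1) & obs; X2 <- (M == 2) & obs
  X0[is.na(X0)] <- FALSE; X1[is.na(X1)] <- FALSE; X2[is.na(X2)] <- FALSE
  s01 <- tcrossprod(X0 * 1, X1 * 1)
  s12 <- tcrossprod(X1 * 1, X2 * 1)
  s02 <- tcrossprod(X0 * 1, X2 * 1)
  absdiff <- s01 + t(s01) + s12 + t(s12) + 2 * (s02 + t(s02))
  RD <- absdiff / (2 * npair)
  dimnames(RD) <- list(rownames(M), rownames(M))
  RD
}

#' @rdname rogers_distance
#' @param eps small diagonal inflation used when bending.
#' @export
kinship_matrix <- function(geno, eps = 1e-6) {
  RD <- if (is.matrix(geno) && isSymmetric(unname(geno)) &&
            all(diag(geno) == 0) && all(geno >= 0 & geno <= 1))
    geno else rogers_distance(geno)
  A <- 2 * (1 - RD)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  bend <- 0
  if (min(ev) < 0) {
    bend <- -min(ev) + eps
    diag(A) <- diag(A) + bend
  }
  structure(list(A = A, RD = RD, bending = bend), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix: ", nrow(x$A), " genotypes, mean off-diagonal A = ",
      signif(mean(x$A[upper.tri(x$A)]), 3),
      if (x$bending > 0) sprintf(", bent by %.2g", x$bending), "\n", sep = "")
  invisible(x)
}

#' Linkage disequilibrium as squared correlation
#'
#' @param v1,v2 dosage vectors; pairwise-complete observations are used.
#' @return squared Pearson correlation in \[0, 1\]; invariant to allele
#'   relabelling (v vs 2 - v).
#' @export
ld_r2 <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::var(v1[ok]) == 0 || stats::var(v2[ok]) == 0)
    stop("monomorphic marker: zero dosage variance")
  stats::cor(v1[ok], v2[ok])^2
}

#' Per-chromosome LD matrices
#'
#' Pairwise r^2 among the markers of one chromosome, using only markers with
#' a unique genetic map position (co-located duplicates are dropped beyond
#' the first). Monomorphic markers are dropped with a message.
#'
#' @param geno a [genotype_matrix].
#' @param chromosome chromosome label; if `NULL`, a list over all chromosomes.
#' @param unique_positions drop markers sharing an exact cM position.
#' @return symmetric r^2 matrix (or list of them), diagonal 1.
#' @export
ld_matrix <- function(geno, chromosome = NULL, unique_positions = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(chromosome)) {
    chrs <- unique(geno$map$chromosome[!geno$unmapped])
    out <- lapply(chrs, function(ch) ld_matrix(geno, ch, unique_positions))
    names(out) <- chrs
    return(out)
  }
  sel <- !geno$unmapped & geno$map$chromosome == chromosome
  map <- geno$map[sel, ]
  if (unique_positions) {
    keep <- !duplicated(map$position_cM)
    map <- map[keep, ]
  }
  M <- geno$dosages[, map$marker, drop = FALSE]
  v <- apply(M, 2, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE)) {
    message("dropping ", sum(v == 0), " monomorphic marker(s) on ",
            chromosome)
    M <- M[, v > 0, drop = FALSE]
  }
  r2 <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  r2
}

#' Effective number of independent tests from an LD matrix
#'
#' The smallest number of eigenvalues of the r^2 matrix whose cumulative sum
#' reaches `variance_threshold` of the total (negative eigenvalues, possible
#' because an r^2 matrix is only approximately Gram, are floored at zero
#' before accumulating). `m_eff_genome()` sums the per-chromosome counts.
#'
#' @param ld symmetric r^2 matrix, or a [genotype_matrix] for
#'   `m_eff_genome()`.
#' @param variance_threshold fraction of matrix variation to explain.
#' @return integer count.
#' @examples
#' m_eff(diag(20))          # 19
#' m_eff(matrix(1, 5, 5))   # 1
#' @export
m_eff <- function(ld, variance_threshold = 0.95) {
  ld <- as.matrix(ld)
  if (any(!is.finite(ld))) stop("non-finite entries in LD matrix")
  if (!isSymmetric(unname(ld), tol = 1e-8)) stop("LD matrix must be symmetric")
  ev <- eigen((ld + t(ld)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= variance_threshold - 1e-12)[1])
}

#' @rdname m_eff
#' @export
m_eff_genome <- function(ld, variance_threshold = 0.95) {
  stopifnot(inherits(ld, "genotype_matrix"))
  mats <- ld_matrix(ld)
  sum(vapply(mats, m_eff, integer(1),
             variance_threshold = variance_threshold))
}

#' LD window around a target marker
#'
#' Markers on the same chromosome whose r^2 with the target exceeds
#' `r2_min`, excluding the target itself. Only markers with unique map
#' positions are considered candidates (the target must be mapped). An empty
#' window means the two-dimensional pleiotropy-vs-linkage test cannot be run
#' for that target.
#'
#' @param geno a [genotype_matrix].
#' @param target_marker marker id.
#' @param r2_min strict lower r^2 bound (default 0.5).
#' @return character vector of marker ids (possibly empty).
#' @export
ld_window <- function(geno, target_marker, r2_min = 0.5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  i <- match(target_marker, geno$map$marker)
  if (is.na(i)) stop("unknown marker: ", target_marker)
  if (geno$unmapped[i]) stop("target marker is unmapped: ", target_marker)
  ch <- geno$map$chromosome[i]
  cand <- which(!geno$unmapped & geno$map$chromosome == ch &
                  geno$map$marker != target_marker)
  # unique positions among candidates (target's own position may be shared)
  cand <- cand[!duplicated(geno$map$position_cM[cand])]
  if (!length(cand)) return(character(0))
  tv <- geno$dosages[, target_marker]
  keep <- vapply(cand, function(j) {
    v <- geno$dosages[, j]
    ok <- !is.na(v) & !is.na(tv)
    if (sum(ok) < 3 || stats::var(v[ok]) == 0 || stats::var(tv[ok]) == 0)
      return(FALSE)
    ld_r2(tv, v) > r2_min
  }, logical(1))
  geno$map$marker[cand[keep]]
}

#' Impute missing functional-marker genotypes by genotype frequencies
#'
#' Missing entries are drawn from the marginal genotype-class distribution of
#' the observed entries, provided the missing fraction is below
#' `max_missing`; otherwise the marker is excluded via a classed condition
#' (`wheatmt_marker_excluded`) rather than silently dropped.
#'
#' @param dosage 0/1/2 dosage vector with `NA`s.
#' @param max_missing exclusion threshold on the missing fraction.
#' @param seed integer seed for the imputation draws.
#' @return completed dosage vector.
#' @export
impute_functional <- function(dosage, max_missing = 0.10, seed = 1) {
  mis <- is.na(dosage)
  frac <- mean(mis)
  if (frac >= max_missing)
    stop(structure(class = c("wheatmt_marker_excluded", "error", "condition"),
                   list(message = sprintf(
                     "marker excluded: %.1f%% missing (threshold %.1f%%)",
                     100 * frac, 100 * max_missing), call = NULL)))
  if (!any(mis)) return(dosage)
  obs <- dosage[!mis]
  tab <- table(factor(obs, levels = c(0, 1, 2)))
  set.seed(seed)
  dosage[mis] <- sample(c(0, 1, 2), sum(mis), replace = TRUE,
                        prob = as.numeric(tab) / sum(tab))
  dosage
}

#' Expand a multi-allelic marker into bi-allelic presence dosages
#'
#' Each allele of a multi-allelic (e.g. functional) marker is treated as its
#' own bi-allelic marker: the returned dosage vector counts copies of that
#' allele (0/1/2), so the per-genotype dosages sum to 2 across alleles.
#'
#' @param calls character vector of diploid calls `"A/B"` (`NA` allowed).
#' @param sep allele separator within a call.
#' @return named list of dosage vectors, one per allele; an empty list (with
#'   a warning) if the marker carries a single allele.
#' @export
expand_multiallelic <- function(calls, sep = "/") {
  parts <- strsplit(as.character(calls), sep, fixed = TRUE)
  bad <- !vapply(parts, function(p) length(p) == 2 || all(is.na(p)),
                 logical(1))
  if (any(bad)) stop("calls must be 'allele1/allele2'")
  alleles <- sort(unique(unlist(parts)))
  alleles <- alleles[!is.na(alleles) & alleles != "NA"]
  if (length(alleles) < 2) {
    warning("single-allele marker: nothing to expand")
    return(list())
  }
  out <- lapply(alleles, function(a)
    vapply(parts, function(p)
      if (all(is.na(p))) NA_real_ else sum(p == a), numeric(1)))
  names(out) <- alleles
  out
}
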