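#' Genotype matrix with genetic map
#'
#' Bundles an allele-dosage matrix (genotypes x markers, entries 0/1/2 or
#' `NA`) with a genetic map (chromosome, position in centimorgan). Dosage
#' codes the count of the second (minor at construction time) allele, so
#' inbred lines carry 0 or 2 almost everywhere. Markers are stored sorted by
#' chromosome and map position; markers without a map position are retained
#' but flagged unmapped and excluded from LD windows and per-chromosome LD
#' matrices.
#'
#' @param dosages numeric matrix, genotypes in rows, markers in columns;
#'   entries must be 0, 1, 2 or `NA`. Row and column names are used as
#'   genotype and marker ids if `genotype_ids`/`marker_ids` are missing.
#' @param map data.frame with columns `marker`, `chromosome`, `position_cM`.
#'   Markers present in `dosages` but absent from `map` (or with `NA`
#'   position) are kept as unmapped.
#' @param genotype_ids,marker_ids optional character vectors of unique ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `map` (one row per marker, in column order), and logical
#'   `unmapped`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 2, 2, 0, 0, 2), nrow = 3,
#'          dimnames = list(c("v1", "v2", "v3"), c("m1", "m2"))),
#'   map = data.frame(marker = c("m1", "m2"), chromosome = "1A",
#'                    position_cM = c(0, 5)))
#' dim(g$dosages)
#' @export
genotype_matrix <- function(dosages, map = NULL, genotype_ids = NULL,
                            marker_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (!is.null(genotype_ids)) rownames(dosages) <- genotype_ids
  if (!is.null(marker_ids)) colnames(dosages) <- marker_ids
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("G", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated genotype ids")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicated marker ids")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; offending entries: ",
         paste(utils::head(which(bad)), collapse = ", "))
  storage.mode(dosages) <- "double"

  mk <- colnames(dosages)
  if (is.null(map)) {
    map <- data.frame(marker = mk, chromosome = NA_character_,
                      position_cM = NA_real_, stringsAsFactors = FALSE)
  } else {
    req <- c("marker", "chromosome", "position_cM")
    if (!all(req %in% names(map)))
      stop("map must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(map$marker)) stop("duplicated marker ids in map")
    map <- map[match(mk, map$marker), req]
    map$marker <- mk  # markers absent from map become unmapped rows
    rownames(map) <- NULL
  }
  unmapped <- is.na(map$position_cM) | is.na(map$chromosome)

  # sort mapped markers by (chromosome, cM); unmapped go last
  ord <- order(unmapped, as.character(map$chromosome), map$position_cM)
  dosages <- dosages[, ord, drop = FALSE]
  map <- map[ord, ]
  rownames(map) <- NULL
  structure(list(dosages = dosages, map = map, unmapped = unmapped[ord]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "genotypes x",
      ncol(x$dosages), "markers\n")
  cat("  chromosomes:",
      paste(unique(x$map$chromosome[!x$unmapped]), collapse = " "), "\n")
  if (any(x$unmapped)) cat("  unmapped markers:", sum(x$unmapped), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read / write genotype matrices
#'
#' The on-disk format is a tab-delimited dosage matrix (first column
#' `genotype`, remaining columns one per marker) plus a separate map file
#' with columns `marker`, `chromosome`, `position_cM`. Lines starting with
#' `#` are ignored.
#'
#' @param path path of the dosage matrix file.
#' @param map_path path of the map file; may be `NULL` (all markers unmapped).
#' @return `read_genotypes()` returns a [genotype_matrix]; `write_genotypes()`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path, map_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(tab)[1] != "genotype")
    stop("first column of a genotype file must be 'genotype'")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  vals <- m[!is.na(m)]
  if (!all(vals %in% c(0, 1, 2))) {
    bad <- which(!(m %in% c(0, 1, 2) | is.na(m)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage at data row %d, marker '%s'",
                 bad[1], colnames(m)[bad[2]]))
  }
  map <- NULL
  if (!is.null(map_path))
    map <- utils::read.delim(map_path, comment.char = "#",
                             stringsAsFactors = FALSE)
  genotype_matrix(m, map = map, genotype_ids = ids)
}

#' @rdname read_genotypes
#' @param geno a [genotype_matrix].
#' @export
write_genotypes <- function(geno, path, map_path = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  tab <- data.frame(genotype = rownames(geno$dosages), geno$dosages,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(geno$map[!geno$unmapped, ], map_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
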