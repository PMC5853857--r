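#' Long-format phenotype table
#'
#' Validates a long-format phenotype table. At plot level the required
#' columns are `genotype`, `environment`, `replicate`, `block`, `trait`,
#' `value` and the key (genotype, environment, replicate, trait) must be
#' unique. Stage-1 BLUEs drop `replicate`/`block`; stage-2 BLUEs additionally
#' drop `environment`.
#'
#' @param records data.frame with the columns above.
#' @param stage one of `"plot"`, `"stage1"`, `"stage2"`.
#' @return The validated data.frame with a `stage` attribute, class
#'   `trait_dataset`.
#' @export
trait_dataset <- function(records, stage = c("plot", "stage1", "stage2")) {
  stage <- match.arg(stage)
  req <- switch(stage,
                plot = c("genotype", "environment", "replicate", "block",
                         "trait", "value"),
                stage1 = c("genotype", "environment", "trait", "value"),
                stage2 = c("genotype", "trait", "value"))
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(records$value))
    stop("'value' must be numeric")
  if (any(!is.finite(records$value) & !is.na(records$value)))
    stop("non-finite trait values")
  keycols <- setdiff(req, c("block", "value"))
  key <- do.call(paste, c(records[keycols], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicated ", stage, "-level keys (", paste(keycols, collapse = ","),
         ")")
  out <- records[, union(req, names(records)), drop = FALSE]
  attr(out, "stage") <- stage
  class(out) <- c("trait_dataset", "data.frame")
  out
}

#' Read / write phenotype tables
#'
#' Comma-separated long format; columns as in [trait_dataset()]. Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @param stage passed to [trait_dataset()].
#' @return `read_phenotypes()` returns a [trait_dataset].
#' @export
read_phenotypes <- function(path, stage = "plot") {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("value" %in% names(tab) && !is.numeric(tab$value))
    stop("non-numeric entries in 'value' column")
  trait_dataset(tab, stage = stage)
}

#' @rdname read_phenotypes
#' @param phenos a [trait_dataset].
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.csv(as.data.frame(phenos), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
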