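#' Read and write pipeline tables
#'
#' Helpers for the plain-text formats the pipeline exchanges: long-format
#' phenotype CSV (`line_id`, `trait`, `condition`, `replicate`, `value`),
#' gene-by-sample count TSV (first column `gene_id`), and the sample-sheet
#' TSV (`sample_id`, `role`, `condition`, `replicate`). Writers prepend
#' `#`-comment header lines carrying provenance (tool version, seed,
#' config hash) which readers skip.
#'
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_trait_table <- function(path) {
  validate_trait_table(utils::read.csv(path, comment.char = "#",
                                       stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @param traits Long-format trait table.
#' @param header Character vector of provenance comment lines (without
#'   the leading `#`).
#' @export
write_trait_table <- function(traits, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(traits, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) stop("counts must be non-negative integers")
  m
}

#' @rdname pipeline_io
#' @param counts Count matrix, genes x samples.
#' @export
write_counts <- function(counts, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "condition", "replicate")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(s$role), c("maternal", "paternal", "hybrid"))
  if (length(bad)) stop("unknown sample roles: ", paste(bad, collapse = ", "))
  s
}

#' @rdname pipeline_io
#' @param samples Sample sheet data frame.
#' @export
write_sample_sheet <- function(samples, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(samples, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param table Any data frame to write as a headered TSV.
#' @export
write_tsv <- function(table, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
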