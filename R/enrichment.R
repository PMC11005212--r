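#' Hypergeometric over-representation test
#'
#' Upper-tail probability of drawing at least `k` annotated genes when
#' sampling `n` genes without replacement from a universe of `N` genes of
#' which `K` carry the annotation: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap (`0 <= k <= min(n, K)`).
#' @param n Query list size.
#' @param K Term size in the universe.
#' @param N Universe size.
#' @return Upper-tail p-value in (0, 1].
#' @examples
#' hypergeom_test(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(n > N) || any(K > N)) stop("n and K must not exceed N")
  if (any(k < 0) || any(k > pmin(n, K))) stop("k must lie in [0, min(n, K)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation analysis
#'
#' Tests each annotation term for over-representation in a gene list via
#' [hypergeom_test()], with Benjamini-Hochberg adjustment across the
#' tested terms. Query genes outside the universe are dropped with a
#' warning; terms with no members in the universe are dropped with a
#' message. Output rows are sorted by q, then p, then term ID.
#'
#' @param gene_list Character vector of query gene IDs.
#' @param annotation Named list of term member vectors (see
#'   [read_gmt()]).
#' @param universe Background gene IDs; default is the union of all term
#'   members (annotated-only background).
#' @param q_threshold Enrichment flag threshold (default 0.05).
#' @return Data frame: `term`, `description`, `k`, `n`, `K`, `N`, `p`,
#'   `q`, `enriched`.
#' @export
enrich <- function(gene_list, annotation, universe = NULL,
                   q_threshold = 0.05) {
  if (is.null(universe)) universe <- unique(unlist(annotation, use.names = FALSE))
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    gene_list <- intersect(gene_list, universe)
  }
  desc <- attr(annotation, "description")
  members <- lapply(annotation, function(g) intersect(unique(g), universe))
  empty <- vapply(members, length, 1L) == 0L
  if (any(empty)) {
    message(sprintf("enrich: %d term(s) empty after universe restriction dropped",
                    sum(empty)))
    members <- members[!empty]
  }
  if (length(gene_list) == 0L || length(members) == 0L) {
    warning("empty gene list or annotation after restriction")
    return(data.frame(term = character(0), description = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      enriched = logical(0)))
  }
  N <- length(universe)
  n <- length(gene_list)
  K <- vapply(members, length, 1L)
  k <- vapply(members, function(g) length(intersect(g, gene_list)), 1L)
  p <- hypergeom_test(k, n, K, N)
  q <- bh_adjust(p)
  out <- data.frame(term = names(members),
                    description = if (is.null(desc)) names(members)
                                  else unname(desc[names(members)]),
                    k = k, n = n, K = K, N = N, p = p, q = q,
                    enriched = q <= q_threshold, row.names = NULL)
  out[order(out$q, out$p, out$term), , drop = FALSE]
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-delimited gene-set format: one term per line, with the
#' term ID, a description, and the member gene IDs as remaining fields.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of member vectors with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop(sprintf("GMT line %d: need term, description, >= 1 gene",
                             which(bad)[1]))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate term IDs in GMT file")
  attr(sets, "description") <- stats::setNames(vapply(fields, `[`, "", 2L),
                                               names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member gene vectors; an optional
#'   `description` attribute supplies the second column.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(tm) {
    paste(c(tm, desc[[tm]], sets[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
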