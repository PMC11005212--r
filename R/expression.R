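#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed against a geometric-mean reference
#' over genes observed in every sample: for each sample, the factor is the
#' median of that sample's counts divided by the reference. Factors are
#' scaled to have geometric mean 1. If no gene is nonzero in all samples,
#' total-count scaling is used instead (with a message).
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("each sample needs at least one nonzero count")
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok)) {
    message("size_factors: no gene nonzero in all samples; using total-count scaling")
    sf <- colSums(counts)
  } else {
    logref <- rowMeans(log(counts[ok, , drop = FALSE]))
    sf <- apply(counts[ok, , drop = FALSE], 2L, function(col) {
      exp(stats::median(log(col) - logref))
    })
  }
  sf / exp(mean(log(sf)))
}

#' Normalize counts by size factors
#'
#' @param counts Count matrix, genes x samples.
#' @param sf Per-sample size factors (default: [size_factors()]).
#' @return Matrix of normalized counts (`counts[, j] / sf[j]`).
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts)) stop("one size factor per sample required")
  sweep(counts, 2L, sf, "/")
}

#' Reads per kilobase per million (RPKM)
#'
#' Length- and depth-normalized expression:
#' \eqn{RPKM = 10^9 \cdot count / (length \cdot library\_size)}.
#'
#' @param counts Count matrix, genes x samples.
#' @param gene_length Positive gene lengths in bp, one per gene.
#' @param library_size Per-sample totals (default `colSums(counts)`).
#' @return Matrix of RPKM values.
#' @export
rpkm <- function(counts, gene_length, library_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_length) != nrow(counts)) stop("one gene length per gene required")
  if (any(gene_length <= 0)) stop("gene lengths must be > 0")
  if (any(library_size <= 0)) stop("library sizes must be > 0")
  sweep(counts / gene_length, 2L, library_size, "/") * 1e9
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across a vector of p-values.
#'
#' @param pvalues Numeric vector in [0, 1] (`NA` allowed, propagated).
#' @return Adjusted q-values in [0, 1].
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks gene-wise sample variances toward a common prior estimated from
#' all genes, assuming the gene variances follow a scaled F distribution
#' around a prior variance `s0^2` with `d0` prior degrees of freedom
#' (estimated by matching moments of `log(s^2)`). The posterior variance
#' is the df-weighted average `(d0*s0^2 + df*s^2) / (d0 + df)` and tests
#' using it gain `d0` degrees of freedom.
#'
#' @param s2 Gene-wise sample variances.
#' @param df Residual degrees of freedom of each variance (scalar).
#' @return List with `var_post`, `df_prior` (`d0`, may be `Inf`), and
#'   `var_prior` (`s0^2`).
#' @export
squeeze_variances <- function(s2, df) {
  if (df < 1) stop("need at least 1 residual degree of freedom")
  pos <- is.finite(s2) & s2 > 0
  if (sum(pos) < 2L) {
    return(list(var_post = s2, df_prior = 0, var_prior = NA_real_))
  }
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e) - trigamma(df / 2)
  if (is.finite(ev) && ev > 0) {
    d0 <- 2 * trigamma_inverse(ev)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    var_post <- (d0 * s0 + df * pmax(s2, 0)) / (d0 + df)
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
    var_post <- rep(s0, length(s2))
  }
  list(var_post = var_post, df_prior = d0, var_prior = s0)
}

#' Two-group differential expression test
#'
#' Tests each gene for differential expression between two sample groups
#' on `log2(normalized count + pseudocount)` values. The default engine
#' (`"modt"`) is a moderated t-statistic: gene-wise pooled variances are
#' shrunk toward a common prior with [squeeze_variances()], and the
#' t-statistic gains the prior degrees of freedom. Engine `"welch"` is a
#' classical per-gene Welch t-test without moderation. Fold changes are
#' ratios of normalized group means (with the pseudocount guarding zeros),
#' reported as `log2fc = log2(mean_A / mean_B)`, i.e. group A relative to
#' group B. Genes with all-zero counts in both groups get `p = 1`.
#'
#' A gene is flagged as differentially expressed (DEG) when
#' `|log2fc| >= log2(min_fc)` and `q <= max_fdr`; q-values are
#' Benjamini-Hochberg adjusted within the contrast.
#'
#' @param counts Count matrix, genes x samples (named columns).
#' @param group_a,group_b Column names or indices of the two groups
#'   (>= 2 samples each).
#' @param sf Size factors for all columns of `counts` (default computed
#'   from the full matrix).
#' @param min_fc Fold-change threshold (default 2).
#' @param max_fdr FDR threshold (default 0.05).
#' @param engine `"modt"` (moderated, default) or `"welch"`.
#' @param pseudocount Added before log2 (default 1).
#' @param exclude_allzero If `TRUE`, genes all-zero in both groups are
#'   excluded from the FDR denominator (their `q` is `NA`); default
#'   `FALSE`.
#' @return Data frame: `gene`, `mean_a`, `mean_b`, `log2fc`, `p`, `q`,
#'   `deg` (logical), `direction` (`"up"`/`"down"`/`"ns"`, group A
#'   relative to group B).
#' @export
de_test <- function(counts, group_a, group_b, sf = size_factors(counts),
                    min_fc = 2, max_fdr = 0.05,
                    engine = c("modt", "welch"), pseudocount = 1,
                    exclude_allzero = FALSE) {
  engine <- match.arg(engine)
  counts <- as.matrix(counts)
  norm <- normalize_counts(counts, sf)
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 replicates per group")

  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  ya <- log2(a + pseudocount); yb <- log2(b + pseudocount)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- apply(ya, 1L, stats::var); vb <- apply(yb, 1L, stats::var)
  diff <- ma - mb

  if (engine == "modt") {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    sq <- squeeze_variances(s2, df = na + nb - 2)
    se <- sqrt(sq$var_post * (1 / na + 1 / nb))
    df_t <- sq$df_prior + na + nb - 2
    tstat <- diff / se
    p <- 2 * stats::pt(abs(tstat), df = df_t, lower.tail = FALSE)
  } else {
    se <- sqrt(va / na + vb / nb)
    df_t <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tstat <- diff / se
    p <- 2 * stats::pt(abs(tstat), df = df_t, lower.tail = FALSE)
  }
  p[!is.finite(p)] <- 1  # zero-variance, zero-difference genes
  p <- pmin(p, 1)

  allzero <- rowSums(counts[, c(group_a, group_b), drop = FALSE]) == 0
  p[allzero] <- 1
  if (exclude_allzero) {
    q <- rep(NA_real_, length(p))
    q[!allzero] <- bh_adjust(p[!allzero])
  } else {
    q <- bh_adjust(p)
  }

  deg <- !is.na(q) & q <= max_fdr & abs(log2fc) >= log2(min_fc)
  direction <- ifelse(deg, ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(gene = if (is.null(rownames(counts))) seq_len(nrow(counts))
                    else rownames(counts),
             mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
             p = p, q = q, deg = deg, direction = direction,
             row.names = NULL)
}
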