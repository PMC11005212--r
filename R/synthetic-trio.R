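#' Expression profile codes and categories
#'
#' The eight hybrid-parent expression profiles and the coarse category
#' each belongs to. P0/P7 are additive (hybrid at the mid-parent, parents
#' differing; P0 maternal-low, P7 maternal-high), P1/P6 maternal-expression
#' dominance (hybrid equals the maternal parent; P1 maternal-low, P6
#' maternal-high), P3/P4 paternal-expression dominance (P3 paternal-low,
#' P4 paternal-high), P5 transgressive up-regulation and P2 transgressive
#' down-regulation (hybrid significantly above/below both parents).
#'
#' @return Named character vector mapping profile code to category.
#' @export
profile_categories <- function() {
  c(P0 = "additive", P7 = "additive",
    P1 = "maternal-dominant", P6 = "maternal-dominant",
    P3 = "paternal-dominant", P4 = "paternal-dominant",
    P5 = "transgressive-up", P2 = "transgressive-down",
    unclassified = "null")
}

#' Configuration for the trio count simulator
#'
#' Defines a hybrid-parent trio RNA-seq design: a gene-by-sample count
#' matrix for the maternal parent, paternal parent and hybrid, with a
#' fixed number of replicates per group, where each gene carries a known
#' expression class. Classes are the eight profiles of
#' [profile_categories()] plus `null` (all three groups share one mean).
#'
#' Group means are built from a baseline drawn log-uniformly over
#' `mean_log_range` and separated by `effect_size` where the class demands
#' a difference (for additive classes the hybrid sits exactly at the
#' mid-parent). Counts are negative binomial with variance
#' \eqn{\mu + \phi \mu^2}; per-sample library-size factors drawn uniformly
#' from `lib_factor_range` scale the means so that normalization is
#' exercised downstream.
#'
#' @param n_genes Number of genes.
#' @param reps_per_group Replicates per group (default 3).
#' @param class_proportions Named fractions over
#'   `c(paste0("profile", 0:7), "null")`, summing to 1. Default: 0.075 per
#'   profile and 0.4 null.
#' @param effect_size Fold separation between groups meant to differ
#'   (> 1, default 4).
#' @param dispersion Negative-binomial dispersion \eqn{\phi \ge 0}
#'   (0 = Poisson; default 0.05).
#' @param mean_log_range Range of baseline natural-log means (default
#'   `log(c(100, 5000))`).
#' @param lib_factor_range Range of per-sample library-size factors
#'   (default `c(0.7, 1.3)`).
#' @param condition Condition label for the sample sheet (default
#'   `"stress"`).
#' @param seed Integer seed.
#' @return A `trio_sim_config` list.
#' @export
trio_sim_config <- function(n_genes = 5000, reps_per_group = 3,
                            class_proportions = NULL,
                            effect_size = 4, dispersion = 0.05,
                            mean_log_range = log(c(100, 5000)),
                            lib_factor_range = c(0.7, 1.3),
                            condition = "stress",
                            seed = 1L) {
  classes <- c(paste0("profile", 0:7), "null")
  if (is.null(class_proportions)) {
    class_proportions <- stats::setNames(c(rep(0.075, 8), 0.4), classes)
  }
  if (!all(names(class_proportions) %in% classes)) {
    stop("unknown class names in class_proportions")
  }
  full <- stats::setNames(numeric(length(classes)), classes)
  full[names(class_proportions)] <- class_proportions
  if (abs(sum(full) - 1) > 1e-8) stop("class_proportions must sum to 1")
  if (any(full < 0)) stop("class_proportions must be non-negative")
  if (effect_size <= 1) stop("effect_size must be > 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(mean_log_range) != 2L || diff(mean_log_range) < 0) {
    stop("mean_log_range must be an increasing pair")
  }
  structure(list(n_genes = as.integer(n_genes),
                 reps_per_group = as.integer(reps_per_group),
                 class_proportions = full, effect_size = effect_size,
                 dispersion = dispersion, mean_log_range = mean_log_range,
                 lib_factor_range = lib_factor_range,
                 condition = condition, seed = as.integer(seed)),
            class = "trio_sim_config")
}

# Group means (maternal, paternal, hybrid) implied by a class, given a
# baseline mean mu and fold separation e. Orderings follow
# profile_categories(): e.g. profile6 = maternal dominance with the
# maternal parent high.
trio_class_means <- function(class, mu, e) {
  switch(class,
    null     = c(m = mu,     p = mu,     h = mu),
    profile0 = c(m = mu,     p = e * mu, h = (mu + e * mu) / 2),
    profile7 = c(m = e * mu, p = mu,     h = (mu + e * mu) / 2),
    profile1 = c(m = mu,     p = e * mu, h = mu),
    profile6 = c(m = e * mu, p = mu,     h = e * mu),
    profile3 = c(m = e * mu, p = mu,     h = mu),
    profile4 = c(m = mu,     p = e * mu, h = e * mu),
    profile5 = c(m = mu,     p = mu,     h = e * mu),
    profile2 = c(m = e * mu, p = e * mu, h = mu),
    stop("unknown class: ", class))
}

# True profile label the classifier should recover for a simulated class.
true_profile_label <- function(class) {
  ifelse(class == "null", "unclassified",
         sub("^profile", "P", class))
}

#' Simulate a hybrid-parent trio count matrix
#'
#' Draws per-gene classes from the configured proportions, builds the
#' implied group means, and samples negative-binomial counts with
#' per-sample library-size factors. Sample columns are named
#' `<role>_<condition>_<replicate>`.
#'
#' @param cfg A [trio_sim_config()].
#' @return List with `counts` (integer matrix, genes x samples), `samples`
#'   (data frame: `sample_id`, `role`, `condition`, `replicate`,
#'   `lib_factor`), `truth` (data frame: `gene_id`, `class`,
#'   `true_profile`, `true_category`, and the three true group means), and
#'   `config`.
#' @export
simulate_trio_counts <- function(cfg) {
  stopifnot(inherits(cfg, "trio_sim_config"))
  set.seed(cfg$seed)
  classes <- names(cfg$class_proportions)
  gene_class <- sample(classes, cfg$n_genes, replace = TRUE,
                       prob = cfg$class_proportions)
  mu0 <- exp(stats::runif(cfg$n_genes, cfg$mean_log_range[1],
                          cfg$mean_log_range[2]))
  mns <- t(vapply(seq_len(cfg$n_genes),
                  function(i) trio_class_means(gene_class[i], mu0[i],
                                               cfg$effect_size),
                  numeric(3)))
  roles <- c("maternal", "paternal", "hybrid")
  nrep <- cfg$reps_per_group
  samples <- data.frame(
    sample_id = paste(rep(roles, each = nrep), cfg$condition,
                      rep(seq_len(nrep), times = 3), sep = "_"),
    role = rep(roles, each = nrep),
    condition = cfg$condition,
    replicate = rep(seq_len(nrep), times = 3))
  samples$lib_factor <- stats::runif(nrow(samples), cfg$lib_factor_range[1],
                                     cfg$lib_factor_range[2])

  mu_mat <- cbind(m = mns[, "m"], p = mns[, "p"], h = mns[, "h"])
  role_idx <- match(samples$role, roles)  # 1 m, 2 p, 3 h
  counts <- matrix(0L, cfg$n_genes, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    mu_j <- mu_mat[, role_idx[j]] * samples$lib_factor[j]
    counts[, j] <- if (cfg$dispersion == 0) {
      stats::rpois(cfg$n_genes, mu_j)
    } else {
      stats::rnbinom(cfg$n_genes, mu = mu_j, size = 1 / cfg$dispersion)
    }
  }
  storage.mode(counts) <- "integer"
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  dimnames(counts) <- list(gene_ids, samples$sample_id)
  cats <- profile_categories()
  truth <- data.frame(gene_id = gene_ids, class = gene_class,
                      true_profile = true_profile_label(gene_class),
                      true_category = unname(cats[true_profile_label(gene_class)]),
                      mean_maternal = mu_mat[, "m"], mean_paternal = mu_mat[, "p"],
                      mean_hybrid = mu_mat[, "h"])
  list(counts = counts, samples = samples, truth = truth, config = cfg)
}

#' Simulate a GMT-style annotation over a gene universe
#'
#' Builds `n_terms` gene sets by sampling without replacement from the
#' supplied universe, with sizes drawn uniformly from `size_range`.
#' Useful for exercising enrichment end to end on synthetic data; set
#' membership is random, so no term is truly enriched for a random query
#' list.
#'
#' @param genes Character vector, the annotation universe.
#' @param n_terms Number of terms (default 50).
#' @param size_range Term size range (default `c(10, 200)`).
#' @param seed Integer seed.
#' @return A named list of gene-ID vectors (an annotation usable by
#'   [enrich()]), with a `description` attribute per term.
#' @export
simulate_annotation <- function(genes, n_terms = 50,
                                size_range = c(10, 200), seed = 1L) {
  set.seed(seed)
  size_range[2] <- min(size_range[2], length(genes))
  sets <- lapply(seq_len(n_terms), function(i) {
    sz <- sample(seq(size_range[1], size_range[2]), 1L)
    sample(genes, sz)
  })
  names(sets) <- sprintf("TERM:%04d", seq_len(n_terms))
  sets
}
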