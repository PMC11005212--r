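#' Test hybrid expression against the mid-parent value
#'
#' For each gene, tests the hybrid's replicate-level normalized expression
#' against the mid-parent reference (average of the maternal and paternal
#' group means), on the log2 scale with a pseudocount. Because the
#' reference is itself estimated from the parental replicates, its
#' sampling variance is propagated into the test's standard error (delta
#' method on `log2(mid + pseudocount)`); ignoring it would inflate the
#' type-I error on truly additive genes. Replicate variances are
#' moderated across genes as in [de_test()]. The returned ratio is the
#' signed `log2(hybrid mean / mid-parent mean)`; genes with a zero
#' mid-parent mean get `p = 1` and an `NA` ratio.
#'
#' @param hybrid,maternal,paternal Normalized expression matrices
#'   (genes x replicates), rows aligned.
#' @param pseudocount Added before log2 (default 1).
#' @param moderate Shrink replicate variances across genes (default
#'   `TRUE`).
#' @return Data frame: `log2_ratio`, `p`, `q` (BH across genes).
#' @export
midparent_test <- function(hybrid, maternal, paternal, pseudocount = 1,
                           moderate = TRUE) {
  hybrid <- as.matrix(hybrid)
  maternal <- as.matrix(maternal)
  paternal <- as.matrix(paternal)
  nh <- ncol(hybrid); nm <- ncol(maternal); np <- ncol(paternal)
  if (nh < 2L || nm < 2L || np < 2L) stop("need >= 2 replicates per role")
  mmean <- rowMeans(maternal); pmean <- rowMeans(paternal)
  mid <- (mmean + pmean) / 2
  hmean <- rowMeans(hybrid)
  log2_ratio <- ifelse(mid > 0 & hmean > 0, log2(hmean / mid), NA_real_)

  yh <- log2(hybrid + pseudocount)
  ym <- log2(maternal + pseudocount)
  yp <- log2(paternal + pseudocount)
  mu0 <- log2(mid + pseudocount)
  diff <- rowMeans(yh) - mu0
  vh <- apply(yh, 1L, stats::var)
  vm <- apply(ym, 1L, stats::var)
  vp <- apply(yp, 1L, stats::var)
  if (moderate) {
    vh <- squeeze_variances(vh, df = nh - 1)$var_post
    sqm <- squeeze_variances(vm, df = nm - 1)
    vm <- sqm$var_post
    vp <- squeeze_variances(vp, df = np - 1)$var_post
    df_t <- (if (is.finite(sqm$df_prior)) sqm$df_prior else 1e6) +
      nh + nm + np - 3
  } else {
    df_t <- nh - 1
  }
  # delta method: var(log2(mid+pc)) from the parental log-scale variances
  ref_var <- ((mmean + pseudocount)^2 * vm / nm +
              (pmean + pseudocount)^2 * vp / np) /
    (4 * (mid + pseudocount)^2)
  se <- sqrt(vh / nh + ref_var)
  p <- 2 * stats::pt(abs(diff / se), df = df_t, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p[mid == 0] <- 1
  log2_ratio[mid == 0] <- NA_real_
  data.frame(log2_ratio = log2_ratio, p = pmin(p, 1), q = bh_adjust(pmin(p, 1)))
}

#' Build the per-gene contrast set for profile classification
#'
#' Runs the four contrasts the eight-profile classifier needs on one
#' condition of a trio experiment: hybrid vs maternal, hybrid vs paternal,
#' maternal vs paternal (two-group tests via [de_test()]), and hybrid vs
#' mid-parent ([midparent_test()]). Size factors are computed once on the
#' full selected matrix so all contrasts share one normalization.
#'
#' @param counts Count matrix, genes x samples.
#' @param samples Sample sheet with `sample_id`, `role`
#'   (`maternal`/`paternal`/`hybrid`), `condition`, `replicate`.
#' @param condition Which condition to analyze (default: the only one
#'   present; required if several).
#' @param engine,pseudocount Passed to [de_test()].
#' @return Data frame of class `trio_test_set`: group means, per-contrast
#'   `log2fc`/`q` columns (`hm` hybrid vs maternal, `hp` hybrid vs
#'   paternal, `mp` maternal vs paternal, `hmid` hybrid vs mid-parent).
#' @export
trio_test_set <- function(counts, samples, condition = NULL,
                          engine = "modt", pseudocount = 1) {
  counts <- as.matrix(counts)
  need <- c("sample_id", "role", "condition", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (!all(samples$sample_id %in% colnames(counts))) {
    stop("sample sheet lists samples absent from the count matrix")
  }
  if (is.null(condition)) {
    condition <- unique(samples$condition)
    if (length(condition) > 1L) stop("multiple conditions present; pick one")
  }
  sheet <- samples[samples$condition == condition, ]
  grp <- function(role) sheet$sample_id[sheet$role == role]
  for (role in c("maternal", "paternal", "hybrid")) {
    if (length(grp(role)) < 2L) {
      stop(sprintf("role '%s' needs >= 2 replicates in condition '%s'",
                   role, condition))
    }
  }
  sel <- counts[, sheet$sample_id, drop = FALSE]
  sf <- size_factors(sel)
  norm <- normalize_counts(sel, sf)

  hm <- de_test(sel, grp("hybrid"), grp("maternal"), sf = sf,
                engine = engine, pseudocount = pseudocount)
  hp <- de_test(sel, grp("hybrid"), grp("paternal"), sf = sf,
                engine = engine, pseudocount = pseudocount)
  mp <- de_test(sel, grp("maternal"), grp("paternal"), sf = sf,
                engine = engine, pseudocount = pseudocount)
  hmid <- midparent_test(norm[, grp("hybrid"), drop = FALSE],
                         norm[, grp("maternal"), drop = FALSE],
                         norm[, grp("paternal"), drop = FALSE],
                         pseudocount = pseudocount)

  out <- data.frame(
    gene = hm$gene,
    mean_hybrid = hm$mean_a, mean_maternal = hm$mean_b,
    mean_paternal = hp$mean_b,
    mean_midparent = (hm$mean_b + hp$mean_b) / 2,
    log2fc_hm = hm$log2fc, q_hm = hm$q,
    log2fc_hp = hp$log2fc, q_hp = hp$q,
    log2fc_mp = mp$log2fc, q_mp = mp$q,
    log2fc_hmid = hmid$log2_ratio, q_hmid = hmid$q)
  class(out) <- c("trio_test_set", "data.frame")
  attr(out, "condition") <- condition
  out
}

#' Assign the eight expression profiles
#'
#' Classifies each gene of a [trio_test_set()] into one of the eight
#' hybrid-parent expression profiles or `unclassified`, by a fixed
#' decision tree over the four contrasts (a contrast is "significant" when
#' its q-value is at most `alpha`; directions come from the group means):
#' \enumerate{
#'   \item hybrid significantly above both parents: P5 (transgressive up);
#'   \item hybrid significantly below both parents: P2 (transgressive
#'     down);
#'   \item hybrid not different from the maternal parent and significantly
#'     different from the paternal parent: maternal dominance, P6 if the
#'     maternal mean exceeds the paternal, P1 otherwise;
#'   \item hybrid not different from the paternal parent and significantly
#'     different from the maternal parent: paternal dominance, P3 if the
#'     paternal mean is the lower one, P4 otherwise;
#'   \item parents significantly different and hybrid not different from
#'     the mid-parent: additive, P0 if the maternal mean is the lower one,
#'     P7 otherwise;
#'   \item otherwise unclassified.
#' }
#' Transgressive clauses take precedence over dominance, and dominance
#' over additivity, so a gene satisfying several clauses receives the
#' stronger (non-additive) call only when both of its defining contrasts
#' are significant.
#'
#' @param tests A [trio_test_set()] (or data frame with its columns).
#' @param alpha Significance threshold on contrast q-values (default
#'   0.05).
#' @return Data frame: `gene`, `profile` (factor `P0..P7, unclassified`),
#'   `category`, and the four contrast q-values.
#' @export
assign_profiles <- function(tests, alpha = 0.05) {
  sig_hm <- !is.na(tests$q_hm) & tests$q_hm <= alpha
  sig_hp <- !is.na(tests$q_hp) & tests$q_hp <= alpha
  sig_mp <- !is.na(tests$q_mp) & tests$q_mp <= alpha
  sig_hmid <- !is.na(tests$q_hmid) & tests$q_hmid <= alpha
  h <- tests$mean_hybrid; m <- tests$mean_maternal; p <- tests$mean_paternal

  above_m <- sig_hm & h > m; below_m <- sig_hm & h < m
  above_p <- sig_hp & h > p; below_p <- sig_hp & h < p

  profile <- rep("unclassified", nrow(tests))
  profile[above_m & above_p] <- "P5"
  profile[below_m & below_p] <- "P2"

  open <- profile == "unclassified"
  mat_dom <- open & !sig_hm & sig_hp
  profile[mat_dom & m > p] <- "P6"
  profile[mat_dom & m < p] <- "P1"

  open <- profile == "unclassified"
  pat_dom <- open & !sig_hp & sig_hm
  profile[pat_dom & p < m] <- "P3"
  profile[pat_dom & p > m] <- "P4"

  open <- profile == "unclassified"
  addv <- open & sig_mp & !sig_hmid
  profile[addv & m < p] <- "P0"
  profile[addv & m > p] <- "P7"

  cats <- profile_categories()
  data.frame(gene = tests$gene,
             profile = factor(profile,
                              levels = c(paste0("P", 0:7), "unclassified")),
             category = unname(cats[profile]),
             q_hm = tests$q_hm, q_hp = tests$q_hp,
             q_mp = tests$q_mp, q_hmid = tests$q_hmid,
             row.names = NULL)
}

#' Summarize profile assignments
#'
#' Per-profile gene counts and the non-additive fraction: genes assigned
#' to any dominance or transgressive profile (P1-P6), restricted to a DEG
#' universe, as a percentage of that universe.
#'
#' @param assignments Output of [assign_profiles()].
#' @param deg_universe Gene IDs forming the denominator (e.g. genes
#'   differentially expressed in at least one hybrid-parent contrast).
#'   Default: all assigned genes.
#' @return List with `profile_counts` (named vector over
#'   `P0..P7, unclassified`), `n_universe`, `n_non_additive`, and
#'   `non_additive_pct`.
#' @export
profile_summary <- function(assignments, deg_universe = assignments$gene) {
  if (length(deg_universe) == 0L) stop("empty DEG universe")
  counts <- table(assignments$profile)
  non_add <- paste0("P", 1:6)
  in_univ <- assignments$gene %in% deg_universe
  k <- sum(in_univ & assignments$profile %in% non_add)
  list(profile_counts = c(counts),
       n_universe = length(unique(deg_universe)),
       n_non_additive = k,
       non_additive_pct = non_additive_fraction(k, length(unique(deg_universe))))
}

#' Non-additive fraction
#'
#' Percentage of a gene universe falling in non-additive (dominant or
#' transgressive) expression profiles.
#'
#' @param n_non_additive Count of non-additive genes.
#' @param n_universe Size of the gene universe (> 0).
#' @return Percentage `100 * n_non_additive / n_universe`.
#' @examples
#' non_additive_fraction(25829, 65547)  # 39.41 (to two decimals)
#' @export
non_additive_fraction <- function(n_non_additive, n_universe) {
  if (n_universe <= 0) stop("empty gene universe")
  if (n_non_additive < 0 || n_non_additive > n_universe) {
    stop("non-additive count must lie in [0, n_universe]")
  }
  100 * n_non_additive / n_universe
}
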