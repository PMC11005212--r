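#' Tolerance report for an F1 population
#'
#' Runs the full phenotypic evaluation on a long-format trait table: per
#' line and trait, the stress/control ratio (waterlogging tolerance index,
#' WI); per trait, min-max membership values across all entries (parents
#' included); per line, the composite membership score (MFVW, the mean of
#' per-trait membership values); and a five-level tolerance grade for the
#' F1 lines based on the mean and standard deviation of the F1 MFVW
#' distribution.
#'
#' Traits listed in `score_traits` are measured only under treatment (a
#' visual damage score has no control counterpart); their treatment mean
#' enters the membership function directly instead of a WI. A trait whose
#' index is constant across the population carries no ranking information;
#' it is dropped from the composite score with a warning.
#'
#' @param traits Data frame with columns `line_id`, `trait`, `condition`
#'   (`"control"`/`"treatment"`), `replicate`, `value`.
#' @param maternal_id,paternal_id Line IDs of the two parents.
#' @param score_traits Character vector of treatment-only traits (default
#'   `"Score"`).
#' @param grade_multipliers Inner/outer SD multipliers for the grade bands
#'   (default `c(1, 1.64)`).
#' @return A list of class `tolerance_report` with elements
#'   \item{index}{data frame `line_id` x `trait` of tolerance indices (WI,
#'     or raw treatment mean for score traits)}
#'   \item{membership}{data frame of per-trait membership values}
#'   \item{lines}{data frame with `line_id`, `mfvw`, `grade` (`NA` grade for
#'     the parents), and `is_parent`}
#'   \item{dropped_traits}{traits excluded from MFVW as degenerate}
#' @export
tolerance_report <- function(traits, maternal_id, paternal_id,
                             score_traits = "Score",
                             grade_multipliers = c(1, 1.64)) {
  traits <- validate_trait_table(traits)
  ids <- unique(traits$line_id)
  if (!all(c(maternal_id, paternal_id) %in% ids)) {
    stop("parent IDs not found in trait table")
  }
  trait_names <- unique(traits$trait)

  grp <- stats::aggregate(value ~ line_id + trait + condition, traits, mean)
  wi_one <- function(tr) {
    g <- grp[grp$trait == tr, ]
    trt <- g[g$condition == "treatment", ]
    idx <- stats::setNames(trt$value, trt$line_id)
    if (!(tr %in% score_traits)) {
      ctl <- g[g$condition == "control", ]
      if (!all(trt$line_id %in% ctl$line_id)) {
        stop(sprintf("trait '%s': missing control measurements", tr))
      }
      ctl_v <- stats::setNames(ctl$value, ctl$line_id)[trt$line_id]
      idx <- waterlogging_index(idx, ctl_v)
    }
    idx[ids]
  }
  index <- as.data.frame(lapply(stats::setNames(trait_names, trait_names), wi_one))
  rownames(index) <- ids

  dropped <- character(0)
  membership <- index
  for (tr in trait_names) {
    v <- index[[tr]]
    if (length(unique(v)) < 2L) {
      warning(sprintf("trait '%s' has a degenerate index; dropped from MFVW", tr))
      dropped <- c(dropped, tr)
      membership[[tr]] <- NA_real_
    } else {
      membership[[tr]] <- membership_values(v)
    }
  }

  keep <- setdiff(trait_names, dropped)
  if (length(keep) == 0L) stop("no usable traits left for MFVW")
  mfvw_i <- apply(membership[, keep, drop = FALSE], 1L, mfvw)

  is_parent <- ids %in% c(maternal_id, paternal_id)
  f1_scores <- mfvw_i[!is_parent]
  grade <- rep(NA_character_, length(ids))
  if (length(f1_scores) >= 2L) {
    g <- tolerance_grade(f1_scores, mean(f1_scores), stats::sd(f1_scores),
                         multipliers = grade_multipliers)
    grade[!is_parent] <- as.character(g)
  }
  lines <- data.frame(line_id = ids, mfvw = unname(mfvw_i),
                      grade = factor(grade, levels = c("HWT", "WT", "MWT", "WS", "HWS")),
                      is_parent = is_parent, row.names = NULL)

  structure(list(index = index, membership = membership, lines = lines,
                 dropped_traits = dropped,
                 maternal_id = maternal_id, paternal_id = paternal_id),
            class = "tolerance_report")
}

#' @export
print.tolerance_report <- function(x, ...) {
  n_f1 <- sum(!x$lines$is_parent)
  cat(sprintf("Tolerance report: %d F1 lines + 2 parents, %d traits\n",
              n_f1, ncol(x$index)))
  if (length(x$dropped_traits)) {
    cat("  dropped (degenerate):", paste(x$dropped_traits, collapse = ", "), "\n")
  }
  tab <- table(x$lines$grade[!x$lines$is_parent])
  cat("  grades:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Population heterosis report
#'
#' Per-trait heterosis of an F1 population relative to its parents,
#' computed on the tolerance indices from [tolerance_report()] (and on the
#' composite MFVW). Each F1 line contributes one observation (its index);
#' mid-parent heterosis (MPH) and high-parent heterosis (HPH) are the
#' percent deviations of the F1 mean from the mid-parent and high-parent
#' values, each with a two-sided one-sample t-test across lines.
#'
#' @param tol A `tolerance_report`.
#' @return Data frame with one row per trait plus `"MFVW"`: parental
#'   values, `mpv`, `f1_mean`, `cv` (percent, across F1 lines), `mph`,
#'   `hph`, their p-values and significance stars.
#' @export
heterosis_report <- function(tol) {
  stopifnot(inherits(tol, "tolerance_report"))
  idx <- cbind(tol$index, MFVW = tol$lines$mfvw)
  ids <- tol$lines$line_id
  f1 <- !tol$lines$is_parent
  rows <- lapply(colnames(idx), function(tr) {
    v <- idx[[tr]]
    mm <- v[ids == tol$maternal_id]
    pm <- v[ids == tol$paternal_id]
    h <- heterosis(v[f1], mm, pm)
    data.frame(trait = tr, maternal = mm, paternal = pm, mpv = h$mpv,
               f1_mean = h$mean, cv = coefficient_of_variation(v[f1]),
               mph = h$mph, hph = h$hph, p_mph = h$p_mph, p_hph = h$p_hph,
               sig_mph = signif_stars(h$p_mph), sig_hph = signif_stars(h$p_hph))
  })
  do.call(rbind, rows)
}

#' Single-line heterosis
#'
#' Heterosis of one F1 line relative to the parents, per trait, using the
#' line's replicate-level indices as observations: each treatment replicate
#' is divided by the line's control mean (or used directly for
#' treatment-only score traits), giving a within-line distribution to test
#' against the parental MPV and HPV.
#'
#' @param traits Long-format trait table (see [tolerance_report()]).
#' @param line_id The F1 line to evaluate.
#' @param maternal_id,paternal_id Parent line IDs.
#' @param score_traits Treatment-only traits (default `"Score"`).
#' @return Data frame, one row per trait, with `mph`, `hph`, p-values and
#'   stars.
#' @export
line_heterosis <- function(traits, line_id, maternal_id, paternal_id,
                           score_traits = "Score") {
  traits <- validate_trait_table(traits)
  per_rep_index <- function(id, tr) {
    d <- traits[traits$line_id == id & traits$trait == tr, ]
    trt <- d$value[d$condition == "treatment"]
    if (tr %in% score_traits) return(trt)
    ctl <- mean(d$value[d$condition == "control"])
    waterlogging_index(trt, ctl)
  }
  trait_names <- unique(traits$trait)
  rows <- lapply(trait_names, function(tr) {
    v <- per_rep_index(line_id, tr)
    mm <- mean(per_rep_index(maternal_id, tr))
    pm <- mean(per_rep_index(paternal_id, tr))
    h <- heterosis(v, mm, pm)
    data.frame(trait = tr, line_mean = h$mean, maternal = mm, paternal = pm,
               mpv = h$mpv, mph = h$mph, hph = h$hph,
               p_mph = h$p_mph, p_hph = h$p_hph,
               sig_mph = signif_stars(h$p_mph), sig_hph = signif_stars(h$p_hph))
  })
  do.call(rbind, rows)
}

#' Validate a long-format trait table
#'
#' Checks the schema (`line_id`, `trait`, `condition`, `replicate`,
#' `value`), condition levels, and positivity of measurements.
#'
#' @param traits Data frame to validate.
#' @return The validated data frame (conditions normalized to character).
#' @keywords internal
validate_trait_table <- function(traits) {
  need <- c("line_id", "trait", "condition", "replicate", "value")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("trait table missing columns: ", paste(miss, collapse = ", "))
  traits$condition <- as.character(traits$condition)
  bad <- setdiff(unique(traits$condition), c("control", "treatment"))
  if (length(bad)) stop("unknown condition levels: ", paste(bad, collapse = ", "))
  if (any(!is.finite(traits$value))) stop("non-finite trait values")
  traits
}
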