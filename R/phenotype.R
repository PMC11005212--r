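#' Waterlogging tolerance index
#'
#' Ratio of a line's trait value under stress to its value under control
#' conditions (WI). Values near 1 indicate no stress penalty; values near 0
#' indicate near-total loss of the trait under stress.
#'
#' @param treatment_mean Numeric vector of trait means under treatment.
#' @param control_mean Numeric vector of trait means under control; must be
#'   strictly positive.
#' @return Numeric vector `treatment_mean / control_mean`.
#' @examples
#' waterlogging_index(0.5, 1.0)
#' @export
waterlogging_index <- function(treatment_mean, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop("control_mean must be finite and > 0")
  }
  treatment_mean / control_mean
}

#' Membership function values
#'
#' Min-max rescaling of a tolerance index across a population: the smallest
#' observed value maps to 0, the largest to 1, intermediate values linearly.
#' Used to put traits with different units on a common [0, 1] scale before
#' averaging into a composite tolerance score.
#'
#' @param x Numeric vector of tolerance indices for one trait across lines;
#'   must contain at least two distinct finite values.
#' @return Numeric vector in [0, 1], same length and names as `x`.
#' @export
membership_values <- function(x) {
  if (any(!is.finite(x))) stop("membership_values: all values must be finite")
  rng <- range(x)
  if (length(x) < 2L || rng[1] == rng[2]) {
    stop("membership_values: need >= 2 distinct values (degenerate scale)")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Composite membership score (MFVW)
#'
#' Arithmetic mean of a line's per-trait membership values. Higher values
#' indicate higher overall stress tolerance.
#'
#' @param membership Numeric vector of per-trait membership values in [0, 1].
#' @return Scalar mean in [0, 1].
#' @export
mfvw <- function(membership) {
  membership <- membership[!is.na(membership)]
  if (length(membership) == 0L) stop("mfvw: no trait membership values")
  if (any(membership < 0 | membership > 1)) {
    stop("mfvw: membership values must lie in [0, 1]")
  }
  mean(membership)
}

#' Five-level tolerance grade
#'
#' Classifies composite tolerance scores into five grades relative to the
#' population mean `m` and standard deviation `s`:
#' \describe{
#'   \item{HWT}{highly tolerant, `x >= m + k2*s`}
#'   \item{WT}{tolerant, `m + k1*s <= x < m + k2*s`}
#'   \item{MWT}{moderately tolerant, `m - k1*s <= x < m + k1*s`}
#'   \item{WS}{sensitive, `m - k2*s <= x < m - k1*s`}
#'   \item{HWS}{highly sensitive, `x < m - k2*s`}
#' }
#' with default multipliers `k1 = 1` and `k2 = 1.64`. The upper boundary of
#' each band is closed on the tolerant side, so a score exactly at
#' `m + 1.64 s` is graded HWT.
#'
#' @param x Numeric vector of composite scores to grade.
#' @param center Population mean of the scores.
#' @param sd Population standard deviation (`>= 0`).
#' @param multipliers Length-2 numeric, the inner and outer SD multipliers
#'   (default `c(1, 1.64)`).
#' @return Factor with levels `HWT, WT, MWT, WS, HWS`.
#' @export
tolerance_grade <- function(x, center, sd, multipliers = c(1, 1.64)) {
  stopifnot(length(multipliers) == 2L, multipliers[1] < multipliers[2])
  if (any(sd < 0)) stop("tolerance_grade: sd must be >= 0")
  k1 <- multipliers[1]
  k2 <- multipliers[2]
  g <- ifelse(x >= center + k2 * sd, "HWT",
       ifelse(x >= center + k1 * sd, "WT",
       ifelse(x >= center - k1 * sd, "MWT",
       ifelse(x >= center - k2 * sd, "WS", "HWS"))))
  factor(g, levels = c("HWT", "WT", "MWT", "WS", "HWS"))
}

#' Mid-parent and high-parent values
#'
#' `mid_parent_value` is the average of the two parental means; the
#' high-parent value is the larger of the two. These are the references for
#' mid-parent and high-parent heterosis.
#'
#' @param maternal_mean,paternal_mean Parental trait means.
#' @return Numeric vector.
#' @examples
#' mid_parent_value(0.44, 0.08)  # 0.26
#' @export
mid_parent_value <- function(maternal_mean, paternal_mean) {
  (maternal_mean + paternal_mean) / 2
}

#' @rdname mid_parent_value
#' @export
high_parent_value <- function(maternal_mean, paternal_mean) {
  pmax(maternal_mean, paternal_mean)
}

#' Mid-parent and high-parent heterosis
#'
#' Percent deviation of offspring performance from the mid-parent value
#' (MPH) and from the better parent (HPH):
#' \deqn{MPH = 100 (\bar{F1} - MPV)/MPV, \quad HPH = 100 (\bar{F1} - HPV)/HPV}
#' When `values` has two or more observations (population line means, or
#' replicate values for a single line), two-sided one-sample t-tests of the
#' observations against MPV and HPV give the significance of each component.
#'
#' @param values Numeric vector of offspring values (or a single value, in
#'   which case p-values are `NA`).
#' @param maternal_mean,paternal_mean Parental means; the implied MPV and
#'   HPV must be nonzero.
#' @return A one-row data frame with columns `n`, `mean`, `mpv`, `hpv`,
#'   `mph`, `hph`, `p_mph`, `p_hph`.
#' @export
heterosis <- function(values, maternal_mean, paternal_mean) {
  values <- values[!is.na(values)]
  mpv <- mid_parent_value(maternal_mean, paternal_mean)
  hpv <- high_parent_value(maternal_mean, paternal_mean)
  if (mpv == 0 || hpv == 0) stop("heterosis: MPV and HPV must be nonzero")
  m <- mean(values)
  mph <- (m - mpv) / mpv * 100
  hph <- (m - hpv) / hpv * 100
  p_mph <- p_hph <- NA_real_
  if (length(values) >= 2L && stats::sd(values) > 0) {
    p_mph <- stats::t.test(values, mu = mpv)$p.value
    p_hph <- stats::t.test(values, mu = hpv)$p.value
  }
  data.frame(n = length(values), mean = m, mpv = mpv, hpv = hpv,
             mph = mph, hph = hph, p_mph = p_mph, p_hph = p_hph)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, as a percentage.
#'
#' @param values Numeric vector with at least two observations and nonzero
#'   mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("coefficient_of_variation: need n >= 2")
  m <- mean(values)
  if (m == 0) stop("coefficient_of_variation: zero mean")
  stats::sd(values) / m * 100
}

#' Significance stars
#'
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise; `NA` stays `NA`.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @keywords internal
signif_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
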