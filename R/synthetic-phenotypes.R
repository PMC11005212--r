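#' Configuration for the phenotype simulator
#'
#' Defines an F1 population trial: two parents and `n_lines` F1 lines,
#' measured for a set of traits under control and waterlogging treatment
#' with unequal replication (the treatment group is replicated more
#' heavily than the control group). Each line carries a single latent
#' tolerance effect: under treatment its expected trait values are the
#' control baselines multiplied by that effect, so the recoverable
#' stress/control ratio (WI) equals the effect by construction. Replicate
#' noise is multiplicative log-normal with a given coefficient of
#' variation.
#'
#' Score-type traits are recorded for the treatment group only, on their
#' own baseline scale, again proportional to the line's tolerance effect.
#'
#' @param n_lines Number of F1 lines (default 140).
#' @param traits Trait names; the first element is treated as the
#'   treatment-only score trait when it matches `score_traits`.
#' @param score_traits Which traits are treatment-only (default `"Score"`).
#' @param reps_control,reps_treatment Replicates per line per condition
#'   (defaults 6 and 10).
#' @param parent_tolerance Named pair of tolerance multipliers for the
#'   maternal and paternal parent (defaults 0.65 and 0.25: a tolerant and
#'   a sensitive parent).
#' @param line_effect_mean,line_effect_sd Mean and SD of the per-line
#'   tolerance effect (normal, truncated below at 0.01); the default
#'   (0.45, 0.15) spans both parents, giving transgressive segregation.
#' @param noise_cv Replicate-level coefficient of variation (> 0,
#'   default 0.15).
#' @param trait_baselines Named vector of control-condition trait means
#'   (all > 0). Defaults cover the standard seven-trait panel.
#' @param seed Integer seed; fixed seeds give byte-identical output.
#' @return A `pheno_sim_config` list.
#' @export
pheno_sim_config <- function(n_lines = 140,
                             traits = c("Score", "SH", "RL", "SFW",
                                        "RFW", "SDW", "RDW"),
                             score_traits = "Score",
                             reps_control = 6, reps_treatment = 10,
                             parent_tolerance = c(maternal = 0.65, paternal = 0.25),
                             line_effect_mean = 0.45, line_effect_sd = 0.15,
                             noise_cv = 0.15,
                             trait_baselines = NULL,
                             seed = 1L) {
  if (is.null(trait_baselines)) {
    defaults <- c(Score = 20, SH = 30, RL = 15, SFW = 8, RFW = 3,
                  SDW = 1.2, RDW = 0.4)
    trait_baselines <- defaults[traits]
    trait_baselines[is.na(trait_baselines)] <- 10
    names(trait_baselines) <- traits
  }
  cfg <- list(n_lines = as.integer(n_lines), traits = traits,
              score_traits = intersect(score_traits, traits),
              reps_control = as.integer(reps_control),
              reps_treatment = as.integer(reps_treatment),
              parent_tolerance = parent_tolerance,
              line_effect_mean = line_effect_mean,
              line_effect_sd = line_effect_sd,
              noise_cv = noise_cv, trait_baselines = trait_baselines,
              seed = as.integer(seed))
  if (cfg$n_lines < 1L) stop("n_lines must be >= 1")
  if (cfg$reps_control < 2L || cfg$reps_treatment < 2L) {
    stop("replicate counts must be >= 2")
  }
  if (!is.numeric(noise_cv) || noise_cv <= 0) stop("noise_cv must be > 0")
  if (any(trait_baselines <= 0)) stop("trait baselines must be > 0")
  if (length(parent_tolerance) != 2L || any(parent_tolerance <= 0)) {
    stop("parent_tolerance must be two positive multipliers")
  }
  if (line_effect_sd < 0) stop("line_effect_sd must be >= 0")
  structure(cfg, class = "pheno_sim_config")
}

#' Simulate an F1 phenotype trial
#'
#' Draws per-line tolerance effects, then replicate-level trait
#' measurements for both parents and all F1 lines under control and
#' treatment, in the long format consumed by [tolerance_report()].
#' Treatment-only score traits have no control rows.
#'
#' The multiplicative noise is log-normal with mean 1 and coefficient of
#' variation `noise_cv`, so expected treatment/control ratios equal the
#' configured tolerance effects and all measurements stay positive.
#'
#' @param cfg A [pheno_sim_config()].
#' @return List with elements `traits` (long data frame: `line_id`,
#'   `trait`, `condition`, `replicate`, `value`), `truth` (data frame
#'   `line_id`, `tolerance`, `is_parent`), and `config`.
#' @export
simulate_phenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "pheno_sim_config"))
  set.seed(cfg$seed)
  f1_ids <- sprintf("L%03d", seq_len(cfg$n_lines))
  ids <- c("maternal", "paternal", f1_ids)
  eff <- stats::rnorm(cfg$n_lines, cfg$line_effect_mean, cfg$line_effect_sd)
  eff <- pmax(eff, 0.01)
  tolerance <- c(unname(cfg$parent_tolerance[1]),
                 unname(cfg$parent_tolerance[2]), eff)

  # log-normal noise with mean 1 and CV = noise_cv
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  meanlog <- -sdlog^2 / 2
  noise <- function(n) stats::rlnorm(n, meanlog, sdlog)

  out <- vector("list", length(ids) * length(cfg$traits) * 2L)
  k <- 0L
  for (i in seq_along(ids)) {
    for (tr in cfg$traits) {
      base <- cfg$trait_baselines[[tr]]
      score_only <- tr %in% cfg$score_traits
      if (!score_only) {
        k <- k + 1L
        out[[k]] <- data.frame(
          line_id = ids[i], trait = tr, condition = "control",
          replicate = seq_len(cfg$reps_control),
          value = base * noise(cfg$reps_control))
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        line_id = ids[i], trait = tr, condition = "treatment",
        replicate = seq_len(cfg$reps_treatment),
        value = base * tolerance[i] * noise(cfg$reps_treatment))
    }
  }
  traits <- do.call(rbind, out[seq_len(k)])
  truth <- data.frame(line_id = ids, tolerance = tolerance,
                      is_parent = ids %in% c("maternal", "paternal"))
  list(traits = traits, truth = truth, config = cfg)
}

#' Noise-free phenotype expectation
#'
#' Deterministic version of [simulate_phenotypes()]: replicate values equal
#' their expectations exactly (no noise draw). Used to verify that the
#' evaluation pipeline recovers configured effects exactly.
#'
#' @param cfg A [pheno_sim_config()]; `noise_cv` is ignored.
#' @inherit simulate_phenotypes return
#' @export
simulate_phenotypes_noisefree <- function(cfg) {
  stopifnot(inherits(cfg, "pheno_sim_config"))
  set.seed(cfg$seed)
  f1_ids <- sprintf("L%03d", seq_len(cfg$n_lines))
  ids <- c("maternal", "paternal", f1_ids)
  eff <- pmax(stats::rnorm(cfg$n_lines, cfg$line_effect_mean, cfg$line_effect_sd), 0.01)
  tolerance <- c(unname(cfg$parent_tolerance[1]),
                 unname(cfg$parent_tolerance[2]), eff)
  rows <- list(); k <- 0L
  for (i in seq_along(ids)) {
    for (tr in cfg$traits) {
      base <- cfg$trait_baselines[[tr]]
      if (!(tr %in% cfg$score_traits)) {
        k <- k + 1L
        rows[[k]] <- data.frame(line_id = ids[i], trait = tr,
                                condition = "control",
                                replicate = seq_len(cfg$reps_control),
                                value = base)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(line_id = ids[i], trait = tr,
                              condition = "treatment",
                              replicate = seq_len(cfg$reps_treatment),
                              value = base * tolerance[i])
    }
  }
  traits <- do.call(rbind, rows)
  truth <- data.frame(line_id = ids, tolerance = tolerance,
                      is_parent = ids %in% c("maternal", "paternal"))
  list(traits = traits, truth = truth, config = cfg)
}
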