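#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either input file paths
#' (trait CSV, count TSV, sample sheet, GMT annotation) or simulator
#' settings, plus the decision thresholds shared by the stages. Stage
#' toggles allow partial runs. All randomness derives from `seed`.
#'
#' @param seed Integer master seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "phenotype", "de", "classify", "enrich")`.
#' @param pheno Named list of overrides for [pheno_sim_config()].
#' @param trio Named list of overrides for [trio_sim_config()]
#'   (`condition` and `seed` are set per condition by the pipeline).
#' @param conditions Trio conditions to simulate/analyze (default
#'   `c("control", "stress")`).
#' @param traits_file,counts_file,samples_file,gmt_file Input paths used
#'   when `"simulate"` is not among the stages (the GMT may also be given
#'   alongside simulation to replace the synthetic annotation).
#' @param maternal_id,paternal_id Parent line IDs in the trait table.
#' @param min_fc,max_fdr DEG thresholds (defaults 2 and 0.05).
#' @param alpha Profile-classification significance threshold (default
#'   0.05).
#' @param grade_multipliers Tolerance-grade SD multipliers (default
#'   `c(1, 1.64)`).
#' @param enrich_profile Profile whose genes form the enrichment query
#'   (default `"P5"`, transgressive up-regulation).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "phenotype", "de",
                                  "classify", "enrich"),
                       pheno = list(), trio = list(),
                       conditions = c("control", "stress"),
                       traits_file = NULL, counts_file = NULL,
                       samples_file = NULL, gmt_file = NULL,
                       maternal_id = "maternal", paternal_id = "paternal",
                       min_fc = 2, max_fdr = 0.05, alpha = 0.05,
                       grade_multipliers = c(1, 1.64),
                       enrich_profile = "P5") {
  all_stages <- c("simulate", "phenotype", "de", "classify", "enrich")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (min_fc < 1) stop("min_fc must be >= 1")
  if (max_fdr <= 0 || max_fdr > 1) stop("max_fdr must lie in (0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!enrich_profile %in% c(paste0("P", 0:7))) {
    stop("enrich_profile must be one of P0..P7")
  }
  structure(list(seed = as.integer(seed), stages = stages, pheno = pheno,
                 trio = trio, conditions = conditions,
                 traits_file = traits_file, counts_file = counts_file,
                 samples_file = samples_file, gmt_file = gmt_file,
                 maternal_id = maternal_id, paternal_id = paternal_id,
                 min_fc = min_fc, max_fdr = max_fdr, alpha = alpha,
                 grade_multipliers = grade_multipliers,
                 enrich_profile = enrich_profile),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("heterosim")),
           error = function(e) "dev")
}

#' Run the heterosis pipeline end to end
#'
#' Executes the enabled stages in order — simulate, phenotype, de,
#' classify, enrich — writing each stage's tables under `out_dir` and a
#' YAML manifest (`manifest.yaml`) recording the package version, seed,
#' config hash and per-stage output row counts. All output tables carry
#' `#`-comment provenance headers. Reruns with the same configuration are
#' bit-identical for the deterministic stages and reproduce the same
#' random draws through the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- c(sprintf("heterosim %s", pkg_version()),
           sprintf("seed: %d", config$seed),
           sprintf("config: %s", hash))
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(version = pkg_version(), seed = config$seed,
                   config_hash = hash, stages = list())
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- files
  }
  t0 <- Sys.time()

  traits <- counts <- samples <- annotation <- truth_trio <- NULL

  if ("simulate" %in% config$stages) {
    say("[simulate] phenotypes + trio counts (seed %d)", config$seed)
    pcfg <- do.call(pheno_sim_config,
                    utils::modifyList(list(seed = config$seed), config$pheno))
    sim <- simulate_phenotypes(pcfg)
    traits <- sim$traits
    write_trait_table(traits, file.path(out_dir, "traits.csv"), hdr)
    write_tsv(sim$truth, file.path(out_dir, "pheno_truth.tsv"), hdr)

    cmats <- list(); sheets <- list(); truths <- list()
    for (i in seq_along(config$conditions)) {
      cond <- config$conditions[i]
      tcfg <- do.call(trio_sim_config,
                      utils::modifyList(list(seed = config$seed + i - 1L,
                                             condition = cond),
                                        config$trio))
      tsim <- simulate_trio_counts(tcfg)
      cmats[[cond]] <- tsim$counts
      sheets[[cond]] <- tsim$samples
      tr <- tsim$truth; tr$condition <- cond
      truths[[cond]] <- tr
    }
    counts <- do.call(cbind, cmats)
    colnames(counts) <- unlist(lapply(sheets, `[[`, "sample_id"))
    samples <- do.call(rbind, sheets)
    rownames(samples) <- NULL
    truth_trio <- do.call(rbind, truths)
    rownames(truth_trio) <- NULL
    write_counts(counts, file.path(out_dir, "counts.tsv"), hdr)
    write_sample_sheet(samples, file.path(out_dir, "samples.tsv"), hdr)
    write_tsv(truth_trio, file.path(out_dir, "trio_truth.tsv"), hdr)
    note("simulate", list(traits = nrow(traits), counts = nrow(counts),
                          samples = nrow(samples)))
  } else {
    if (any(c("phenotype") %in% config$stages)) {
      if (is.null(config$traits_file)) stop("phenotype stage needs traits_file")
      traits <- read_trait_table(config$traits_file)
    }
    if (any(c("de", "classify") %in% config$stages)) {
      if (is.null(config$counts_file) || is.null(config$samples_file)) {
        stop("de/classify stages need counts_file and samples_file")
      }
      counts <- read_counts(config$counts_file)
      samples <- read_sample_sheet(config$samples_file)
    }
  }

  if ("phenotype" %in% config$stages) {
    say("[phenotype] tolerance + heterosis reports")
    tol <- tolerance_report(traits, config$maternal_id, config$paternal_id,
                            grade_multipliers = config$grade_multipliers)
    het <- heterosis_report(tol)
    write_tsv(cbind(line_id = rownames(tol$index), tol$index),
              file.path(out_dir, "tolerance_index.tsv"), hdr)
    write_tsv(tol$lines, file.path(out_dir, "tolerance_lines.tsv"), hdr)
    write_tsv(het, file.path(out_dir, "heterosis.tsv"), hdr)
    note("phenotype", list(lines = nrow(tol$lines), traits_tested = nrow(het)))
  }

  test_sets <- list()
  if (any(c("de", "classify") %in% config$stages)) {
    conds <- intersect(config$conditions, unique(samples$condition))
    if (length(conds) == 0L) stop("no configured condition present in sample sheet")
    for (cond in conds) {
      test_sets[[cond]] <- trio_test_set(counts, samples, condition = cond)
    }
  }

  if ("de" %in% config$stages) {
    n_deg <- integer(0)
    for (cond in names(test_sets)) {
      say("[de] contrasts under %s", cond)
      ts <- test_sets[[cond]]
      de_tab <- data.frame(gene = ts$gene,
                           log2fc_hm = ts$log2fc_hm, q_hm = ts$q_hm,
                           log2fc_hp = ts$log2fc_hp, q_hp = ts$q_hp,
                           log2fc_mp = ts$log2fc_mp, q_mp = ts$q_mp)
      de_tab$deg_hm <- abs(de_tab$log2fc_hm) >= log2(config$min_fc) &
        de_tab$q_hm <= config$max_fdr
      de_tab$deg_hp <- abs(de_tab$log2fc_hp) >= log2(config$min_fc) &
        de_tab$q_hp <= config$max_fdr
      write_tsv(de_tab, file.path(out_dir, sprintf("de_%s.tsv", cond)), hdr)
      n_deg[cond] <- sum(de_tab$deg_hm | de_tab$deg_hp)
    }
    note("de", as.list(n_deg))
  }

  assignments <- list()
  if ("classify" %in% config$stages) {
    for (cond in names(test_sets)) {
      say("[classify] profiles under %s", cond)
      ts <- test_sets[[cond]]
      asn <- assign_profiles(ts, alpha = config$alpha)
      deg_univ <- ts$gene[(abs(ts$log2fc_hm) >= log2(config$min_fc) &
                             ts$q_hm <= config$max_fdr) |
                          (abs(ts$log2fc_hp) >= log2(config$min_fc) &
                             ts$q_hp <= config$max_fdr)]
      smry <- profile_summary(asn, deg_universe = deg_univ)
      assignments[[cond]] <- asn
      write_tsv(asn, file.path(out_dir, sprintf("profiles_%s.tsv", cond)), hdr)
      write_tsv(data.frame(profile = names(smry$profile_counts),
                           n = as.integer(smry$profile_counts)),
                file.path(out_dir, sprintf("profile_summary_%s.tsv", cond)), hdr)
      note(paste0("classify_", cond),
           list(assigned = sum(asn$profile != "unclassified"),
                non_additive_pct = round(smry$non_additive_pct, 2)))
    }
  }

  if ("enrich" %in% config$stages) {
    cond <- names(assignments)[length(assignments)]
    if (is.null(cond)) stop("enrich stage requires the classify stage")
    say("[enrich] %s genes under %s", config$enrich_profile, cond)
    if (!is.null(config$gmt_file)) {
      annotation <- read_gmt(config$gmt_file)
    } else {
      annotation <- simulate_annotation(rownames(counts),
                                        seed = config$seed + 100L)
    }
    asn <- assignments[[cond]]
    query <- asn$gene[asn$profile == config$enrich_profile]
    et <- enrich(query, annotation, universe = rownames(counts))
    write_tsv(et, file.path(out_dir, sprintf("enrichment_%s.tsv", cond)), hdr)
    note("enrich", list(terms = nrow(et), significant = sum(et$enriched),
                        query = length(query)))
  }

  manifest$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 2)
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
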