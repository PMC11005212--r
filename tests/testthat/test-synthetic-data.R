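test_that("phenotype simulator respects shape, determinism and config checks", {
  cfg <- pheno_sim_config(n_lines = 140, seed = 1)
  sim <- simulate_phenotypes(cfg)
  # (140 + 2 parents) x 7 traits x (6 + 10) cells, minus the control cells
  # of the treatment-only score trait
  n_expected <- 142 * 7 * 16 - 142 * 1 * 6
  expect_equal(nrow(sim$traits), n_expected)
  expect_false(any(sim$traits$trait == "Score" &
                     sim$traits$condition == "control"))
  expect_true(all(sim$traits$value > 0))
  expect_equal(nrow(sim$truth), 142)

  sim2 <- simulate_phenotypes(cfg)
  expect_identical(sim$traits, sim2$traits)
  expect_identical(sim$truth, sim2$truth)

  expect_error(pheno_sim_config(noise_cv = 0), "noise_cv")
  expect_error(pheno_sim_config(reps_control = 1), "replicate")
  expect_error(pheno_sim_config(trait_baselines = c(Score = -1)), "baselines")
})

test_that("replicate noise has the configured coefficient of variation", {
  cfg <- pheno_sim_config(n_lines = 200, noise_cv = 0.15, seed = 21)
  sim <- simulate_phenotypes(cfg)
  ctl <- sim$traits[sim$traits$condition == "control" & sim$traits$trait == "SH", ]
  # control replicates share one baseline: pooled CV estimates noise_cv
  cv_hat <- sd(ctl$value) / mean(ctl$value)
  expect_lt(abs(cv_hat - 0.15), 0.02)
})

test_that("trio simulator: determinism, null case, and class mean orderings", {
  cfg <- trio_sim_config(n_genes = 400, seed = 2)
  a <- simulate_trio_counts(cfg)
  b <- simulate_trio_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$counts), c(400, 9))
  expect_true(all(a$counts >= 0))
  expect_identical(storage.mode(a$counts), "integer")
  # ground truth partitions the genes
  expect_equal(nrow(a$truth), 400)
  expect_false(anyNA(a$truth$class))

  # null-only: no group means differ
  ncfg <- trio_sim_config(n_genes = 50, class_proportions = c(null = 1), seed = 3)
  nsim <- simulate_trio_counts(ncfg)
  expect_equal(nsim$truth$mean_maternal, nsim$truth$mean_paternal)
  expect_equal(nsim$truth$mean_maternal, nsim$truth$mean_hybrid)

  # class orderings: hybrid at mid for additive, at matched parent for
  # dominance, beyond both for transgressive
  tr <- a$truth
  add <- tr[tr$class %in% c("profile0", "profile7"), ]
  expect_equal(add$mean_hybrid, (add$mean_maternal + add$mean_paternal) / 2)
  mat <- tr[tr$class %in% c("profile1", "profile6"), ]
  expect_equal(mat$mean_hybrid, mat$mean_maternal)
  pat <- tr[tr$class %in% c("profile3", "profile4"), ]
  expect_equal(pat$mean_hybrid, pat$mean_paternal)
  up <- tr[tr$class == "profile5", ]
  expect_true(all(up$mean_hybrid >=
                    cfg$effect_size * pmax(up$mean_maternal, up$mean_paternal)))
  dn <- tr[tr$class == "profile2", ]
  expect_true(all(dn$mean_hybrid <=
                    pmin(dn$mean_maternal, dn$mean_paternal) / cfg$effect_size))

  expect_error(trio_sim_config(class_proportions = c(null = 0.5)), "sum to 1")
  expect_error(trio_sim_config(effect_size = 1), "effect_size")
  expect_error(trio_sim_config(dispersion = -1), "dispersion")
})

test_that("near-Poisson additive genes give hybrid means at the mid-parent", {
  # parents at 100 and 300: hybrid mean must be ~200 within 3 standard errors
  cfg <- trio_sim_config(n_genes = 2000, reps_per_group = 3,
                         class_proportions = c(profile0 = 1),
                         effect_size = 3, dispersion = 0,
                         mean_log_range = log(c(100, 100)),
                         lib_factor_range = c(1, 1), seed = 8)
  sim <- simulate_trio_counts(cfg)
  hyb <- sim$counts[, sim$samples$role == "hybrid", drop = FALSE]
  se <- sqrt(200 / length(hyb))  # Poisson SE of the grand mean
  expect_lt(abs(mean(hyb) - 200), 3 * se)
  mat <- sim$counts[, sim$samples$role == "maternal", drop = FALSE]
  expect_lt(abs(mean(mat) - 100), 3 * sqrt(100 / length(mat)))
})

test_that("simulated counts match negative-binomial moments", {
  phi <- 0.2; mu <- 150
  cfg <- trio_sim_config(n_genes = 6000, class_proportions = c(null = 1),
                         dispersion = phi, mean_log_range = log(c(mu, mu)),
                         lib_factor_range = c(1, 1), seed = 13)
  sim <- simulate_trio_counts(cfg)
  x <- as.vector(sim$counts)
  expect_lt(abs(mean(x) - mu) / mu, 0.02)
  expect_lt(abs(var(x) - (mu + phi * mu^2)) / (mu + phi * mu^2), 0.05)
})

test_that("synthetic annotation covers the universe and is seeded", {
  genes <- sprintf("g%03d", 1:300)
  ann <- simulate_annotation(genes, n_terms = 20, size_range = c(5, 50), seed = 4)
  expect_length(ann, 20)
  expect_true(all(unlist(ann) %in% genes))
  sizes <- lengths(ann)
  expect_true(all(sizes >= 5 & sizes <= 50))
  expect_identical(ann, simulate_annotation(genes, 20, c(5, 50), seed = 4))
})
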