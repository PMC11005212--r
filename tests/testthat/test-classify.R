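# Build a single-gene test-set row with chosen means and contrast q-values.
ts_row <- function(h, m, p, q_hm, q_hp, q_mp, q_hmid, gene = "g1") {
  data.frame(gene = gene, mean_hybrid = h, mean_maternal = m,
             mean_paternal = p, mean_midparent = (m + p) / 2,
             log2fc_hm = log2((h + 1) / (m + 1)), q_hm = q_hm,
             log2fc_hp = log2((h + 1) / (p + 1)), q_hp = q_hp,
             log2fc_mp = log2((m + 1) / (p + 1)), q_mp = q_mp,
             log2fc_hmid = log2((h + 1) / ((m + p) / 2 + 1)), q_hmid = q_hmid)
}

test_that("decision tree honors the definitional anchor cases", {
  sig <- 0.001; ns <- 0.8
  # hybrid >> both parents -> transgressive up (P5)
  a <- assign_profiles(ts_row(400, 100, 100, sig, sig, ns, sig))
  expect_equal(as.character(a$profile), "P5")
  expect_equal(a$category, "transgressive-up")
  # hybrid << both parents -> transgressive down (P2)
  a <- assign_profiles(ts_row(25, 100, 100, sig, sig, ns, sig))
  expect_equal(as.character(a$profile), "P2")
  # hybrid ~ maternal, maternal >> paternal -> maternal dominance, high (P6)
  a <- assign_profiles(ts_row(400, 400, 100, ns, sig, sig, sig))
  expect_equal(as.character(a$profile), "P6")
  expect_equal(a$category, "maternal-dominant")
  # hybrid ~ maternal, maternal << paternal -> maternal dominance, low (P1)
  a <- assign_profiles(ts_row(100, 100, 400, ns, sig, sig, sig))
  expect_equal(as.character(a$profile), "P1")
  # hybrid ~ paternal, paternal low (P3) / high (P4)
  a <- assign_profiles(ts_row(100, 400, 100, sig, ns, sig, sig))
  expect_equal(as.character(a$profile), "P3")
  expect_equal(a$category, "paternal-dominant")
  a <- assign_profiles(ts_row(400, 100, 400, sig, ns, sig, sig))
  expect_equal(as.character(a$profile), "P4")
  # parents differ, hybrid at mid -> additive (P0 maternal low, P7 high)
  a <- assign_profiles(ts_row(250, 100, 400, sig, sig, sig, ns))
  expect_equal(as.character(a$profile), "P0")
  expect_equal(a$category, "additive")
  a <- assign_profiles(ts_row(250, 400, 100, sig, sig, sig, ns))
  expect_equal(as.character(a$profile), "P7")
  # all indistinguishable -> unclassified
  a <- assign_profiles(ts_row(100, 100, 100, ns, ns, ns, ns))
  expect_equal(as.character(a$profile), "unclassified")
  expect_equal(a$category, "null")
})

test_that("assignment is exhaustive and mutually exclusive over outcome space", {
  qs <- c(0.001, 0.2)
  grid <- expand.grid(h = c(50, 150, 400), m = c(100, 300), p = c(100, 300),
                      q_hm = qs, q_hp = qs, q_mp = qs, q_hmid = qs)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    ts_row(g$h, g$m, g$p, g$q_hm, g$q_hp, g$q_mp, g$q_hmid,
           gene = paste0("g", i))
  }))
  a <- assign_profiles(rows)
  expect_equal(nrow(a), nrow(grid))
  expect_false(anyNA(a$profile))
  expect_true(all(as.character(a$profile) %in%
                    c(paste0("P", 0:7), "unclassified")))
  # category is a deterministic function of profile
  expect_equal(a$category, unname(profile_categories()[as.character(a$profile)]))
})

test_that("role swap permutes profiles exactly as maternal/paternal exchange", {
  sim <- small_trio(seed = 17)
  ts <- trio_test_set(sim$counts, sim$samples)
  swapped <- ts
  swapped$mean_maternal <- ts$mean_paternal
  swapped$mean_paternal <- ts$mean_maternal
  swapped$q_hm <- ts$q_hp
  swapped$q_hp <- ts$q_hm
  swapped$log2fc_hm <- ts$log2fc_hp
  swapped$log2fc_hp <- ts$log2fc_hm
  swapped$log2fc_mp <- -ts$log2fc_mp

  a <- assign_profiles(ts)
  b <- assign_profiles(swapped)
  swap_map <- c(P0 = "P7", P7 = "P0", P1 = "P3", P3 = "P1",
                P6 = "P4", P4 = "P6", P2 = "P2", P5 = "P5",
                unclassified = "unclassified")
  expect_identical(as.character(b$profile),
                   unname(swap_map[as.character(a$profile)]))
})

test_that("raising alpha never turns a transgressive call into an additive one", {
  qs <- c(0.005, 0.02, 0.04, 0.06, 0.3)
  grid <- expand.grid(q_hm = qs, q_hp = qs, q_mp = qs, q_hmid = qs)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    ts_row(400, 100, 300, g$q_hm, g$q_hp, g$q_mp, g$q_hmid,
           gene = paste0("g", i))
  }))
  alphas <- c(0.01, 0.05, 0.1, 0.25)
  prof <- sapply(alphas, function(al) {
    as.character(assign_profiles(rows, alpha = al)$profile)
  })
  trans <- c("P2", "P5")
  addv <- c("P0", "P7")
  for (i in seq_len(ncol(prof) - 1)) {
    became_additive <- prof[, i] %in% trans & prof[, i + 1] %in% addv
    expect_false(any(became_additive))
  }
})

test_that("mid-parent test: null at the mid-parent, significant at 4x", {
  set.seed(61)
  n <- 800
  mu <- 400
  mk <- function(m) matrix(rnbinom(n * 3, mu = m, size = 20), n, 3)
  mat <- mk(mu); pat <- mk(3 * mu)
  hyb_null <- mk(2 * mu)          # exactly mid-parent
  hyb_alt <- mk(4 * 2 * mu)       # 4x the mid-parent
  t_null <- midparent_test(hyb_null, mat, pat)
  t_alt <- midparent_test(hyb_alt, mat, pat)
  expect_lt(mean(t_null$p < 0.05), 0.09)
  expect_gt(mean(t_alt$q <= 0.05), 0.99)
  expect_lt(abs(median(t_alt$log2_ratio) - 2), 0.1)
  expect_lt(abs(median(t_null$log2_ratio)), 0.05)

  # parents equal, hybrid equal: everything null
  same <- mk(mu)
  t_same <- midparent_test(mk(mu), same, same)
  expect_lt(mean(t_same$p < 0.05), 0.09)

  # zero mid-parent mean: p = 1, ratio flagged NA
  z <- matrix(0, 2, 3)
  h <- matrix(5, 2, 3)
  tz <- midparent_test(h, z, z)
  expect_equal(tz$p, c(1, 1))
  expect_true(all(is.na(tz$log2_ratio)))
})

test_that("profile summary counts non-additive genes over a universe", {
  asn <- data.frame(gene = paste0("g", 1:10),
                    profile = factor(c("P0", "P1", "P2", "P3", "P4", "P5",
                                       "P6", "P7", "unclassified", "P5"),
                                     levels = c(paste0("P", 0:7),
                                                "unclassified")),
                    category = NA)
  s <- profile_summary(asn)
  expect_equal(s$n_non_additive, 7)
  expect_equal(s$non_additive_pct, 70)
  # restricting the universe restricts numerator and denominator
  s2 <- profile_summary(asn, deg_universe = paste0("g", 1:5))
  expect_equal(s2$n_non_additive, 4)
  expect_equal(s2$non_additive_pct, 80)
  expect_error(profile_summary(asn, deg_universe = character(0)), "empty")

  expect_equal(non_additive_fraction(0, 10), 0)
  expect_equal(non_additive_fraction(10, 10), 100)
  expect_error(non_additive_fraction(5, 0), "empty")
})

test_that("trio test set validates roles and condition selection", {
  sim <- small_trio(seed = 19, n_genes = 120)
  no_hybrid <- sim$samples[sim$samples$role != "hybrid", ]
  expect_error(trio_test_set(sim$counts, no_hybrid), "hybrid")
  bad_sheet <- sim$samples
  bad_sheet$sample_id[1] <- "missing_sample"
  expect_error(trio_test_set(sim$counts, bad_sheet), "absent")
  ts <- trio_test_set(sim$counts, sim$samples)
  expect_equal(nrow(ts), 120)
  expect_false(anyNA(ts$q_hm))
})
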