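test_that("size factors recover known column scalings", {
  set.seed(31)
  base <- matrix(rpois(200, 100), 50, 4)
  rownames(base) <- paste0("g", 1:50)

  eq <- cbind(base[, 1], base[, 1])
  expect_equal(size_factors(eq), c(1, 1))

  doub <- cbind(a = base[, 1], b = 2L * base[, 1])
  sf <- size_factors(doub)
  expect_equal(sf[["b"]] / sf[["a"]], 2)

  # exact scalar multiples of one column recover the scalars up to a constant
  scal <- sapply(c(1, 0.5, 3), function(s) round(base[, 1] * s))
  sf2 <- size_factors(scal)
  expect_equal(sf2 / sf2[1], c(1, 0.5, 3), tolerance = 0.05)

  single <- matrix(c(10, 20, 40), 1)
  sf3 <- size_factors(single)
  expect_equal(sf3 / sf3[1], c(1, 2, 4))

  # idempotence: factors of a factor-normalized matrix are ~1
  norm <- normalize_counts(doub)
  expect_equal(unname(size_factors(norm)), c(1, 1), tolerance = 1e-8)

  # fallback when no gene is shared across all samples
  disj <- rbind(c(5L, 0L), c(0L, 7L))
  expect_message(sfd <- size_factors(disj), "total-count")
  expect_equal(sfd[2] / sfd[1], 7 / 5)
})

test_that("rpkm follows the per-kilobase-per-million formula", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  r <- rpkm(m, gene_length = c(1000, 500), library_size = 1e6)
  expect_equal(r["a", 1], 10)
  expect_equal(r["b", 1], 0)
  expect_equal(rpkm(m, c(1000, 500), library_size = 2e6)["a", 1], 5)
  expect_error(rpkm(m, c(0, 500)), "lengths")
})

test_that("bh adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(41)
  for (n in 1:10) {
    for (rep in 1:20) {
      p <- round(runif(n), 2)  # rounding forces ties
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("de_test: identical groups are null, symmetry negates fold changes", {
  set.seed(51)
  cts <- matrix(rpois(100 * 6, 80), 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  same <- cbind(cts[, 1:3], cts[, 1:3])
  colnames(same) <- paste0("s", 1:6)
  de0 <- de_test(same, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de0$log2fc, rep(0, 100))
  expect_true(all(de0$p > 0.999))
  expect_false(any(de0$deg))

  ab <- de_test(cts, paste0("s", 1:3), paste0("s", 4:6))
  ba <- de_test(cts, paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)

  expect_error(de_test(cts, "s1", paste0("s", 2:3)), "2 replicates")
})

test_that("strong fold changes at high expression are flagged with direction", {
  set.seed(52)
  n <- 300
  mu_a <- rep(800, n); mu_b <- mu_a
  up <- 1:50
  mu_a[up] <- mu_a[up] * 8
  cts <- cbind(sapply(1:3, function(i) rnbinom(n, mu = mu_a, size = 20)),
               sapply(1:3, function(i) rnbinom(n, mu = mu_b, size = 20)))
  dimnames(cts) <- list(paste0("g", 1:n), paste0("s", 1:6))
  de <- de_test(cts, paste0("s", 1:3), paste0("s", 4:6))
  expect_gt(mean(de$deg[up]), 0.9)
  expect_true(all(de$direction[up][de$deg[up]] == "up"))
  expect_lt(mean(de$deg[-up]), 0.02)
})

test_that("moderated t agrees with the established empirical-Bayes engine", {
  set.seed(53)
  n <- 500
  cts <- matrix(rnbinom(n * 6, mu = 300, size = 10), n, 6,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  cts[1:40, 1:3] <- matrix(rnbinom(40 * 3, mu = 1800, size = 10), 40, 3)
  sf <- rep(1, 6)
  de <- de_test(cts, paste0("s", 1:3), paste0("s", 4:6), sf = sf)
  y <- log2(normalize_counts(cts, sf) + 1)
  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(y, design))
  p_limma <- fit$p.value[, 2]
  # same model (pooled variance, eBayes squeeze): near-identical p-values
  expect_gt(cor(-log10(de$p), -log10(p_limma)), 0.999)
  expect_lt(max(abs(de$p - p_limma)), 0.02)
})

test_that("all-zero genes get p = 1 and can be excluded from the FDR set", {
  cts <- matrix(rpois(50 * 6, 30), 50, 6,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  cts[1:5, ] <- 0L
  de <- de_test(cts, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(de$p[1:5] == 1))
  de2 <- de_test(cts, paste0("s", 1:3), paste0("s", 4:6),
                 exclude_allzero = TRUE)
  expect_true(all(is.na(de2$q[1:5])))
  expect_false(anyNA(de2$q[-(1:5)]))
})

test_that("variance squeezing shrinks toward a common prior", {
  set.seed(54)
  s2 <- rchisq(2000, df = 4) / 4 * 0.5  # true variance 0.5
  sq <- squeeze_variances(s2, df = 4)
  expect_gt(sq$df_prior, 1)
  expect_lt(abs(sq$var_prior - 0.5), 0.1)
  # posterior lies between observation and prior
  expect_true(all(sq$var_post >= pmin(s2, sq$var_prior) - 1e-12 &
                    sq$var_post <= pmax(s2, sq$var_prior) + 1e-12))
})
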