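test_that("per-replicate features skip uncovered replicates", {
  ds <- sim_dataset(n_genes = 3, n_replicates = 3, seed = 2)
  v <- feature_per_replicate(ds, "g0001", "control", "signed_auc", c(0, 24))
  expect_length(v, 3L)
  expect_named(v, c("1", "2", "3"))
  # replicate 1 loses coverage of late times
  txt <- expr_text("ID\tA1\tA2\tA3\tA4",
                   "g1\t1\t2\t1\t2")
  lab <- expr_text("Array\tA1\tA2\tA3\tA4", "Treatment\ta\ta\ta\ta",
                   "Replicate\t1\t1\t2\t2", "Time\t0\t4\t0\t9")
  ds2 <- assemble_dataset(read_expression_matrix(textConnection(txt)),
                          read_design_table(textConnection(lab)))
  expect_warning(
    v2 <- feature_per_replicate(ds2, "g1", "a", "signed_auc", c(0, 9)),
    "skipped")
  expect_named(v2, "2")
  expect_equal(
    feature_per_replicate(ds2, "g1", "a", "time_point", 4)[["1"]], 2)
  expect_error(
    suppressWarnings(
      feature_per_replicate(ds2, "g1", "a", "signed_auc", c(0, 99))),
    "no usable replicate")
})

test_that("two-sample tests match stated conventions and examples", {
  r <- two_sample_test(c(1, 2, 3), c(1, 2, 3), "t")
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
  mw <- two_sample_test(c(1, 2), c(3, 4), "wilcoxon_mw")
  expect_equal(mw$statistic, 0)            # U = 0
  expect_equal(mw$p_value, 1 / 3)          # exact two-sided
  deg <- two_sample_test(c(2, 2), c(2, 2), "t")
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  deg2 <- two_sample_test(c(3, 3), c(1, 1), "t")
  expect_equal(deg2$p_value, 0)
  # symmetric under group exchange
  withr::with_seed(5, for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(two_sample_test(a, b, "t")$p_value,
                 two_sample_test(b, a, "t")$p_value)
    expect_equal(two_sample_test(a, b, "wilcoxon_mw")$p_value,
                 two_sample_test(b, a, "wilcoxon_mw")$p_value)
  })
})

test_that("Mann-Whitney exact p agrees with full enumeration for small samples", {
  withr::with_seed(31, {
    for (na in 1:4) for (nb in na:(8 - na)) {
      for (rep in 1:3) {
        a <- round(rnorm(na), 2)
        b <- round(rnorm(nb, 0.5), 2)
        if (anyDuplicated(c(a, b))) next   # exact MW defined without ties
        got <- two_sample_test(a, b, "wilcoxon_mw")$p_value
        expect_equal(got, enumerate_mw_p(a, b), tolerance = 1e-12,
                     info = sprintf("na=%d nb=%d", na, nb))
      }
    }
  })
})

test_that("paired tests handle matched replicates and degeneracies", {
  a <- c(1, 2, 3, 4)
  expect_equal(paired_test(a, a, "paired_t")$p_value, 1)
  expect_equal(paired_test(a, a, "wilcoxon_signed_rank")$p_value, 1)
  r <- paired_test(a + 1, a, "paired_t")    # constant nonzero differences
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  expect_error(paired_test(c(1, 2), c(1, 2, 3)), "equal length")
  pt <- paired_test(c(5, 3, 8, 6), c(1, 2, 3, 4), "paired_t")
  ref <- t.test(c(5, 3, 8, 6), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(pt$p_value, ref$p.value)
  expect_equal(pt$statistic, unname(ref$statistic))
})

test_that("exact permutation p-values match hand enumeration", {
  r <- permutation_test(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$n_used, 6)
  expect_equal(r$p_value, 1 / 3)           # 2 of 6 relabelings as extreme
  rp <- permutation_test(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_true(rp$exact)
  expect_equal(rp$p_value, 2 / 8)          # all-plus and all-minus flips
  expect_equal(permutation_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(permutation_test(c(1, 2), c(3, 4), n_perm = 0), "n_perm")
})

test_that("exact permutation p equals brute force for all sizes up to 8", {
  withr::with_seed(17, {
    for (na in 2:4) for (nb in 2:(8 - na)) {
      for (rep in 1:3) {
        a <- rnorm(na); b <- rnorm(nb, 1)
        got <- permutation_test(a, b)
        expect_true(got$exact)
        expect_equal(got$p_value, enumerate_perm_p(a, b), tolerance = 1e-12,
                     info = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
      }
    }
  })
})

test_that("exact permutation p ignores the seed; sampled p converges to exact", {
  a <- c(0.3, 1.2, -0.5, 2.1); b <- c(1.4, 2.2, 0.9, 3.0)
  e1 <- permutation_test(a, b, seed = 1)
  e2 <- permutation_test(a, b, seed = 999)
  expect_identical(e1$p_value, e2$p_value)
  exact <- e1$p_value
  sampled <- permutation_test(a, b, n_perm = 50000, seed = 3,
                              exact_limit = 1)
  expect_false(sampled$exact)
  expect_lt(abs(sampled$p_value - exact), 0.02)
  expect_gte(sampled$p_value, 1 / (sampled$n_used + 1))
})

test_that("permutation p-values are valid probabilities with the +1 floor", {
  withr::with_seed(23, for (i in 1:5) {
    a <- rnorm(3); b <- rnorm(12, 2)
    r <- permutation_test(a, b, n_perm = 99, seed = i, exact_limit = 10)
    expect_gte(r$p_value, 1 / 100)
    expect_lte(r$p_value, 1)
  })
})
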