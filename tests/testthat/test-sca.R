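test_that("log transform is element-wise natural log with named errors", {
  prof <- tibble::tibble(sample_id = c("s1", "s2"), A = c(1, exp(1)), B = c(4, 9))
  lt <- log_transform(prof)
  expect_equal(lt$A, c(0, 1))
  expect_equal(lt$B, log(c(4, 9)))
  bad <- tibble::tibble(sample_id = c("s1", "s2"), A = c(1, -1))
  expect_error(log_transform(bad), "s2.*A")
})

test_that("correlation of log profiles is invariant to the log base", {
  set.seed(10)
  x <- exp(rnorm(30)); y <- exp(rnorm(30) + 0.5 * log(x))
  expect_equal(cor(log(x), log(y)), cor(log10(x), log10(y)), tolerance = 1e-12)
})

test_that("pair records equal the textbook Pearson correlation of logs", {
  prof <- random_profiles(25, c("A", "B", "C"), seed = 3)
  res <- run_sca(prof)
  L <- log(as.matrix(prof[-1]))
  pairs <- res[res$category == "pair", ]
  expect_equal(pairs$r[pairs$side_A == "A" & pairs$side_B == "B"],
               cor(L[, "A"], L[, "B"]), tolerance = 1e-12)
  expect_equal(pairs$r[pairs$side_A == "B" & pairs$side_B == "C"],
               cor(L[, "B"], L[, "C"]), tolerance = 1e-12)
})

test_that("exact functional dependence is recovered with its weights", {
  set.seed(4)
  xi <- exp(rnorm(30)); xj <- exp(rnorm(30))
  xk <- xi^2 * xj  # log xk = 2 log xi + log xj
  L <- cbind(log(xi), log(xj), log(xk))
  fit <- max_stoich_correlation(L, c(1, 2), 3)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_identical(fit$beta, c(2L, 1L))
  expect_identical(fit$eta, 1L)
})

test_that("ratio-deduplicated search equals exhaustive grid search", {
  set.seed(11)
  for (rep in 1:40) {
    L <- matrix(rnorm(40), nrow = 10)
    fit <- max_stoich_correlation(L, c(1, 2), c(3, 4))
    orc <- oracle_max_cor(L, c(1, 2), c(3, 4))
    expect_equal(fit$r, orc$r, tolerance = 1e-12)
    expect_identical(fit$beta, orc$beta)
    expect_identical(fit$eta, orc$eta)
    # triplet splits too
    fit3 <- max_stoich_correlation(L, c(1, 3), 2)
    orc3 <- oracle_max_cor(L, c(1, 3), 2)
    expect_equal(fit3$r, orc3$r, tolerance = 1e-12)
    expect_identical(fit3$beta, orc3$beta)
  }
})

test_that("maximization is symmetric, dominant and monotone in the bound", {
  set.seed(12)
  for (rep in 1:10) {
    L <- matrix(rnorm(48), nrow = 12)
    f1 <- max_stoich_correlation(L, c(1, 2), c(3, 4))
    f2 <- max_stoich_correlation(L, c(3, 4), c(1, 2))
    expect_equal(f1$r, f2$r, tolerance = 1e-12)
    expect_identical(f1$beta, f2$eta)
    expect_identical(f1$eta, f2$beta)
    # dominance over the all-ones combination
    ones <- cor(L[, 1] + L[, 2], L[, 3] + L[, 4])
    expect_gte(f1$r, ones - 1e-12)
    # enlarging the weight bound never lowers the maximum
    r_by_imax <- vapply(1:5, function(im)
      max_stoich_correlation(L, c(1, 2), c(3, 4), i_max = im)$r, numeric(1))
    expect_true(all(diff(r_by_imax) >= -1e-12))
  }
})

test_that("whole-run fast path agrees with the per-split search", {
  prof <- random_profiles(15, sprintf("m%d", 1:5), seed = 20)
  res <- run_sca(prof)
  expect_equal(nrow(res), count_splits(5))
  L <- log(as.matrix(prof[-1]))
  mets <- profile_metabolites(prof)
  for (i in sample(nrow(res), 25)) {
    a <- match(strsplit(res$side_A[i], ",")[[1]], mets)
    b <- match(strsplit(res$side_B[i], ",")[[1]], mets)
    fit <- max_stoich_correlation(L, a, b)
    expect_equal(res$r[i], fit$r, tolerance = 1e-12)
    expect_identical(res$beta[i], paste(fit$beta, collapse = ","))
    expect_identical(res$eta[i], paste(fit$eta, collapse = ","))
  }
})

test_that("run_sca output is deterministic and minimal cases work", {
  prof <- random_profiles(10, c("A", "B"), seed = 30)
  res <- run_sca(prof)
  expect_equal(nrow(res), 1)
  expect_equal(res$category, "pair")
  res2 <- run_sca(prof)
  expect_identical(tidy(res), tidy(res2))
  expect_error(run_sca(prof[1:3, ]), "samples")
})

test_that("missing values trigger per-split complete-case analysis", {
  prof <- random_profiles(20, c("A", "B", "C"), seed = 31)
  prof$A[1:3] <- -1  # nonpositive -> missing under drop_sample
  res <- run_sca(prof, nonpositive = "drop_sample")
  expect_equal(res$n_used[res$side_A == "A" & res$side_B == "B"], 17)
  expect_equal(res$n_used[res$side_A == "B" & res$side_B == "C"], 20)
  # too few usable samples -> split skipped and logged
  prof$B[1:16] <- -1
  res2 <- run_sca(prof, nonpositive = "drop_sample")
  skipped <- attr(res2, "skipped")
  expect_gt(nrow(skipped), 0)
})

test_that("degenerate constant profiles are skipped with a reason", {
  prof <- random_profiles(12, c("A", "B", "C"), seed = 32)
  prof$C <- 1  # log is constant zero
  res <- run_sca(prof)
  # any split where C stands alone is degenerate for every weight choice
  expect_false(any(res$side_A == "C" | res$side_B == "C"))
  expect_gt(nrow(attr(res, "skipped")), 0)
  # on a two-member side the combination is non-constant, so the split is
  # computable and its r must equal the plain A-B correlation
  mix <- res[res$side_A == "A,C" & res$side_B == "B", ]
  expect_equal(mix$r, res$r[res$side_A == "A" & res$side_B == "B"],
               tolerance = 1e-12)
})

test_that("tidy and glance expose the result and its summary", {
  prof <- random_profiles(15, c("A", "B", "C", "D"), seed = 33)
  res <- run_sca(prof)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "sca_result"))
  gl <- glance(res)
  expect_equal(gl$n_splits, 21)
  expect_equal(gl$n_pairs + gl$n_triplets + gl$n_quadruples, 21)
  expect_s3_class(autoplot(res), "ggplot")
})
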