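make_records <- function(rows, mets) {
  df <- tibble::as_tibble(do.call(rbind.data.frame, rows))
  fake_result(df, mets)
}

rec <- function(a, b, r = 0.99, p_adj = 0.001, beta = "1", eta = "1") {
  cat <- if (length(strsplit(a, ",")[[1]]) + length(strsplit(b, ",")[[1]]) == 2) "pair"
  else if (length(strsplit(a, ",")[[1]]) + length(strsplit(b, ",")[[1]]) == 3) "triplet"
  else "quadruple"
  list(category = cat, side_A = a, side_B = b, beta = beta, eta = eta,
       r = r, n_used = 20L, p = p_adj / 2, p_adj = p_adj)
}

test_that("coupling degree counts membership in significant records", {
  mets <- c("ala", "gly", "ser", "thr")
  empty <- make_records(list(rec("ala", "gly", r = 0.2)), mets)
  deg0 <- coupling_degree(empty, tau = 0.8)
  expect_equal(sum(deg0$degree), 0)
  expect_setequal(deg0$metabolite, mets)

  one <- make_records(list(rec("ala", "gly")), mets)
  deg1 <- coupling_degree(one, tau = 0.8)
  expect_equal(deg1$degree[deg1$metabolite == "ala"], 1)
  expect_equal(deg1$degree[deg1$metabolite == "gly"], 1)
  expect_equal(deg1$degree[deg1$metabolite == "ser"], 0)

  # membership-count oracle on random record sets
  set.seed(50)
  for (i in 1:10) {
    rows <- lapply(1:15, function(j) {
      ab <- sample(mets, 4)
      rec(paste(sort(ab[1:2]), collapse = ","), paste(sort(ab[3:4]), collapse = ","),
          r = runif(1, 0.5, 1), p_adj = runif(1, 0, 0.1))
    })
    res <- make_records(rows, mets)
    deg <- coupling_degree(res, tau = 0.8, alpha = 0.05)
    sig <- res[res$p_adj <= 0.05 & res$r >= 0.8, ]
    members <- unlist(strsplit(c(sig$side_A, sig$side_B), ","))
    for (m in mets) {
      expect_equal(deg$degree[deg$metabolite == m], sum(members == m))
    }
    # total degree equals summed side sizes of significant records
    expect_equal(sum(deg$degree), length(members))
  }
})

test_that("coupling degree is monotone non-increasing in the threshold", {
  prof <- random_profiles(25, sprintf("aa%d", 1:5), seed = 51)
  res <- run_sca(prof)
  taus <- c(0.3, 0.5, 0.7, 0.9)
  degs <- lapply(taus, function(t) coupling_degree(res, tau = t, alpha = 1))
  for (m in attr(res, "metabolites")) {
    d <- vapply(degs, function(dd) dd$degree[dd$metabolite == m], integer(1))
    expect_true(all(diff(d) <= 0))
  }
})

test_that("top-k ranking breaks ties alphabetically", {
  tab <- tibble::tibble(metabolite = c("cit", "akg", "mal", "fum"),
                        degree = c(3L, 3L, 1L, 0L))
  top <- rank_coupled(tab, 3)
  expect_identical(top$metabolite, c("akg", "cit", "mal"))
  zero <- tibble::tibble(metabolite = c("b", "a", "c"), degree = c(0L, 0L, 0L))
  expect_identical(rank_coupled(zero, 2)$metabolite, c("a", "b"))
  expect_error(rank_coupled(tab, 0), ">= 1")
})

test_that("overlap reports shared and unique records per category", {
  mets <- c("ala", "gly", "ser", "thr", "val")
  a <- make_records(list(rec("ala", "gly"), rec("ala,gly", "ser"),
                         rec("ala,gly", "ser,thr")), mets)
  same <- overlap_results(a, a)
  expect_equal(sum(same$counts$unique_a), 0)
  expect_equal(sum(same$counts$unique_b), 0)
  expect_equal(sum(same$counts$shared), 3)

  b <- make_records(list(rec("ala", "ser"), rec("gly,ser", "thr")), mets)
  ov <- make_overlap <- overlap_results(a, b)
  expect_equal(sum(ov$counts$shared), 0)
  expect_equal(sum(ov$counts$unique_a), 3)
  expect_equal(sum(ov$counts$unique_b), 2)
  # per-category accounting identity
  expect_equal(ov$counts$shared + ov$counts$unique_a, ov$counts$total_a)
  expect_equal(ov$counts$shared + ov$counts$unique_b, ov$counts$total_b)

  # symmetry
  ba <- overlap_results(b, a)
  expect_equal(ba$counts$unique_a, ov$counts$unique_b)
  expect_equal(ba$counts$shared, ov$counts$shared)

  disjoint <- make_records(list(rec("x1", "x2")), c("x1", "x2"))
  expect_error(overlap_results(a, disjoint), "disjoint")
})

test_that("overlap matching agrees with a brute-force intersection oracle", {
  mets <- sprintf("m%02d", 1:8)
  set.seed(52)
  for (i in 1:8) {
    gen <- function() {
      rows <- lapply(1:12, function(j) {
        ab <- sample(mets, 4)
        rec(paste(sort(ab[1:2]), collapse = ","), paste(sort(ab[3:4]), collapse = ","),
            beta = paste(sample(1:3, 2), collapse = ","),
            eta = paste(sample(1:3, 2), collapse = ","))
      })
      make_records(rows, mets)
    }
    a <- gen(); b <- gen()
    for (mode in c("split", "split+coefficients")) {
      ov <- overlap_results(a, b, mode = mode)
      okey <- function(x) {
        sa <- vapply(strsplit(x$side_A, ","), function(v) paste(sort(v), collapse = ","), "")
        sb <- vapply(strsplit(x$side_B, ","), function(v) paste(sort(v), collapse = ","), "")
        lo <- pmin(sa, sb); hi <- pmax(sa, sb)
        k <- paste(lo, hi)
        if (mode == "split+coefficients") {
          k <- paste(k, ifelse(sa <= sb, x$beta, x$eta), ifelse(sa <= sb, x$eta, x$beta))
        }
        k
      }
      expect_equal(sum(ov$counts$shared), length(intersect(okey(a), okey(b))))
      expect_equal(sum(ov$counts$unique_a), length(setdiff(okey(a), okey(b))))
    }
  }
})

test_that("metabolite names are matched after case and whitespace folding", {
  a <- make_records(list(rec("Ala", "Gly")), c("Ala", "Gly"))
  b <- make_records(list(rec("ala", "gly ")), c("ala", "gly "))
  ov <- overlap_results(a, b)
  expect_equal(sum(ov$counts$shared), 1)
})
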