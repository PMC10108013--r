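test_that("normal scores are rank-based standard-normal quantiles", {
  x <- c(3, 1, 2, 5, 4, 6)
  expect_equal(normal_scores(x), qnorm(rank(x) / 7))
  expect_equal(normal_scores(sort(x)), qnorm((1:6) / 7))
  expect_equal(median(normal_scores(x)), 0)
  # missing values pass through; ranks use observed values only
  y <- c(3, NA, 1, 2, 5, 4, 6)
  ns <- normal_scores(y)
  expect_true(is.na(ns[2]))
  expect_equal(ns[-2], qnorm(rank(y[-2]) / 7))
  expect_error(normal_scores(rep(5, 6)), "constant")
  expect_error(normal_scores(c(1, 2, 3)), ">= 6")
})

test_that("local similarity matches hand-worked alignments", {
  xh <- c(0.6745, -0.6745, 0)
  ls <- local_similarity(xh, xh, D = 0)
  expect_equal(ls$score, (0.6745^2 * 2) / 3, tolerance = 1e-4)
  expect_identical(ls$delay, 0L)
  # sign antisymmetry
  neg <- local_similarity(xh, -xh, D = 0)
  expect_equal(neg$score, -ls$score)
  expect_identical(neg$delay, ls$delay)
  # one dominant pulse shifted by one interval is found at |delay| = 1,
  # and only once the delay window allows it
  x <- c(0, 0, 3, 0, 0, 0, 0, 0) + 0.01 * (1:8)
  y <- c(0, 0, 0, 3, 0, 0, 0, 0) + 0.01 * (8:1)
  d1 <- local_similarity(x, y, D = 1)
  d0 <- local_similarity(x, y, D = 0)
  expect_identical(d1$delay, 1L)
  expect_gt(abs(d1$score), abs(d0$score))
  expect_error(local_similarity(x, y[-1], D = 1), "lengths")
  expect_error(local_similarity(x, y, D = 8), "D")
})

test_that("dynamic program equals exhaustive segment enumeration", {
  set.seed(2024)
  for (trial in 1:300) {
    n <- sample(2:8, 1)
    D <- min(sample(0:2, 1), n - 1L)
    x <- rnorm(n); y <- rnorm(n)
    dp <- local_similarity(x, y, D)
    bf <- ls_brute_force(x, y, D)
    expect_equal(abs(dp$score), unname(bf[["score"]]), tolerance = 1e-10)
    expect_identical(dp$delay, as.integer(bf[["d"]]))
    if (bf[["score"]] > 1e-12) {
      expect_identical(sign(dp$score), unname(bf[["sgn"]]))
    }
  }
})

test_that("swapping the series negates the delay, keeps the magnitude", {
  set.seed(7)
  for (trial in 1:50) {
    x <- rnorm(12); y <- rnorm(12)
    a <- local_similarity(x, y, D = 2)
    b <- local_similarity(y, x, D = 2)
    expect_equal(abs(a$score), abs(b$score), tolerance = 1e-12)
    expect_identical(a$delay, -b$delay)
  }
})

test_that("the score never decreases as the delay window widens", {
  set.seed(8)
  for (trial in 1:30) {
    x <- rnorm(15); y <- rnorm(15)
    s <- vapply(0:4, function(D) abs(local_similarity(x, y, D)$score),
                numeric(1))
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("permutation p-values are seeded, floored and sane", {
  xh <- normal_scores(c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10, 12, 11))
  # a series against itself: no permutation should match the maximum
  expect_equal(ls_permutation_p(xh, xh, D = 1, n_perm = 200, seed = 42),
               1 / 201)
  y <- normal_scores(rnorm(12))
  p1 <- ls_permutation_p(xh, y, D = 1, n_perm = 200, seed = 9)
  expect_identical(p1, ls_permutation_p(xh, y, D = 1, n_perm = 200, seed = 9))
  expect_gt(p1, 0)
  expect_lte(p1, 1)
  expect_error(ls_permutation_p(xh, y, D = 1, n_perm = 50), "n_perm")
})

test_that("type-I error at p <= 0.05 is calibrated under the null", {
  set.seed(314)
  hits <- 0L
  n_pairs <- 1000L
  for (i in seq_len(n_pairs)) {
    x <- normal_scores(rnorm(30))
    y <- normal_scores(rnorm(30))
    p <- ls_permutation_p(x, y, D = 1, n_perm = 200, seed = i)
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits / n_pairs, 0.03)
  expect_lte(hits / n_pairs, 0.07)
})

test_that("all-pairs analysis handles gaps, q-values and ordering", {
  tr <- campaign_truth(n_dropout = 0L, seed = 5)
  tab <- simulate_campaign(tr)$table
  res <- lsa_all_pairs(tab, D = 1, n_perm = 200, seed = 1)
  expect_equal(nrow(res), choose(6, 2))
  expect_true(!is.unsorted(rev(abs(res$ls_score))))
  expect_true(all(res$q_value >= res$p_value))
  # a variable and its exact copy dominate the ranking
  tab2 <- tab[, c("date", "chl_a", "cyanobacteria", "sar11")]
  tab2$chl_copy <- tab2$chl_a
  res2 <- lsa_all_pairs(tab2, D = 1, n_perm = 200, seed = 2)
  expect_setequal(unlist(res2[1, c("var_x", "var_y")]),
                  c("chl_a", "chl_copy"))
  expect_equal(res2$p_value[1], min(res2$p_value))
  # 3 variables -> 3 pairs
  expect_equal(nrow(lsa_all_pairs(tab[, 1:4], D = 1, n_perm = 200,
                                      seed = 3)), 3L)
})

test_that("missing-value policy: interpolate single gaps, truncate runs", {
  set.seed(10)
  n <- 30
  base <- data.frame(date = seq(as.Date("2011-01-01"), by = "month",
                                length.out = n),
                     a = rnorm(n), b = rnorm(n))
  # single isolated gap: interpolated, full length used
  g1 <- base; g1$a[10] <- NA
  r1 <- lsa_all_pairs(g1, D = 1, n_perm = 200, seed = 4)
  expect_equal(r1$n_effective, n)
  # a run of >= 2 missing: pair truncated to the longest complete stretch
  g2 <- base; g2$a[10:12] <- NA
  r2 <- lsa_all_pairs(g2, D = 1, n_perm = 200, seed = 4)
  expect_equal(r2$n_effective, n - 12L)
  # constant and gappy variables are dropped with a message
  g3 <- base; g3$c <- 1
  expect_message(lsa_all_pairs(g3, D = 1, n_perm = 200, seed = 4),
                 "ineligible")
})

test_that("time-series CSV round trip preserves values and gaps", {
  tab <- simulate_campaign(campaign_truth(seed = 2))$table
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(tab, path)
  back <- read_timeseries(path)
  expect_equal(back$date, tab$date)
  expect_equal(back$chl_a, tab$chl_a, tolerance = 1e-12)
  expect_identical(is.na(back$sar11), is.na(tab$sar11))
})
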