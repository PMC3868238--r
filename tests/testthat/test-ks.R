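test_that("KS statistic reproduces hand-evaluated cases", {
  r <- ks_statistic(c(1, 2), 10)
  expect_equal(r$a, 0.8)
  expect_equal(r$b, 0.1)
  expect_equal(r$ks, 0.8)

  r <- ks_statistic(c(10, 9), 10)  # order irrelevant
  expect_equal(r$a, 0.0)
  expect_equal(r$b, 0.9)
  expect_equal(r$ks, -0.9)
  expect_equal(r$matched_query_ranks, c(9L, 10L))

  # query = entire panel: a = 0, b = 1/N
  r <- ks_statistic(1:10, 10)
  expect_equal(r$a, 0)
  expect_equal(r$ks, -0.1)
})

test_that("KS matches the brute-force oracle for every subset of N <= 8", {
  for (n in 1:8) {
    for (ranks in all_subsets(n)) {
      got <- ks_statistic(ranks, n)
      want <- ks_brute(ranks, n)
      expect_equal(got$a, want$a)
      expect_equal(got$b, want$b)
      expect_equal(got$ks, want$ks)
      expect_true(got$a >= 0 && got$b >= 0)
      expect_true(got$ks >= -1 && got$ks <= 1)
    }
  }
})

test_that("invalid rank sets are rejected", {
  expect_error(ks_statistic(integer(0), 10), "empty")
  expect_error(ks_statistic(c(1, 11), 10), "1\\.\\.10")
  expect_error(ks_statistic(c(0, 1), 10), "1\\.\\.10")
  expect_error(ks_statistic(c(3, 3), 10), "duplicate")
})

test_that("running sum matches its step-function oracle and peaks at a", {
  expect_equal(running_sum(c(1, 2), 10),
               c(0.4, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0))
  for (n in 1:8) {
    for (ranks in all_subsets(n)) {
      d <- running_sum(ranks, n)
      expect_equal(d, running_sum_brute(ranks, n))
      expect_equal(max(d), ks_statistic(ranks, n)$a)
      expect_equal(d[n], 0)  # all query kinases are in the profile
    }
  }
})

test_that("improving any single query rank never decreases KS", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    m <- sample(1:min(8, n - 1), 1)
    ranks <- sort(sample.int(n, m))
    ks0 <- ks_statistic(ranks, n)$ks
    # move one kinase to a strictly better unoccupied rank
    movable <- which(vapply(ranks, function(r)
      any(setdiff(seq_len(r - 1), ranks) > 0), logical(1)))
    if (length(movable) == 0L) next
    i <- sample(rep(movable, 2), 1)
    better <- setdiff(seq_len(ranks[i] - 1), ranks)
    ranks2 <- sort(c(ranks[-i], sample(rep(better, 2), 1)))
    expect_gte(ks_statistic(ranks2, n)$ks, ks0)
  }
})

test_that("connectivity scores rescale by P and Q with sign preserved", {
  expect_equal(connectivity_scores(c(0.8, -0.9, 0.4)), c(1, -1, 0.5))
  expect_equal(connectivity_scores(c(0.3, 0.3, 0.3)), c(1, 1, 1))
  expect_equal(connectivity_scores(0), 0)
  expect_equal(connectivity_scores(c(0, 0)), c(0, 0))
  # single drug is its own extreme
  expect_equal(connectivity_scores(-0.4), 1 * sign(-0.4) * 1)
  # NA (unscored drug) passes through and does not enter P/Q
  s <- connectivity_scores(c(0.5, NA, -0.2))
  expect_equal(s, c(1, NA, -1))
})

test_that("scores stay in [-1, 1] and the sign rule holds on random inputs", {
  set.seed(23)
  for (rep in 1:50) {
    ks <- round(stats::runif(sample(2:30, 1), -1, 1), 3)
    s <- connectivity_scores(ks)
    expect_true(all(s >= -1 & s <= 1))
    expect_equal(sign(s), sign(ks))
    if (any(ks > 0)) expect_equal(max(s), 1)
    if (any(ks < 0)) expect_equal(min(s), -1)
    # exactly the drugs attaining P (resp. Q) hit +1 (resp. -1)
    expect_equal(s == 1, ks == max(ks) & ks > 0)
    expect_equal(s == -1, ks == min(ks) & ks < 0)
  }
})

test_that("normalization is the affine map (S+1)/2 and preserves order", {
  expect_equal(normalize_scores(c(-1, 0, 0.8, 1)), c(0, 0.5, 0.9, 1))
  set.seed(5)
  s <- stats::runif(50, -1, 1)
  ns <- normalize_scores(s)
  expect_true(all(ns >= 0 & ns <= 1))
  expect_equal(order(ns), order(s))
  expect_error(normalize_scores(1.5), "\\[-1, 1\\]")
})
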