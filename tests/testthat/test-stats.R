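test_that("Clopper-Pearson reproduces published 95% bounds at 2 d.p.", {
  expect_equal(round(100 * clopper_pearson(64, 2339), 2),
               c(lo = 2.11, hi = 3.48))
  expect_equal(round(100 * clopper_pearson(8, 2339), 2),
               c(lo = 0.15, hi = 0.67))
  ci0 <- clopper_pearson(0, 2339)
  expect_identical(ci0[["lo"]], 0)
  expect_equal(round(100 * ci0[["hi"]], 2), 0.16)
  expect_identical(clopper_pearson(5, 5)[["hi"]], 1)
})

test_that("Clopper-Pearson matches the exact binomial test interval", {
  for (x in c(0, 3, 64, 500, 2339)) {
    expect_equal(unname(clopper_pearson(x, 2339)),
                 as.numeric(binom.test(x, 2339)$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("Wilson reproduces published 95% bounds at 2 d.p.", {
  expect_equal(round(100 * wilson(64, 2339), 2), c(lo = 2.15, hi = 3.48))
  expect_equal(round(100 * wilson(0, 2339), 2), c(lo = 0, hi = 0.16))
  expect_equal(round(100 * wilson(8, 2339), 2), c(lo = 0.17, hi = 0.67))
  expect_identical(wilson(0, 10)[["lo"]], 0)
})

test_that("both intervals contain x/n and shrink with n at fixed x/n", {
  for (m in c(clopper_pearson, wilson)) {
    for (x in c(0, 1, 7, 50)) {
      ci <- m(x, 100)
      expect_lte(ci[["lo"]], x / 100)
      expect_gte(ci[["hi"]], x / 100)
      wide <- diff(m(x, 100))
      narrow <- diff(m(10 * x, 1000))
      expect_lt(narrow, wide)
    }
  }
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(wilson(1, 10, level = 1.2), "level")
})

test_that("Pearson chi-squared matches independent computations", {
  # hand-expanded oracle on a 2x2
  m <- rbind(c(12, 5), c(3, 14))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  by_hand <- sum((m - E)^2 / E)
  got <- pearson_chi2(m)
  expect_equal(got$statistic, by_hand)
  expect_equal(got$df, 1)

  # cross-check against the standard implementation, no correction
  set.seed(9)
  for (rep in 1:10) {
    t <- matrix(rpois(6, 40) + 1, nrow = 2)
    ref_test <- suppressWarnings(chisq.test(t, correct = FALSE))
    mine <- pearson_chi2(t)
    expect_equal(mine$statistic, unname(ref_test$statistic))
    expect_equal(mine$df, unname(ref_test$parameter))
    expect_equal(mine$p_value, unname(ref_test$p.value))
  }

  # proportional rows give statistic 0; permutation invariance
  expect_equal(pearson_chi2(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  t <- rbind(c(7, 2, 9), c(1, 8, 3))
  expect_equal(pearson_chi2(t[, c(3, 1, 2)])$statistic,
               pearson_chi2(t)$statistic)
  expect_equal(pearson_chi2(t[2:1, ])$statistic, pearson_chi2(t)$statistic)

  # degenerate margins are dropped with a warning, df reduced
  expect_warning(out <- pearson_chi2(rbind(c(5, 0, 9), c(3, 0, 2))),
                 "dropping")
  expect_equal(out$df, 1)
  expect_error(pearson_chi2(rbind(c(1, -2), c(3, 4))), "non-negative")
})

# enumerate all R x C tables with the observed margins (tiny tables only)
enumerate_fisher_p <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  logp <- function(t) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(sum(t) + 1) - sum(lgamma(t + 1))
  tables <- list()
  fill <- function(partial, r) {
    if (r == length(rs)) {
      rest <- cs - colSums(do.call(rbind, partial))
      if (all(rest >= 0)) tables[[length(tables) + 1L]] <<-
          do.call(rbind, c(partial, list(rest)))
      return(invisible())
    }
    cells <- expand.grid(lapply(cs, function(x) 0:min(x, rs[r])))
    cells <- cells[rowSums(cells) == rs[r], , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      row <- as.numeric(cells[i, ])
      upto <- if (length(partial)) colSums(do.call(rbind, partial)) else 0
      if (all(upto + row <= cs)) fill(c(partial, list(row)), r + 1L)
    }
  }
  fill(list(), 1L)
  lp <- vapply(tables, logp, numeric(1))
  obs <- logp(m)
  sum(exp(lp[lp <= obs + 1e-7])) / sum(exp(lp))
}

test_that("Fisher exact matches enumeration and the standard test", {
  m <- rbind(c(0, 5), c(5, 0))
  expect_equal(fisher_exact(m)$p_value,
               unname(fisher.test(m)$p.value), tolerance = 1e-10)
  set.seed(12)
  for (rep in 1:10) {
    t <- matrix(rpois(4, 6), nrow = 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact(t)$p_value, unname(fisher.test(t)$p.value),
                 tolerance = 1e-9, info = paste(t, collapse = ","))
  }
  # zero margin
  expect_equal(fisher_exact(rbind(c(0, 0), c(3, 4)))$p_value, 1)
})

test_that("Monte-Carlo Fisher p converges to the enumeration p", {
  m <- rbind(c(3, 0, 2, 1), c(0, 2, 0, 3))  # sparse 2x4
  p_enum <- enumerate_fisher_p(m)
  mc <- fisher_exact(m, mc_draws = 20000L, seed = 99)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p_value - p_enum), 3 * mc$se + 1e-4)
})

test_that("outcome_table percentages and intervals are internally consistent", {
  counts <- c(cannot_exclude = 2275L, inconclusive = 64L, exclude = 0L)
  ot <- outcome_table(counts)
  expect_equal(sum(ot$count), 2339)
  expect_equal(sum(ot$percent), 100)
  expect_equal(round(ot$percent, 2), c(97.26, 2.74, 0.00))
  expect_equal(round(ot$cp_lo, 2), c(96.52, 2.11, 0.00))
  expect_equal(round(ot$cp_hi, 2), c(97.89, 3.48, 0.16))
  expect_equal(round(ot$wilson_lo, 2), c(96.52, 2.15, 0.00))
  expect_equal(round(ot$wilson_hi, 2), c(97.85, 3.48, 0.16))
  expect_true(all(ot$cp_lo <= ot$percent & ot$percent <= ot$cp_hi))
})
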