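ref <- synthetic_rcrs()

test_that("position_differs implements both heteroplasmy-handling rules", {
  A <- position_call(100, "A"); G <- position_call(100, "G")
  R <- position_call(100, c("A", "G"), 0.3)
  Y <- position_call(100, c("C", "T"), 0.3)
  # both homoplasmic
  expect_false(position_differs(A, A, "isfg"))
  expect_false(position_differs(A, A, "strict"))
  expect_true(position_differs(A, G, "isfg"))
  expect_true(position_differs(A, G, "strict"))
  # heteroplasmic sharing an allele with the homoplasmic type
  expect_false(position_differs(R, G, "isfg"))
  expect_true(position_differs(R, G, "strict"))
  expect_false(position_differs(G, R, "isfg"))  # symmetric
  # disjoint allele sets: a difference in both modes
  expect_true(position_differs(R, Y, "isfg"))
  expect_true(position_differs(R, Y, "strict"))
  # identical heteroplasmies never differ
  expect_false(position_differs(R, R, "strict"))
})

test_that("the three-tier outcome follows the difference count", {
  expect_equal(classify_outcome(0), "cannot_exclude")
  expect_equal(classify_outcome(1), "inconclusive")
  expect_equal(classify_outcome(2), "exclude")
  expect_equal(classify_outcome(7), "exclude")
  expect_error(classify_outcome(-1), "non-negative")
})

test_that("count_differences applies the mode rules over variant unions", {
  h0 <- parse_haplotype("", ref, "a")
  h1 <- parse_haplotype("A16247G", ref, "b")
  expect_equal(count_differences(h0, h1, "isfg", ref)$n_diff, 1)
  expect_equal(count_differences(h0, h1, "strict", ref)$n_diff, 1)

  het <- parse_haplotype("A2833R", ref, "c")
  expect_equal(count_differences(het, h0, "isfg", ref)$n_diff, 0)
  expect_equal(count_differences(het, h0, "strict", ref)$n_diff, 1)

  two <- parse_haplotype("T9012Y A16280R", ref, "d")
  expect_equal(count_differences(two, h0, "isfg", ref)$n_diff, 0)
  strict2 <- count_differences(two, h0, "strict", ref)
  expect_equal(strict2$n_diff, 2)
  expect_equal(strict2$outcome, "exclude")
  expect_equal(strict2$differing, c("9012", "16280"))
})

test_that("indel comparison requires token equality except isfg length-het", {
  i1 <- normalize_haplotype(parse_haplotype("315.1C", ref, "a"), ref)
  i2 <- normalize_haplotype(parse_haplotype("315.1C", ref, "b"), ref)
  lh <- normalize_haplotype(parse_haplotype("315.1c", ref, "c"), ref)
  h0 <- parse_haplotype("", ref, "z")
  expect_equal(count_differences(i1, i2, "strict", ref)$n_diff, 0)
  expect_equal(count_differences(i1, h0, "isfg", ref)$n_diff, 1)
  expect_equal(count_differences(i1, h0, "strict", ref)$n_diff, 1)
  # length heteroplasmy vs concordant fixed-length insertion
  expect_equal(count_differences(i1, lh, "isfg", ref)$n_diff, 0)
  expect_equal(count_differences(i1, lh, "strict", ref)$n_diff, 1)
})

test_that("masked-range variants never appear among differences", {
  # heteroplasmy inside the HVI C-stretch is dropped on normalization
  h <- normalize_haplotype(parse_haplotype("T16189C A16247G", ref, "a"), ref)
  d <- count_differences(h, parse_haplotype("", ref, "b"), "strict", ref)
  expect_equal(d$differing, "16247")
})

test_that("isfg differences are a subset of strict differences", {
  r <- tiny_ref()
  set.seed(31)
  for (rep in 1:30) {
    h1 <- random_point_haplotype(r, "x", 6)
    h2 <- random_point_haplotype(r, "y", 6)
    di <- count_differences(h1, h2, "isfg", r)
    ds <- count_differences(h1, h2, "strict", r)
    expect_true(all(di$differing %in% ds$differing))
    # symmetry in both modes
    expect_equal(count_differences(h2, h1, "isfg", r)$n_diff, di$n_diff)
    expect_equal(count_differences(h2, h1, "strict", r)$n_diff, ds$n_diff)
  }
})

test_that("variant-union comparison equals a full position-by-position scan", {
  r <- tiny_ref(masked = cbind(13, 16))
  set.seed(47)
  for (rep in 1:20) {
    h1 <- normalize_haplotype(random_point_haplotype(r, "x", 8), r)
    h2 <- normalize_haplotype(random_point_haplotype(r, "y", 8), r)
    for (mode in c("isfg", "strict")) {
      expect_equal(count_differences(h1, h2, mode, r)$n_diff,
                   oracle_count_diffs(h1, h2, mode, r),
                   info = paste(mode, encode_haplotype(h1, r), "|",
                                encode_haplotype(h2, r)))
    }
  }
})

test_that("no-call positions are excluded from comparison", {
  r <- tiny_ref()
  h1 <- parse_haplotype("A1G", r, "a")
  h2 <- parse_haplotype("", r, "b")
  attr(h2, "no_call") <- 1L
  expect_equal(count_differences(h1, h2, "strict", r)$n_diff, 0)
})

test_that("compare_all aggregates outcomes and the meiosis matrix", {
  fx <- build_two_family_fixture(ref)
  en <- enumerate_pairs(fx$pedigree)

  # all-identical haplotypes: everything cannot_exclude
  same <- lapply(fx$haplotypes, function(h) {
    mito_haplotype(h$sample_id, NULL, ref)
  })
  all_same <- compare_all(en$pairs, same, "isfg", ref)
  expect_equal(unname(all_same$outcome_counts["cannot_exclude"]),
               nrow(en$pairs))

  # the two-family case structure: 6 + 58 = 64 inconclusive pairs in isfg
  ci <- compare_all(en$pairs, fx$haplotypes, "isfg", ref)
  expect_equal(unname(ci$outcome_counts["inconclusive"]), 64)
  expect_equal(unname(ci$outcome_counts["exclude"]), 0)
  f8 <- en$pairs[en$pairs$clan == "F08-0", ]
  c8 <- compare_all(f8, fx$haplotypes, "isfg", ref)
  expect_equal(unname(c8$outcome_counts),
               c(15L, 6L, 0L))

  # strict mode never increases the cannot_exclude count
  cs <- compare_all(en$pairs, fx$haplotypes, "strict", ref)
  expect_gte(unname(ci$outcome_counts["cannot_exclude"]),
             unname(cs$outcome_counts["cannot_exclude"]))
  # matrix margins agree with totals
  expect_equal(sum(ci$meioses_matrix), ci$n_pairs)
  expect_equal(sum(ci$meioses_matrix[, "1"]), 64)

  expect_error(compare_all(en$pairs, fx$haplotypes[-1], "isfg", ref),
               "no haplotype")
})
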