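ref <- synthetic_rcrs()

test_that("simulated pedigrees have the configured shape", {
  cfg1 <- simulation_config(n_families = 1, generations_total = 2,
                            sampled_generations = 2, mean_daughters = 0,
                            mean_sons = 0, seed = 3)
  ped1 <- simulate_pedigree(cfg1)
  # forced line survival gives founder + 1 child, both sampled: 1 pair
  expect_equal(nrow(ped1), 2)
  en1 <- enumerate_pairs(ped1)
  expect_equal(nrow(en1$pairs), 1)
  expect_equal(en1$pairs$meioses, 1)

  cfg <- simulation_config(n_families = 45, generations_total = 6,
                           sampled_generations = 3, seed = 8)
  ped <- simulate_pedigree(cfg)
  expect_equal(length(maternal_clans(ped)), 45)
  en <- enumerate_pairs(ped)
  sizes <- table(ped$clan[ped$sampled])
  expect_equal(nrow(en$pairs), sum(choose(sizes, 2)))
})

test_that("transmission with zero rates and no heteroplasmy is identity", {
  cfg <- simulation_config(substitution_rate = 0, heteroplasmy_rate = 0,
                           seed = 1)
  mother <- normalize_haplotype(parse_haplotype("A16247G", ref, "m"), ref)
  set.seed(10)
  child <- transmit(mother, cfg, ref, "c")
  expect_identical(child$variants, mother$variants)
  expect_length(attr(child, "events"), 0)
})

test_that("heteroplasmy MAF drift is a bottleneck-binomial martingale", {
  cfg <- simulation_config(substitution_rate = 0, heteroplasmy_rate = 0,
                           bottleneck_n = 30, seed = 1)
  mother <- parse_haplotype("A2833R", ref, "m")
  mother$variants$maf <- 0.3
  mother$variants$minor <- "G"
  mother <- normalize_haplotype(mother, ref)
  set.seed(20250101)
  freqs <- replicate(10000, {
    ch <- transmit(mother, cfg, ref, "c")
    v <- ch$variants
    if (nrow(v) == 0) 0                      # lost (reverted to reference A)
    else if (v$kind == "substitution") 1     # fixed to G
    else if (v$minor == "G") v$maf else 1 - v$maf
  })
  # martingale: mean transmitted frequency of the designated allele ~ 0.3
  se <- sqrt(0.3 * 0.7 / 30) / sqrt(10000)
  expect_lt(abs(mean(freqs) - 0.3), 4 * se)
  # support is k/N_b
  expect_true(all(abs(freqs * 30 - round(freqs * 30)) < 1e-9))
})

test_that("loss probability follows the binomial zero-draw closed form", {
  cfg <- simulation_config(substitution_rate = 0, heteroplasmy_rate = 0,
                           bottleneck_n = 10, seed = 1)
  mother <- parse_haplotype("A2833R", ref, "m")
  mother$variants$maf <- 0.1
  mother$variants$minor <- "G"
  mother <- normalize_haplotype(mother, ref)
  set.seed(404)
  lost <- replicate(4000, {
    ch <- transmit(mother, cfg, ref, "c")
    nrow(ch$variants) == 0
  })
  p_loss <- (1 - 0.1)^10
  expect_lt(abs(mean(lost) - p_loss),
            4 * sqrt(p_loss * (1 - p_loss) / 4000))
})

test_that("fixation plus loss grows as the bottleneck shrinks", {
  mk <- function(nb) simulation_config(substitution_rate = 0,
                                       heteroplasmy_rate = 0,
                                       bottleneck_n = nb, seed = 1)
  mother <- parse_haplotype("A2833R", ref, "m")
  mother$variants$maf <- 0.3
  mother <- normalize_haplotype(mother, ref)
  fixrate <- function(cfg) {
    mean(replicate(2000, {
      ch <- transmit(mother, cfg, ref, "c")
      nrow(ch$variants) == 0 || ch$variants$kind[1] == "substitution"
    }))
  }
  set.seed(55)
  expect_gt(fixrate(mk(5)), fixrate(mk(40)))
})

test_that("read simulation respects depth bounds and the allele mix", {
  r <- tiny_ref()
  cfg <- simulation_config(depth_median = 370, depth_min = 139,
                           depth_max = 1316, error_rate = 0, seed = 1)
  h <- parse_haplotype("A2833R", ref, "m")
  h$variants$maf <- 0.39
  h$variants$minor <- "A"
  h <- normalize_haplotype(h, ref)
  set.seed(61)
  pu <- simulate_reads(h, ref, cfg)
  depth <- rowSums(pu[, c("A", "C", "G", "T")])
  expect_true(all(depth >= 139 & depth <= 1316))
  # called MAF within binomial 99% bounds of the true 0.39 at that depth
  row <- pu[pu$position == 2833, ]
  d <- sum(row[, c("A", "C", "G", "T")])
  bounds <- qbinom(c(0.005, 0.995), d, 0.39) / d
  expect_gte(row$A / d, bounds[1])
  expect_lte(row$A / d, bounds[2])

  # zero error + homoplasmic haplotype: calls recover it exactly
  cfg2 <- simulation_config(depth_median = 40, depth_min = 5,
                            depth_max = 100, error_rate = 0, seed = 1)
  h2 <- parse_haplotype("A1G 9DEL", r, "x")
  set.seed(62)
  pu2 <- simulate_reads(h2, r, cfg2)
  called <- call_haplotype(pu2, r, sample_id = "x")
  pt <- called$variants[called$variants$kind == "substitution", ]
  expect_equal(pt$position, 1)
  expect_equal(pt$alleles, "G")
})

test_that("identical seeds give byte-identical simulations", {
  cfg <- simulation_config(n_families = 4, generations_total = 5,
                           sampled_generations = 3, seed = 77)
  s1 <- simulate_study(cfg, ref)
  s2 <- simulate_study(cfg, ref)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(lapply(s1$haplotypes, `[[`, "variants"),
                   lapply(s2$haplotypes, `[[`, "variants"))
  s3 <- simulate_study(simulation_config(n_families = 4,
                                         generations_total = 5,
                                         sampled_generations = 3,
                                         seed = 78), ref)
  expect_false(identical(s1$pedigree, s3$pedigree))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(substitution_rate = 1.2), "rates")
  expect_error(simulation_config(bottleneck_n = 0), "bottleneck_n")
  expect_error(simulation_config(seed = NA), "seed")
  expect_error(simulation_config(sampled_generations = 9,
                                 generations_total = 4), "exceed")
})

test_that("the two-family fixture is deterministic with the case structure", {
  fx1 <- build_two_family_fixture(ref)
  fx2 <- build_two_family_fixture(ref)
  expect_identical(fx1$pedigree, fx2$pedigree)
  expect_identical(lapply(fx1$haplotypes, encode_haplotype, reference = ref),
                   lapply(fx2$haplotypes, encode_haplotype, reference = ref))
  sizes <- sort(as.integer(table(fx1$pedigree$clan[fx1$pedigree$sampled])))
  expect_equal(sizes, c(7L, 59L))
  carrier <- fx1$haplotypes[["F12-D1-1"]]
  expect_equal(carrier$variants$maf, 0.39)
  expect_equal(carrier$variants$minor, "A")
})
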