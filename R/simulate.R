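#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults emulate the shape
#' of a large multigenerational isolate cohort: 45 maternal families over
#' 10 generations with only the last 4 generations sampled (so sampled
#' pairs span roughly 1-18 meioses), rare private substitutions, germline
#' heteroplasmy governed by a single-bottleneck binomial drift of N_b
#' segregating units per transmission, and per-position sequencing depth
#' log-normal around a median of ~370X clipped to [139, 1316].
#'
#' @param n_families Number of disjoint maternal clans.
#' @param generations_total Generations per clan including the founder.
#' @param sampled_generations How many of the last generations are sampled.
#' @param mean_daughters,mean_sons Poisson means for per-mother offspring
#'   counts (daughters continue the maternal line).
#' @param substitution_rate Probability of a new homoplasmic substitution
#'   per transmission per genome.
#' @param heteroplasmy_rate Probability of a new point heteroplasmy per
#'   transmission per genome.
#' @param bottleneck_n Germline bottleneck size N_b (segregating units);
#'   each heteroplasmic MAF is resampled as Binomial(N_b, maf)/N_b.
#' @param fixation_threshold MAFs drawn at or below this (or at or above
#'   1 - this) convert to homoplasmy; default 0 so only exact 0/N_b and
#'   N_b/N_b draws fix.
#' @param depth_median,depth_min,depth_max,depth_sdlog Per-position depth
#'   model: `exp(rnorm(log(depth_median), depth_sdlog))` clipped to
#'   [depth_min, depth_max].
#' @param error_rate Per-base sequencing error rate, redistributed
#'   uniformly over the three other bases.
#' @param seed Integer seed; mandatory, every simulation is reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 45L,
                              generations_total = 10L,
                              sampled_generations = 4L,
                              mean_daughters = 0.7,
                              mean_sons = 0.6,
                              substitution_rate = 0.002,
                              heteroplasmy_rate = 0.004,
                              bottleneck_n = 30L,
                              fixation_threshold = 0,
                              depth_median = 370,
                              depth_min = 139,
                              depth_max = 1316,
                              depth_sdlog = 0.33,
                              error_rate = 0.001,
                              seed = 1L) {
  rates <- c(substitution_rate, heteroplasmy_rate, error_rate,
             fixation_threshold)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (bottleneck_n < 1) stop("bottleneck_n must be >= 1")
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (sampled_generations > generations_total) {
    stop("sampled_generations cannot exceed generations_total")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a multigenerational maternal pedigree
#'
#' Each family starts from one founding mother; every female has
#' Poisson-distributed daughters and sons each generation (at least one
#' daughter is forced in non-final generations of the founder line so no
#' clan dies out before reaching full depth). Only individuals in the last
#' `sampled_generations` generations are marked sampled.
#'
#' @param config A [simulation_config()].
#' @param rng Unused hook for an external RNG stream; randomness is driven
#'   by `config$seed` via a local RNG scope.
#' @return A `pedigree`.
#' @export
simulate_pedigree <- function(config, rng = NULL) {
  withr_local_seed(config$seed, {
    rows <- list()
    first_sampled <- config$generations_total - config$sampled_generations + 1L
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("F%02d", f)
      founder <- paste0(fam, "-G1-1")
      rows[[length(rows) + 1L]] <- data.frame(
        id = founder, mother_id = NA_character_, sex = "F", family = fam,
        sampled = as.integer(1L >= first_sampled), stringsAsFactors = FALSE)
      mothers <- founder
      for (g in 2:config$generations_total) {
        kids <- character(0)
        counter <- 0L
        for (m in mothers) {
          nd <- stats::rpois(1, config$mean_daughters)
          ns <- stats::rpois(1, config$mean_sons)
          # the founding line always carries at least one daughter, so every
          # clan reaches the configured depth
          if (m == mothers[1] && nd == 0L) nd <- 1L
          sexes <- c(rep("F", nd), rep("M", ns))
          for (s in sexes) {
            counter <- counter + 1L
            id <- paste0(fam, "-G", g, "-", counter)
            rows[[length(rows) + 1L]] <- data.frame(
              id = id, mother_id = m, sex = s, family = fam,
              sampled = as.integer(g >= first_sampled),
              stringsAsFactors = FALSE)
            if (s == "F") kids <- c(kids, id)
          }
        }
        mothers <- kids
        if (length(mothers) == 0L) break
      }
    }
    if (length(rows) == 0L) stop("impossible shape: no individuals generated")
    load_pedigree(do.call(rbind, rows))
  })
}

#' Build a pedigree matching a pairs-per-meiosis histogram exactly
#'
#' A shape-matching helper: constructs a synthetic maternal pedigree whose
#' sampled-pair meiosis histogram equals the given one exactly. Each
#' required pair becomes its own small clan - a founding mother with two
#' maternal chains of combined length m whose two terminal individuals are
#' the only sampled members - so the clans are independent and the
#' histogram is reproduced by construction. No attempt is made to mimic a
#' real pedigree's topology.
#'
#' @param histogram Data frame with columns `meioses` and `count`, e.g.
#'   [ni_pair_histogram()].
#' @return A `pedigree` whose [enumerate_pairs()] histogram equals the
#'   input.
#' @export
pedigree_from_histogram <- function(histogram) {
  acc <- list()
  clan <- 0L
  for (r in seq_len(nrow(histogram))) {
    m <- histogram$meioses[r]
    if (m < 1) stop("meiosis categories must be >= 1")
    for (k in seq_len(histogram$count[r])) {
      clan <- clan + 1L
      fname <- sprintf("H%05d", clan)
      la <- m %/% 2L          # chain lengths from the founding mother
      lb <- m - la
      founder <- paste0(fname, "-0")
      ids <- founder; moms <- NA_character_
      sexes <- "F"; samp <- as.integer(la == 0L)
      for (side in c("a", "b")) {
        len <- if (side == "a") la else lb
        if (len == 0L) next
        chain <- paste0(fname, "-", side, seq_len(len))
        ids <- c(ids, chain)
        moms <- c(moms, c(founder, chain[-len]))
        sexes <- c(sexes, c(rep("F", len - 1L), "U"))
        samp <- c(samp, c(rep(0L, len - 1L), 1L))
      }
      acc[[clan]] <- list(ids = ids, moms = moms, sexes = sexes,
                          samp = samp, fam = rep(fname, length(ids)))
    }
  }
  load_pedigree(data.frame(
    id = unlist(lapply(acc, `[[`, "ids")),
    mother_id = unlist(lapply(acc, `[[`, "moms")),
    sex = unlist(lapply(acc, `[[`, "sexes")),
    family = unlist(lapply(acc, `[[`, "fam")),
    sampled = unlist(lapply(acc, `[[`, "samp")),
    stringsAsFactors = FALSE))
}

#' Published pairs-per-meiosis histogram of the Norfolk Island cohort
#'
#' The number of maternally related pairs per meiotic category (1-18) in
#' the 2339-pair Norfolk Island whole-mtGenome study, usable as the target
#' shape for [pedigree_from_histogram()].
#'
#' @return Data frame with `meioses` (1..18) and `count` (sums to 2339).
#' @export
ni_pair_histogram <- function() {
  data.frame(
    meioses = 1:18,
    count = c(71L, 94L, 72L, 73L, 67L, 55L, 41L, 51L, 90L, 149L, 265L,
              316L, 339L, 323L, 211L, 96L, 18L, 8L))
}

#' One mother-to-child mtDNA transmission
#'
#' Homoplasmic variants are inherited verbatim. Each heteroplasmic variant
#' passes through a germline bottleneck: its MAF is resampled as
#' Binomial(N_b, maf)/N_b, converting to homoplasmy for the major allele
#' (loss) when drawn to 0 or for the minor allele (fixation) when drawn to
#' 1. De-novo substitutions and heteroplasmies arise at the configured
#' per-transmission rates at uniformly random unmasked positions not
#' already variant; de-novo heteroplasmies start at a MAF drawn uniformly
#' from (maf_floor, 0.5] so they are callable at the default >20% rule.
#'
#' @param mother_hap Normalized `mito_haplotype` of the mother.
#' @param config A [simulation_config()].
#' @param reference A `mito_reference`.
#' @param child_id Sample id for the child haplotype.
#' @param maf_floor Lower bound of the de-novo MAF draw (default 0.20;
#'   lower it to seed sub-threshold heteroplasmies that the calling rule
#'   will report as homoplasmic substitutions).
#' @return The child `mito_haplotype` with attribute `events`, a character
#'   vector describing inheritance, drift, fixation, loss and de-novo
#'   changes.
#' @export
transmit <- function(mother_hap, config, reference = synthetic_rcrs(),
                     child_id = paste0(mother_hap$sample_id, ".child"),
                     maf_floor = 0.20) {
  v <- mother_hap$variants
  events <- character(0)
  keep <- rep(TRUE, nrow(v))
  if (nrow(v) > 0L) {
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] != "point_heteroplasmy") next
      maf <- v$maf[i]
      if (is.na(maf)) maf <- 0.3
      alleles <- strsplit(v$alleles[i], "")[[1]]
      rb <- ref_base(v$position[i], reference)
      minor <- v$minor[i]
      if (is.na(minor)) {
        nonref <- setdiff(alleles, rb)
        minor <- if (length(nonref) == 1L) nonref else alleles[2]
      }
      major <- setdiff(alleles, minor)[1]
      k <- stats::rbinom(1, config$bottleneck_n, maf)
      freq <- k / config$bottleneck_n  # post-bottleneck frequency of `minor`
      fixed_to <- NULL
      if (freq <= config$fixation_threshold || k == 0L) {
        fixed_to <- major
        events <- c(events, paste0("loss@", v$position[i]))
      } else if (freq >= 1 - config$fixation_threshold ||
                 k == config$bottleneck_n) {
        fixed_to <- minor
        events <- c(events, paste0("fixation@", v$position[i]))
      }
      if (!is.null(fixed_to)) {
        if (fixed_to == rb) {
          keep[i] <- FALSE
        } else {
          v$kind[i] <- "substitution"; v$alleles[i] <- fixed_to
          v$maf[i] <- NA_real_; v$minor[i] <- NA_character_
        }
      } else {
        if (freq > 0.5) {  # the designated minor allele became the major
          tmp <- minor; minor <- major; major <- tmp
          freq <- 1 - freq
        }
        v$maf[i] <- freq
        v$minor[i] <- minor
        events <- c(events, sprintf("drift@%d:%.3f->%.3f", v$position[i],
                                    maf, v$maf[i]))
      }
    }
    v <- v[keep, , drop = FALSE]
  }
  occupied <- v$position
  free_pos <- function() {
    repeat {
      p <- sample.int(reference$length, 1)
      if (!is_masked(p, reference) && !(p %in% occupied)) return(p)
    }
  }
  if (stats::runif(1) < config$substitution_rate) {
    p <- free_pos(); occupied <- c(occupied, p)
    rb <- ref_base(p, reference)
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    v <- rbind(v, .variant_row(p, "substitution", alt))
    events <- c(events, paste0("denovo_sub@", p))
  }
  if (stats::runif(1) < config$heteroplasmy_rate) {
    p <- free_pos()
    rb <- ref_base(p, reference)
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    maf <- stats::runif(1, maf_floor, 0.5)
    v <- rbind(v, .variant_row(p, "point_heteroplasmy",
                               paste(sort(c(rb, alt)), collapse = ""),
                               maf = maf, minor = alt))
    events <- c(events, paste0("denovo_het@", p))
  }
  child <- normalize_haplotype(mito_haplotype(child_id, v, reference),
                               reference)
  attr(child, "events") <- events
  child
}

#' Simulate a read-count pileup for one haplotype
#'
#' Per-position depth is drawn log-normally around the configured median
#' and clipped to [depth_min, depth_max]; reads are multinomial draws from
#' the sample's true allele mix at each position (heteroplasmic MAF
#' respected) with the per-base error rate redistributed uniformly over the
#' other three bases.
#'
#' @param hap Normalized `mito_haplotype`.
#' @param reference A `mito_reference`.
#' @param config A [simulation_config()].
#' @return Pileup data frame (`position`, `A`, `C`, `G`, `T`).
#' @export
simulate_reads <- function(hap, reference, config) {
  L <- reference$length
  depth <- round(exp(stats::rnorm(L, log(config$depth_median),
                                  config$depth_sdlog)))
  depth <- pmin(pmax(depth, config$depth_min), config$depth_max)
  bases <- c("A", "C", "G", "T")
  truth <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, bases))
  truth[cbind(seq_len(L), match(reference$bases, bases))] <- 1
  v <- hap$variants
  if (nrow(v) > 0L) {
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] == "substitution") {
        truth[v$position[i], ] <- 0
        truth[v$position[i], v$alleles[i]] <- 1
      } else if (v$kind[i] == "point_heteroplasmy") {
        alleles <- strsplit(v$alleles[i], "")[[1]]
        maf <- if (is.na(v$maf[i])) 0.3 else v$maf[i]
        rb <- ref_base(v$position[i], reference)
        minor <- v$minor[i]
        if (is.na(minor)) {
          nonref <- setdiff(alleles, rb)
          minor <- if (length(nonref) == 1L) nonref else alleles[2]
        }
        major <- setdiff(alleles, minor)[1]
        truth[v$position[i], ] <- 0
        truth[v$position[i], major] <- 1 - maf
        truth[v$position[i], minor] <- maf
      }
      # indel kinds do not alter per-position base counts in this model
    }
  }
  # redistribute error mass uniformly over the three non-true bases
  e <- config$error_rate
  probs <- truth * (1 - e) + (e / 3) * (rowSums(truth) - truth)
  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, bases))
  for (p in seq_len(L)) {
    counts[p, ] <- stats::rmultinom(1, depth[p], probs[p, ])
  }
  data.frame(position = seq_len(L), A = counts[, "A"], C = counts[, "C"],
             G = counts[, "G"], T = counts[, "T"])
}

#' Simulate a complete study end to end
#'
#' Pedigree, founder haplotypes (reference-identical by default),
#' transmission down every maternal line, and optionally read-count pileups
#' recalled through the MAF-threshold rule; all under one seed.
#'
#' @param config A [simulation_config()].
#' @param reference A `mito_reference`.
#' @param with_reads If `TRUE`, haplotypes are re-derived from simulated
#'   pileups via [call_haplotype()] (slower); otherwise the transmitted
#'   haplotypes are used directly.
#' @param calling A [calling_config()] used when `with_reads = TRUE`.
#' @return List `pedigree`, `haplotypes` (named list), `pairs` (from
#'   [enumerate_pairs()]), `config`.
#' @export
simulate_study <- function(config, reference = synthetic_rcrs(),
                           with_reads = FALSE,
                           calling = calling_config()) {
  ped <- simulate_pedigree(config)
  withr_local_seed(config$seed + 1L, {
    haps <- list()
    # transmit in pedigree order: mothers always precede children
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      if (is.na(ped$mother_id[i])) {
        haps[[id]] <- mito_haplotype(id, NULL, reference)
      } else {
        haps[[id]] <- transmit(haps[[ped$mother_id[i]]], config, reference,
                               child_id = id)
      }
    }
    sampled_ids <- ped$id[ped$sampled]
    haps <- haps[sampled_ids]
    if (with_reads) {
      haps <- lapply(haps, function(h) {
        call_haplotype(simulate_reads(h, reference, config), reference,
                       calling, sample_id = h$sample_id)
      })
    }
    list(pedigree = ped, haplotypes = haps, pairs = enumerate_pairs(ped),
         config = config)
  })
}
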