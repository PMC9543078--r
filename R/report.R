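#' Annotate a position with its mitochondrial region
#'
#' The control region spans the origin (16024..L and 1..576 by default) and
#' contains the hypervariable regions HVI (16024-16365), HVII (57-372) and
#' HVIII (438-574); everything else is coding region. Boundaries follow the
#' common forensic convention and are configurable.
#'
#' @param position Integer vector of 1-based positions.
#' @param regions Optional list overriding the boundary conventions:
#'   `control` (two rows: start, end), `hv1`, `hv2`, `hv3` (c(start, end)).
#' @param L Reference length (for range checking).
#' @return Character vector of labels such as `"HVI (Control region)"`,
#'   `"Control region"` or `"Coding region"`.
#' @export
#' @examples
#' region_annotate(c(16247, 8817, 146))
region_annotate <- function(position, regions = NULL, L = 16569L) {
  if (is.null(regions)) {
    regions <- list(control = rbind(c(16024L, L), c(1L, 576L)),
                    hv1 = c(16024L, 16365L), hv2 = c(57L, 372L),
                    hv3 = c(438L, 574L))
  }
  if (any(position < 1L) || any(position > L)) {
    stop("position out of range [1, ", L, "]")
  }
  in_range <- function(p, r) p >= r[1] & p <= r[2]
  vapply(position, function(p) {
    if (in_range(p, regions$hv1)) return("HVI (Control region)")
    if (in_range(p, regions$hv2)) return("HVII (Control region)")
    if (in_range(p, regions$hv3)) return("HVIII (Control region)")
    ctrl <- any(apply(regions$control, 1, function(r) in_range(p, r)))
    if (ctrl) "Control region" else "Coding region"
  }, character(1))
}

# Table-2-analog: variants appearing in sampled haplotypes, with region,
# type, carrier count and number of carrying maternal lineages
.variant_summary <- function(haplotypes, pedigree, reference) {
  recs <- list()
  for (h in haplotypes) {
    v <- h$variants
    if (nrow(v) == 0L) next
    tok <- strsplit(encode_haplotype(h, reference), " ")[[1]]
    for (i in seq_len(nrow(v))) {
      recs[[length(recs) + 1L]] <- data.frame(
        token = tok[i], position = v$position[i], kind = v$kind[i],
        carrier = h$sample_id, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(token = character(0), region = character(0),
                      type = character(0), n_carriers = integer(0),
                      n_lineages = integer(0)))
  }
  df <- do.call(rbind, recs)
  df$clan <- pedigree$clan[match(df$carrier, pedigree$id)]
  agg <- do.call(rbind, lapply(split(df, df$token), function(g) {
    data.frame(token = g$token[1], position = g$position[1],
               region = region_annotate(g$position[1]),
               type = chartr("_", " ", g$kind[1]),
               n_carriers = nrow(g),
               n_lineages = length(unique(g$clan)),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Study configuration
#'
#' Reads (or builds) the pipeline configuration: heteroplasmy calling
#' threshold, minimum depth, confidence level, and which comparison modes
#' to run. YAML keys mirror the argument names.
#'
#' @param path Optional YAML file.
#' @param ... Overrides (`maf_threshold`, `min_depth`, `level`, `modes`).
#' @return Named list.
#' @export
study_config <- function(path = NULL, ...) {
  cfg <- list(maf_threshold = 0.20, min_depth = 1L, level = 0.95,
              modes = c("isfg", "strict"))
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    unknown <- setdiff(names(y), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!all(cfg$modes %in% c("isfg", "strict"))) {
    stop("modes must be a subset of isfg/strict")
  }
  cfg
}

#' Run the full interpretation study
#'
#' The end-to-end pipeline: load the pedigree and sequence data, normalize
#' (calling from pileups first if given), enumerate all sampled maternal
#' pairs with meiosis counts, compare every pair under each requested mode,
#' and summarize with outcome percentages, Clopper-Pearson and Wilson
#' confidence intervals, a per-meiosis difference matrix, and a chi-squared
#' comparison of the modes' outcome distributions.
#'
#' @param pedigree A `pedigree` or path to a pedigree TSV.
#' @param sequences Either a named list of `mito_haplotype`, a path to a
#'   haplotype table file, or a named list of pileup data frames (detected
#'   by columns); pileups are converted with [call_haplotype()].
#' @param config A [study_config()] list.
#' @param reference A `mito_reference`.
#' @return A list of class `study_report`: `histogram`, `variant_table`,
#'   `outcome_tables` (per mode), `comparisons` (per mode, incl. the
#'   meioses-by-differences matrix), `chi_squared` (`NULL` with a single
#'   mode), `meta`.
#' @export
run_study <- function(pedigree, sequences, config = study_config(),
                      reference = synthetic_rcrs()) {
  if (is.character(pedigree)) pedigree <- read_pedigree_tsv(pedigree)
  if (is.character(sequences)) sequences <- read_haplotypes(sequences,
                                                            reference)
  calling <- calling_config(config$maf_threshold, config$min_depth)
  haplotypes <- lapply(sequences, function(s) {
    if (is.data.frame(s)) {
      call_haplotype(s, reference, calling)
    } else {
      normalize_haplotype(s, reference)
    }
  })
  if (is.data.frame(sequences[[1]])) {
    # sample ids come from list names when pileups are supplied
    for (id in names(haplotypes)) haplotypes[[id]]$sample_id <- id
  }
  names(haplotypes) <- vapply(haplotypes, `[[`, character(1), "sample_id")

  sampled <- pedigree$id[pedigree$sampled]
  missing_ids <- setdiff(sampled, names(haplotypes))
  if (length(missing_ids)) {
    stop("missing sequence data for sampled individual(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  enum <- enumerate_pairs(pedigree)

  comparisons <- list(); outcome_tables <- list()
  for (mode in config$modes) {
    cmp <- compare_all(enum$pairs, haplotypes, mode, reference)
    comparisons[[mode]] <- cmp
    outcome_tables[[mode]] <- outcome_table(cmp, level = config$level)
  }
  chi <- NULL
  if (length(config$modes) >= 2L) {
    counts <- do.call(rbind, lapply(comparisons,
                                    function(cmp) cmp$outcome_counts))
    chi <- tryCatch(pearson_chi2(counts),
                    error = function(e) list(error = conditionMessage(e)))
  }
  structure(list(
    histogram = enum$histogram,
    variant_table = .variant_summary(haplotypes[sampled], pedigree,
                                     reference),
    outcome_tables = outcome_tables,
    comparisons = comparisons,
    chi_squared = chi,
    meta = list(n_individuals = length(sampled),
                n_pairs = nrow(enum$pairs),
                n_clans = length(unique(pedigree$clan)),
                modes = config$modes,
                maf_threshold = config$maf_threshold,
                level = config$level,
                package_version = as.character(
                  utils::packageVersion("mitokin")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$meta$n_individuals, "individuals,",
      x$meta$n_pairs, "maternal pairs,", x$meta$n_clans, "clans\n")
  for (mode in names(x$outcome_tables)) {
    cat("\nmode:", mode, "\n")
    ot <- x$outcome_tables[[mode]]
    ot[, 3:7] <- round(ot[, 3:7], 2)
    print(ot, row.names = FALSE)
  }
  if (!is.null(x$chi_squared) && is.null(x$chi_squared$error)) {
    cat(sprintf("\nmode comparison: X-squared = %.3f, df = %d, p = %.3g\n",
                x$chi_squared$statistic, x$chi_squared$df,
                x$chi_squared$p_value))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits, under `dir`: `histogram.csv` (pairs per meiosis category),
#' `variants.csv` (differing-variant table with region annotation), one
#' `comparison_<mode>.csv` per mode (per-pair rows), one
#' `meioses_matrix_<mode>.csv` per mode, and `stats.json` (outcome counts,
#' percentages, both CI methods, chi-squared block and run metadata).
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$histogram, file.path(dir, "histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(report$variant_table, file.path(dir, "variants.csv"),
                   row.names = FALSE)
  for (mode in names(report$comparisons)) {
    write_comparison_csv(report$comparisons[[mode]],
                         file.path(dir, paste0("comparison_", mode, ".csv")))
    mm <- report$comparisons[[mode]]$meioses_matrix
    utils::write.csv(as.data.frame.matrix(mm),
                     file.path(dir, paste0("meioses_matrix_", mode, ".csv")))
  }
  stats_block <- list(
    outcomes = lapply(report$outcome_tables, function(ot) {
      lapply(split(ot, ot$outcome), function(r) as.list(r[-1]))
    }),
    chi_squared = if (!is.null(report$chi_squared))
      report$chi_squared[c("statistic", "df", "p_value")],
    meta = report$meta)
  jsonlite::write_json(stats_block, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
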