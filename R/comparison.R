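#' Do two position calls differ?
#'
#' Both homoplasmic: a difference iff the bases differ, in either mode. When
#' at least one call is a point heteroplasmy the two modes diverge:
#' \describe{
#'   \item{`"isfg"`}{a difference only when the allele sets are disjoint.
#'     A heteroplasmic call sharing a base with the comparison sample's
#'     homoplasmic type (e.g. R = A/G vs G) is NOT a difference - the
#'     shared-allele rule.}
#'   \item{`"strict"`}{a difference whenever the allele sets are unequal, so
#'     any heteroplasmy mismatch counts.}
#' }
#' Heteroplasmic-vs-heteroplasmic with disjoint allele sets counts as a
#' difference in both modes: with no shared allele the ISFG rationale does
#' not apply.
#'
#' @param c1,c2 `position_call` objects at the same position.
#' @param mode `"isfg"` or `"strict"`.
#' @return Logical scalar.
#' @export
#' @examples
#' ref <- synthetic_rcrs()
#' r <- position_call(2833, c("A", "G"), 0.39)
#' g <- position_call(2833, "G")
#' position_differs(r, g, "isfg")    # FALSE: shared allele G
#' position_differs(r, g, "strict")  # TRUE
position_differs <- function(c1, c2, mode = c("isfg", "strict")) {
  mode <- match.arg(mode)
  a1 <- c1$alleles; a2 <- c2$alleles
  if (length(a1) == 1L && length(a2) == 1L) return(a1 != a2)
  if (mode == "strict") return(!identical(a1, a2))
  length(intersect(a1, a2)) == 0L
}

#' SWGDAM three-tier outcome from a difference count
#'
#' 0 differences: cannot exclude the pair as sharing a maternal lineage;
#' exactly 1: inconclusive; 2 or more: exclude.
#'
#' @param n_diff Non-negative integer (vectorized).
#' @return Character vector in `{"cannot_exclude", "inconclusive",
#'   "exclude"}`.
#' @export
classify_outcome <- function(n_diff) {
  if (any(n_diff < 0)) stop("n_diff must be non-negative")
  ifelse(n_diff == 0L, "cannot_exclude",
         ifelse(n_diff == 1L, "inconclusive", "exclude"))
}

# indel-kind variants are matched by (position, ordinal, bases); in isfg
# mode a length-heteroplasmy call against a concordant fixed-length
# insertion of the same base at the same anchor is not a difference,
# mirroring the point-heteroplasmy shared-allele logic
.indel_key <- function(v) paste(v$position, v$ordinal, v$bases, v$kind)

#' Count differing positions between two haplotypes
#'
#' Both haplotypes must be normalized against the same reference; only the
#' union of their variant positions need be examined (all other positions
#' agree by construction). Point positions are compared with
#' [position_differs()]; indel variants require token-level equality, except
#' that in `"isfg"` mode an insertion and a length-heteroplasmy of the same
#' base at the same anchor are concordant. Positions with no coverage
#' (`no_call` attribute from [call_haplotype()]) in either sample are
#' excluded from comparison entirely.
#'
#' @param h1,h2 Normalized `mito_haplotype` objects.
#' @param mode `"isfg"` or `"strict"`.
#' @param reference The shared `mito_reference`.
#' @return List with `differing` (character vector of position labels,
#'   sorted), `n_diff`, and `outcome`.
#' @export
count_differences <- function(h1, h2, mode = c("isfg", "strict"),
                              reference = synthetic_rcrs()) {
  mode <- match.arg(mode)
  if (!identical(h1$reference, h2$reference)) {
    stop("haplotypes were built against different references (",
         h1$reference, " vs ", h2$reference, ")")
  }
  skip <- union(attr(h1, "no_call"), attr(h2, "no_call"))

  point_kinds <- c("substitution", "point_heteroplasmy")
  v1 <- h1$variants; v2 <- h2$variants
  pos_union <- sort(unique(c(v1$position[v1$kind %in% point_kinds],
                             v2$position[v2$kind %in% point_kinds])))
  pos_union <- setdiff(pos_union, skip)
  differing <- character(0)
  for (p in pos_union) {
    if (position_differs(call_at(h1, p, reference),
                         call_at(h2, p, reference), mode)) {
      differing <- c(differing, as.character(p))
    }
  }

  i1 <- v1[!(v1$kind %in% point_kinds) & !(v1$position %in% skip), ,
           drop = FALSE]
  i2 <- v2[!(v2$kind %in% point_kinds) & !(v2$position %in% skip), ,
           drop = FALSE]
  if (nrow(i1) > 0L || nrow(i2) > 0L) {
    k1 <- .indel_key(i1); k2 <- .indel_key(i2)
    only1 <- i1[!(k1 %in% k2), , drop = FALSE]
    only2 <- i2[!(k2 %in% k1), , drop = FALSE]
    if (mode == "isfg") {
      # pair off insertion vs length-heteroplasmy of the same base/anchor
      soft <- function(v) paste(v$position, v$ordinal, v$bases)
      concordant <- intersect(soft(only1), soft(only2))
      only1 <- only1[!(soft(only1) %in% concordant), , drop = FALSE]
      only2 <- only2[!(soft(only2) %in% concordant), , drop = FALSE]
      # a pure length-heteroplasmy unmatched on the other side is also not
      # an isfg difference only when the other side truly lacks any indel
      # there; an unshared fixed indel always counts
    }
    lab <- function(v) ifelse(v$kind == "deletion",
                              paste0(v$position, "DEL"),
                              paste0(v$position, ".", v$ordinal,
                                     ifelse(v$kind == "length_heteroplasmy",
                                            tolower(v$bases), v$bases)))
    # discordant indels at the same anchor are one differing position
    both <- rbind(only1, only2)
    anchor <- paste(both$position, both$ordinal, both$kind == "deletion")
    differing <- c(differing, lab(both[!duplicated(anchor), , drop = FALSE]))
  }
  differing <- unique(differing)
  differing <- differing[order(as.numeric(
    sub("^([0-9]+(\\.[0-9]+)?).*$", "\\1", differing)), differing)]
  list(differing = differing, n_diff = length(differing),
       outcome = classify_outcome(length(differing)))
}

#' Compare every maternally related pair
#'
#' Runs [count_differences()] over a pair table, classifies each pair, and
#' aggregates the three-tier outcome counts plus a meioses-by-differences
#' matrix (rows: meiosis category; columns: number of differing positions).
#'
#' @param pairs Pair data frame from [enumerate_pairs()] (`$pairs`).
#' @param haplotypes Named list of normalized `mito_haplotype`, covering
#'   every id appearing in `pairs`.
#' @param mode `"isfg"` or `"strict"`.
#' @param reference The shared `mito_reference`.
#' @return List of class `comparison_table`: `results` (per-pair data
#'   frame), `outcome_counts` (named integer), `n_pairs`, `mode`, and
#'   `meioses_matrix`.
#' @export
compare_all <- function(pairs, haplotypes, mode = c("isfg", "strict"),
                        reference = synthetic_rcrs()) {
  mode <- match.arg(mode)
  missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(haplotypes))
  if (length(missing_ids) > 0L) {
    stop("no haplotype for paired individual(s): ",
         paste(missing_ids, collapse = ", "))
  }
  n <- nrow(pairs)
  n_diff <- integer(n)
  differing <- character(n)
  for (i in seq_len(n)) {
    cd <- count_differences(haplotypes[[pairs$id_a[i]]],
                            haplotypes[[pairs$id_b[i]]], mode, reference)
    n_diff[i] <- cd$n_diff
    differing[i] <- paste(cd$differing, collapse = ";")
  }
  results <- data.frame(
    id_a = pairs$id_a, id_b = pairs$id_b,
    meioses = pairs$meioses, mode = mode, n_diff = n_diff,
    differing_positions = differing,
    outcome = classify_outcome(n_diff), stringsAsFactors = FALSE)
  lev <- c("cannot_exclude", "inconclusive", "exclude")
  counts <- table(factor(results$outcome, levels = lev))
  mm <- if (n > 0) {
    table(meioses = factor(results$meioses,
                           levels = sort(unique(results$meioses))),
          n_diff = factor(results$n_diff,
                          levels = 0:max(c(results$n_diff, 0))))
  } else {
    table(integer(0), integer(0))
  }
  structure(list(results = results,
                 outcome_counts = stats::setNames(as.integer(counts), lev),
                 n_pairs = n, mode = mode,
                 meioses_matrix = unclass(mm)),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table>", x$n_pairs, "pairs, mode:", x$mode, "\n")
  print(x$outcome_counts)
  invisible(x)
}

#' Write the per-pair comparison report CSV
#'
#' Columns: pair ids, meioses, mode, n_diff, differing positions
#' (semicolon-joined tokens), outcome.
#'
#' @param comparison A `comparison_table` from [compare_all()].
#' @param path Output path.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison$results, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
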