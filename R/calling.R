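#' Heteroplasmy calling configuration
#'
#' The calling rule is purely frequency-based: at each position the two most
#' abundant bases are considered, and the position is called heteroplasmic
#' when the minor allele fraction is strictly greater than `maf_threshold`
#' (default 0.20, the conservative forensic NGS threshold), homoplasmic for
#' the major base otherwise. No base-quality model is applied. `min_depth`
#' defaults to 1: no minimum read count or coverage is required.
#'
#' @param maf_threshold Minor allele fraction threshold in [0, 0.5); a call
#'   is heteroplasmic only when MAF is strictly greater than this.
#' @param min_depth Minimum total reads for any call (below it: no-call).
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(maf_threshold = 0.20, min_depth = 1L) {
  if (maf_threshold < 0 || maf_threshold >= 0.5) {
    stop("maf_threshold must lie in [0, 0.5)")
  }
  if (min_depth < 0) stop("min_depth must be non-negative")
  structure(list(maf_threshold = maf_threshold,
                 min_depth = as.integer(min_depth)),
            class = "calling_config")
}

#' Call one position from base counts
#'
#' Ranks bases by count (ties broken by the fixed order A < C < G < T for
#' determinism), computes MAF as second-count / depth, and applies the
#' strictly-greater threshold rule. Returns `NULL` (no-call) when depth is
#' below `min_depth`, signalling missing coverage.
#'
#' @param counts Named numeric vector with entries for A, C, G, T (missing
#'   names count as zero; order irrelevant).
#' @param position Position recorded on the returned call.
#' @param config A [calling_config()].
#' @return A `position_call`, or `NULL` for a no-call.
#' @export
#' @examples
#' call_position(c(A = 296, G = 74), 100)         # homoplasmic A: MAF == 20%
#' call_position(c(A = 39, G = 61), 2833)         # heteroplasmic R, maf 0.39
call_position <- function(counts, position = NA_integer_,
                          config = calling_config()) {
  full <- c(A = 0, C = 0, G = 0, T = 0)
  if (!is.null(names(counts))) {
    nm <- toupper(names(counts))
    if (!all(nm %in% names(full))) stop("counts must be named with A/C/G/T")
    full[nm] <- full[nm] + as.numeric(counts)
  } else {
    stop("counts must be a named vector")
  }
  if (any(full < 0)) stop("counts must be non-negative")
  depth <- sum(full)
  if (depth < config$min_depth || depth == 0) return(NULL)
  ord <- order(-full, names(full))  # count desc, base order A<C<G<T for ties
  b1 <- names(full)[ord[1]]; b2 <- names(full)[ord[2]]
  maf <- full[[b2]] / depth
  if (maf > config$maf_threshold) {
    pc <- position_call(position, c(b1, b2), maf)
    attr(pc, "minor") <- b2
    pc
  } else {
    position_call(position, b1)
  }
}

#' Call a whole haplotype from a pileup
#'
#' Applies [call_position()] at every unmasked position, converts calls that
#' differ from the reference into variants, and normalizes the result.
#' Positions with no-call (depth below `min_depth`) are excluded from the
#' haplotype and returned in the `no_call` attribute so comparisons can skip
#' them.
#'
#' @param pileup Data frame with columns `position`, `A`, `C`, `G`, `T`
#'   covering positions 1..L (as written by [write_pileup()]).
#' @param reference A `mito_reference`.
#' @param config A [calling_config()].
#' @param sample_id Sample label.
#' @return A normalized `mito_haplotype` with attribute `no_call` (integer
#'   vector of uncovered positions).
#' @export
call_haplotype <- function(pileup, reference, config = calling_config(),
                           sample_id = "sample") {
  req <- c("position", "A", "C", "G", "T")
  if (!all(req %in% names(pileup))) {
    stop("pileup must have columns position, A, C, G, T")
  }
  if (!setequal(pileup$position, seq_len(reference$length))) {
    stop("pileup positions do not cover 1..", reference$length)
  }
  pileup <- pileup[order(pileup$position), , drop = FALSE]
  cnt <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(cnt)
  masked <- is_masked(pileup$position, reference)
  no_call <- pileup$position[!masked & depth < max(config$min_depth, 1L)]

  rows <- list()
  consider <- which(!masked & depth >= max(config$min_depth, 1L))
  for (i in consider) {
    pos <- pileup$position[i]
    pc <- call_position(cnt[i, ], pos, config)
    rb <- reference$bases[pos]
    if (length(pc$alleles) == 1L) {
      if (pc$alleles != rb) {
        rows[[length(rows) + 1L]] <- .variant_row(pos, "substitution",
                                                  pc$alleles)
      }
    } else if (!identical(pc$alleles, rb)) {
      rows[[length(rows) + 1L]] <- .variant_row(
        pos, "point_heteroplasmy", paste(pc$alleles, collapse = ""),
        maf = pc$maf, minor = attr(pc, "minor"))
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else .empty_variants()
  h <- normalize_haplotype(mito_haplotype(sample_id, variants, reference),
                           reference)
  attr(h, "no_call") <- as.integer(no_call)
  h
}

#' Read / write a pileup TSV
#'
#' The pileup dialect is a tab-separated table with a header and columns
#' `position`, `A`, `C`, `G`, `T` of non-negative integer read counts.
#'
#' @param path File path.
#' @return `read_pileup`: the pileup data frame.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("position", "A", "C", "G", "T")
  if (!all(req %in% names(df))) {
    stop("pileup TSV must have header columns position, A, C, G, T")
  }
  df[, req]
}

#' @rdname read_pileup
#' @param pileup Pileup data frame.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("position", "A", "C", "G", "T")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
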