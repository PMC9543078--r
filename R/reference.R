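#' Construct a circular mitochondrial reference
#'
#' A reference is the coordinate system every haplotype is expressed against:
#' a 1-based, circular sequence of A/C/G/T plus a set of masked intervals that
#' are excluded from variant reporting and comparison. For a 16,569-base
#' reference the defaults mask the three hypervariable-region C-stretches
#' (HVI 16183-16194, HVII 302-310, HVIII 568-573), where homopolymer length
#' variation is not interpreted.
#'
#' @param sequence Character scalar or character vector of single bases
#'   (A/C/G/T only).
#' @param name Text label for the reference.
#' @param masked_ranges Two-column matrix (start, end) of inclusive 1-based
#'   intervals, or `NULL` for the defaults (the three C-stretch ranges when
#'   the length is 16,569, otherwise no masking).
#' @return An object of class `mito_reference` with elements `name`, `bases`
#'   (character vector of length L), `length`, and `masked_ranges`.
#' @export
mito_reference <- function(sequence, name = "reference", masked_ranges = NULL) {
  bases <- if (length(sequence) == 1L && nchar(sequence) > 1L) {
    strsplit(toupper(sequence), "")[[1]]
  } else {
    toupper(as.character(sequence))
  }
  if (length(bases) < 1L) {
    stop("reference must contain at least one base")
  }
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    bad <- unique(setdiff(bases, c("A", "C", "G", "T")))
    stop("reference contains non-ACGT bases: ", paste(bad, collapse = ", "))
  }
  L <- length(bases)
  if (is.null(masked_ranges)) {
    masked_ranges <- if (L == 16569L) {
      cbind(start = c(16183L, 302L, 568L), end = c(16194L, 310L, 573L))
    } else {
      cbind(start = integer(0), end = integer(0))
    }
  } else {
    masked_ranges <- matrix(as.integer(masked_ranges), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
    if (nrow(masked_ranges) > 0 &&
        (any(masked_ranges < 1L) || any(masked_ranges > L) ||
         any(masked_ranges[, 1] > masked_ranges[, 2]))) {
      stop("masked_ranges must be valid inclusive intervals within [1, L]")
    }
  }
  structure(
    list(name = name, bases = bases, length = L, masked_ranges = masked_ranges),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference>", x$name, "-", x$length, "bp,",
      nrow(x$masked_ranges), "masked range(s)\n")
  invisible(x)
}

#' Is a position inside a masked range?
#'
#' @param position Integer vector of 1-based positions.
#' @param reference A `mito_reference`.
#' @return Logical vector.
#' @export
is_masked <- function(position, reference) {
  mr <- reference$masked_ranges
  if (nrow(mr) == 0L) return(rep(FALSE, length(position)))
  vapply(position, function(p) any(p >= mr[, 1] & p <= mr[, 2]), logical(1))
}

#' Reference base at a position
#'
#' @param position Integer vector of 1-based positions.
#' @param reference A `mito_reference`.
#' @return Character vector of bases.
#' @export
ref_base <- function(position, reference) {
  if (any(position < 1L) || any(position > reference$length)) {
    stop("position out of range [1, ", reference$length, "]")
  }
  reference$bases[position]
}

#' Bundled synthetic 16,569-base reference
#'
#' A deterministic synthetic stand-in for a real human mitochondrial
#' reference, for use when positions only matter as labels (simulation,
#' testing, worked examples). It is NOT the rCRS: the bulk of the sequence is
#' pseudo-random. It does match the rCRS at the handful of positions used in
#' published variant names handled by the package examples (A at 2833, 8470,
#' 8817, 16247 and 16280; T at 146 and 9012; C at 16320 and 16344; and the
#' common control-region sites 73, 263, 315), so those variant strings
#' parse with their reference-base check intact, and it carries cytosine runs
#' across the three masked C-stretch ranges so that 3'-shift normalization
#' and length-variation masking behave as on real data. Users with the real
#' rCRS should load it with [read_reference_fasta()].
#'
#' @return A `mito_reference` of length 16,569 with the default C-stretch
#'   masked ranges.
#' @export
synthetic_rcrs <- function() {
  L <- 16569L
  # fixed linear congruential stream so the sequence is identical on every
  # platform and never touches R's global RNG
  n <- L
  state <- 20220719
  vals <- integer(n)
  a <- 1103515245; cmod <- 2^31
  for (i in seq_len(n)) {
    state <- (a * state + 12345) %% cmod
    vals[i] <- state %% 4L
  }
  bases <- c("A", "C", "G", "T")[vals + 1L]
  # cytosine tracts across the masked hypervariable C-stretch ranges, with a
  # T interrupting the HVI tract as in the real control region
  bases[16183:16194] <- "C"; bases[16189] <- "T"
  bases[302:309] <- "C"; bases[310] <- "T"
  bases[568:573] <- "C"
  # bases at positions named in published whole-mtGenome variant strings
  planted <- c(
    "73" = "A", "146" = "T", "152" = "T", "195" = "T", "263" = "A",
    "315" = "C", "316" = "G",
    "2833" = "A", "8470" = "A", "8817" = "A", "9012" = "T",
    "16223" = "C", "16247" = "A", "16280" = "A", "16320" = "C",
    "16344" = "C"
  )
  bases[as.integer(names(planted))] <- unname(planted)
  mito_reference(bases, name = "synthetic-rCRS-like")
}

#' Read a single-record reference FASTA
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param masked_ranges Optional masked ranges (see [mito_reference()]).
#' @return A `mito_reference`.
#' @export
read_reference_fasta <- function(path, masked_ranges = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop("reference FASTA must contain exactly one record, found ", length(ss))
  }
  mito_reference(as.character(ss[[1]]), name = names(ss)[1],
                 masked_ranges = masked_ranges)
}

#' Write a reference (or any named sequences) to FASTA
#'
#' @param sequences Named character vector of sequences, or a `mito_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "mito_reference")) {
    seqs <- paste(sequences$bases, collapse = "")
    names(seqs) <- sequences$name
    sequences <- seqs
  }
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
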