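# Two-base IUPAC ambiguity codes; the only ambiguity codes used for point
# heteroplasmy (a position carrying exactly two bases within one individual).
.IUPAC2 <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Expand an IUPAC code to its allele set
#'
#' Single bases expand to themselves; the six two-base ambiguity codes
#' (R, Y, S, W, K, M) expand to their base pairs. Three- and four-base codes
#' (B, D, H, V, N) are rejected: a point heteroplasmy carries at most two
#' alleles in this interpretation framework.
#'
#' @param code Single character.
#' @return Character vector of bases, sorted, of length 1 or 2.
#' @export
#' @examples
#' iupac_expand("R")  # A G
#' iupac_encode(c("C", "T"))  # "Y"
iupac_expand <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("code must be a single character")
  }
  code <- toupper(code)
  if (code %in% c("A", "C", "G", "T")) return(code)
  if (code %in% names(.IUPAC2)) return(strsplit(.IUPAC2[[code]], "")[[1]])
  stop("unsupported IUPAC code '", code,
       "' (three/four-base ambiguity codes are not supported)")
}

#' @rdname iupac_expand
#' @param alleles Character vector of 1 or 2 distinct bases.
#' @export
iupac_encode <- function(alleles) {
  alleles <- sort(unique(toupper(alleles)))
  if (!all(alleles %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A/C/G/T")
  }
  if (length(alleles) == 1L) return(alleles)
  if (length(alleles) == 2L) {
    key <- paste(alleles, collapse = "")
    return(names(.IUPAC2)[match(key, .IUPAC2)])
  }
  stop("allele sets of size ", length(alleles), " are not supported")
}

#' Per-position base call
#'
#' A homoplasmic call carries one allele; a point-heteroplasmic call carries
#' two alleles plus the minor allele fraction (MAF), the read fraction of the
#' less frequent base, in (0, 0.5]. The MAF may be `NA` when the call was
#' derived from a variant string rather than read counts.
#'
#' @param position 1-based reference coordinate.
#' @param alleles Character vector of 1 or 2 distinct bases.
#' @param maf Minor allele fraction, required semantics only for two-allele
#'   calls.
#' @return A list of class `position_call` with `position`, `alleles`,
#'   `maf`, `iupac`.
#' @export
position_call <- function(position, alleles, maf = NA_real_) {
  alleles <- sort(unique(toupper(alleles)))
  iupac <- iupac_encode(alleles)  # validates size and bases
  if (length(alleles) == 1L) {
    maf <- NA_real_
  } else if (!is.na(maf) && (maf <= 0 || maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  structure(list(position = as.numeric(position), alleles = alleles,
                 maf = maf, iupac = iupac),
            class = "position_call")
}

#' @export
print.position_call <- function(x, ...) {
  cat("<position_call>", x$position, x$iupac,
      if (!is.na(x$maf)) sprintf("(maf %.2f)", x$maf) else "", "\n")
  invisible(x)
}

.empty_variants <- function() {
  data.frame(position = integer(0), ordinal = integer(0),
             kind = character(0), alleles = character(0),
             maf = numeric(0), minor = character(0), bases = character(0),
             stringsAsFactors = FALSE)
}

# `minor` records which allele of a point heteroplasmy is the less frequent
# one (its frequency is `maf`); NA when unknown or not applicable
.variant_row <- function(position, kind, alleles = NA_character_,
                         maf = NA_real_, minor = NA_character_,
                         bases = NA_character_, ordinal = 0L) {
  data.frame(position = as.integer(position), ordinal = as.integer(ordinal),
             kind = kind, alleles = alleles, maf = maf, minor = minor,
             bases = bases, stringsAsFactors = FALSE)
}

#' Construct a mitochondrial haplotype
#'
#' A haplotype is the set of differences between one sample and the
#' reference; an empty variant table means identity with the reference over
#' unmasked positions. Point variants (substitutions and point
#' heteroplasmies) are keyed by position: at most one per position.
#'
#' @param sample_id Sample label.
#' @param variants Variant table as built by [parse_haplotype()]; internal
#'   columns `position`, `ordinal`, `kind`, `alleles`, `maf`, `bases`.
#' @param reference A `mito_reference` (its name is recorded).
#' @return Object of class `mito_haplotype`.
#' @export
mito_haplotype <- function(sample_id, variants = NULL, reference) {
  if (is.null(variants)) variants <- .empty_variants()
  point <- variants$kind %in% c("substitution", "point_heteroplasmy")
  if (anyDuplicated(variants$position[point])) {
    stop("duplicate point variant position in haplotype '", sample_id, "'")
  }
  structure(list(sample_id = sample_id, variants = variants,
                 reference = reference$name),
            class = "mito_haplotype")
}

#' @export
print.mito_haplotype <- function(x, ...) {
  cat("<mito_haplotype>", x$sample_id, "-", nrow(x$variants),
      "variant(s) vs", x$reference, "\n")
  if (nrow(x$variants) > 0) cat(" ", encode_haplotype(x), "\n")
  invisible(x)
}

#' Parse a forensic variant string into a haplotype
#'
#' Tokens are whitespace-separated, in the EMPOP-style dialect:
#' \describe{
#'   \item{`A16247G`}{substitution: reference base, position, new base}
#'   \item{`T146Y`}{point heteroplasmy: reference base, position, two-base
#'     IUPAC code giving the allele pair}
#'   \item{`315.1C`}{insertion of one base between positions 315 and 316
#'     (ordinal .1, .2, ... for consecutive inserted bases)}
#'   \item{`249DEL`}{deletion of the reference base at the position}
#'   \item{`315.1c`}{lowercase inserted base: length heteroplasmy, i.e. an
#'     insertion of within-individual variable copy number at that anchor}
#' }
#' The leading reference base of point tokens is checked against the
#' reference. Parsing does not normalize; see [normalize_haplotype()].
#'
#' @param text Variant string ("" for a reference-identical haplotype).
#' @param reference A `mito_reference`.
#' @param sample_id Sample label.
#' @return A `mito_haplotype`.
#' @export
#' @examples
#' ref <- synthetic_rcrs()
#' parse_haplotype("A16247G", ref, "S1")
#' parse_haplotype("T146Y A2833R", ref, "S2")
parse_haplotype <- function(text, reference, sample_id = "sample") {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    return(mito_haplotype(sample_id, NULL, reference))
  }
  rows <- lapply(tokens, .parse_token, reference = reference)
  variants <- do.call(rbind, rows)
  key <- paste(variants$position, variants$ordinal, variants$kind)
  if (anyDuplicated(key)) {
    stop("duplicate variant token for sample '", sample_id, "'")
  }
  mito_haplotype(sample_id, variants, reference)
}

.parse_token <- function(token, reference) {
  L <- reference$length
  m <- regmatches(token, regexec("^([ACGT])([0-9]+)([A-Z])$", token))[[1]]
  if (length(m) == 4L) {
    pos <- as.integer(m[3]); refb <- m[2]; alt <- m[4]
    if (pos < 1L || pos > L) stop("position out of range in token '", token, "'")
    if (ref_base(pos, reference) != refb) {
      stop("reference-base mismatch in token '", token, "': reference has ",
           ref_base(pos, reference), " at ", pos)
    }
    alleles <- iupac_expand(alt)
    if (length(alleles) == 1L) {
      if (alleles == refb) stop("substitution equal to reference in '", token, "'")
      return(.variant_row(pos, "substitution", alleles))
    }
    if (identical(alleles, refb)) stop("heteroplasmy equal to reference in '", token, "'")
    nonref <- setdiff(alleles, refb)
    minor <- if (length(nonref) == 1L) nonref else alleles[2]
    return(.variant_row(pos, "point_heteroplasmy",
                        paste(alleles, collapse = ""), minor = minor))
  }
  m <- regmatches(token, regexec("^([0-9]+)\\.([0-9]+)([ACGTacgt])$", token))[[1]]
  if (length(m) == 4L) {
    pos <- as.integer(m[2]); ordn <- as.integer(m[3]); base <- m[4]
    if (pos < 1L || pos > L) stop("position out of range in token '", token, "'")
    if (ordn < 1L) stop("insertion ordinal must be >= 1 in '", token, "'")
    kind <- if (base %in% c("a", "c", "g", "t")) "length_heteroplasmy" else "insertion"
    return(.variant_row(pos, kind, bases = toupper(base), ordinal = ordn))
  }
  m <- regmatches(token, regexec("^([0-9]+)(DEL|del)$", token))[[1]]
  if (length(m) == 3L) {
    pos <- as.integer(m[2])
    if (pos < 1L || pos > L) stop("position out of range in token '", token, "'")
    return(.variant_row(pos, "deletion", bases = ref_base(pos, reference)))
  }
  stop("malformed variant token '", token, "'")
}

#' Encode a haplotype back to its canonical variant string
#'
#' Inverse of [parse_haplotype()]: tokens sorted by position (and insertion
#' ordinal), heteroplasmies rendered with their IUPAC code, length
#' heteroplasmy with a lowercase base.
#'
#' @param h A `mito_haplotype`.
#' @param reference A `mito_reference` supplying the leading reference base
#'   of point tokens; defaults to the bundled synthetic reference.
#' @return A single string ("" when the haplotype is reference-identical).
#' @export
encode_haplotype <- function(h, reference = synthetic_rcrs()) {
  v <- h$variants
  if (nrow(v) == 0L) return("")
  v <- v[order(v$position, v$ordinal), , drop = FALSE]
  tokens <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    tokens[i] <- switch(v$kind[i],
      substitution = paste0(ref_base(v$position[i], reference), v$position[i],
                            v$alleles[i]),
      point_heteroplasmy = paste0(ref_base(v$position[i], reference),
                                  v$position[i],
                                  iupac_encode(strsplit(v$alleles[i], "")[[1]])),
      insertion = paste0(v$position[i], ".", v$ordinal[i], v$bases[i]),
      length_heteroplasmy = paste0(v$position[i], ".", v$ordinal[i],
                                   tolower(v$bases[i])),
      deletion = paste0(v$position[i], "DEL"),
      stop("unknown variant kind ", v$kind[i])
    )
  }
  paste(tokens, collapse = " ")
}

# 3'-most equivalent placement of a single-base deletion: the deleted base
# can slide right while the next reference base equals it (homopolymer run).
.shift_deletion_3p <- function(pos, reference) {
  b <- ref_base(pos, reference)
  while (pos < reference$length && reference$bases[pos + 1L] == b) {
    pos <- pos + 1L
  }
  pos
}

# 3'-most anchor of an insertion of base b after position pos: inserting
# after pos is equivalent to inserting after pos+1 whenever ref[pos+1] == b.
.shift_insertion_3p <- function(pos, b, reference) {
  while (pos < reference$length && reference$bases[pos + 1L] == b) {
    pos <- pos + 1L
  }
  pos
}

#' Normalize a haplotype to forensic nomenclature conventions
#'
#' Applies, in order: (1) every insertion, length-heteroplasmy and deletion
#' is re-anchored at its 3'-most equivalent placement on the light strand
#' (the highest position producing the same edited sequence); (2) variants
#' whose position (point kinds) or anchor (indel kinds) falls inside a
#' masked range are dropped, so C-stretch length variation is never
#' reported; (3) variants are sorted by position and insertion ordinals are
#' renumbered per anchor. The operation is idempotent.
#'
#' @param h A `mito_haplotype`.
#' @param reference The `mito_reference` the haplotype was parsed against.
#' @return A normalized `mito_haplotype`.
#' @export
normalize_haplotype <- function(h, reference) {
  v <- h$variants
  if (nrow(v) > 0L) {
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] == "deletion") {
        v$position[i] <- .shift_deletion_3p(v$position[i], reference)
      } else if (v$kind[i] %in% c("insertion", "length_heteroplasmy")) {
        v$position[i] <- .shift_insertion_3p(v$position[i], v$bases[i],
                                             reference)
      }
    }
    v <- v[!is_masked(v$position, reference), , drop = FALSE]
    v <- v[order(v$position, v$ordinal), , drop = FALSE]
    # renumber insertion ordinals per anchor, preserving order
    ins <- v$kind %in% c("insertion", "length_heteroplasmy")
    if (any(ins)) {
      v$ordinal[ins] <- stats::ave(seq_len(sum(ins)), v$position[ins],
                                   FUN = seq_along)
    }
    rownames(v) <- NULL
  }
  mito_haplotype(h$sample_id, v, reference)
}

#' Base call of a haplotype at one position
#'
#' Returns the haplotype's point variant call at the position if present,
#' otherwise the homoplasmic reference base. Indel variants do not alter
#' point calls.
#'
#' @param h A `mito_haplotype`.
#' @param position Unmasked 1-based position.
#' @param reference A `mito_reference`.
#' @return A `position_call`.
#' @export
call_at <- function(h, position, reference) {
  if (position < 1L || position > reference$length) {
    stop("position out of range")
  }
  if (is_masked(position, reference)) {
    stop("position ", position, " is inside a masked range")
  }
  v <- h$variants
  hit <- which(v$position == position &
               v$kind %in% c("substitution", "point_heteroplasmy"))
  if (length(hit) == 1L) {
    position_call(position, strsplit(v$alleles[hit], "")[[1]], v$maf[hit])
  } else {
    position_call(position, ref_base(position, reference))
  }
}

#' Read a haplotype table file
#'
#' One line per sample: `sample_id<TAB>variant tokens` (tokens themselves
#' whitespace-separated; an id alone means reference-identical).
#'
#' @param path Input path.
#' @param reference A `mito_reference`.
#' @return Named list of `mito_haplotype`.
#' @export
read_haplotypes <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    id <- trimws(parts[1])
    tokens <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else ""
    if (id %in% names(out)) stop("duplicate sample id '", id, "'")
    out[[id]] <- parse_haplotype(tokens, reference, id)
  }
  out
}

#' Write haplotypes to a haplotype table file
#'
#' @param haplotypes Named list of `mito_haplotype`.
#' @param path Output path.
#' @param reference A `mito_reference` for token encoding.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haplotypes, path, reference = synthetic_rcrs()) {
  lines <- vapply(haplotypes, function(h) {
    paste(h$sample_id, encode_haplotype(h, reference), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
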