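#' Load and validate a maternal pedigree
#'
#' A pedigree is a table of individuals with at most one mother each; the
#' maternal links must form a forest (no cycles, every `mother_id` resolving
#' to a row). Founders are rows with an empty/`NA` mother. Individuals
#' listed as someone's mother must not be annotated male.
#'
#' @param table Data frame with columns `id`, `mother_id`, `sex` (F/M/U),
#'   `family`, `sampled` (0/1 or logical).
#' @return Object of class `pedigree`: the validated table (with `sampled`
#'   as logical and `mother_id` as `NA` for founders) plus a `clan` column
#'   giving each individual's founding-mother id.
#' @export
load_pedigree <- function(table) {
  req <- c("id", "mother_id", "sex", "family", "sampled")
  if (!all(req %in% names(table))) {
    stop("pedigree table must have columns ", paste(req, collapse = ", "))
  }
  ped <- as.data.frame(table, stringsAsFactors = FALSE)[, req]
  ped$id <- as.character(ped$id)
  ped$mother_id <- as.character(ped$mother_id)
  ped$mother_id[is.na(ped$mother_id) | !nzchar(trimws(ped$mother_id))] <- NA
  ped$sex <- toupper(as.character(ped$sex))
  ped$sampled <- as.logical(as.integer(as.logical(ped$sampled)))
  if (anyDuplicated(ped$id)) stop("duplicate individual id in pedigree")
  known <- ped$mother_id %in% ped$id
  if (any(!is.na(ped$mother_id) & !known)) {
    bad <- ped$mother_id[!is.na(ped$mother_id) & !known]
    stop("dangling mother_id: ", paste(unique(bad), collapse = ", "))
  }
  mother_sex <- ped$sex[match(ped$mother_id, ped$id)]
  if (any(!is.na(mother_sex) & mother_sex == "M")) {
    stop("individual annotated male is listed as a mother")
  }
  # cycle detection + clan assignment by walking each maternal line
  midx <- match(ped$mother_id, ped$id)
  n <- nrow(ped)
  clan <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(midx[j])) {
      j <- midx[j]; steps <- steps + 1L
      if (steps > n) stop("maternal cycle detected involving '", ped$id[i], "'")
    }
    clan[i] <- ped$id[j]
  }
  ped$clan <- clan
  structure(ped, class = c("pedigree", "data.frame"))
}

#' Read the pedigree TSV dialect
#'
#' Tab-separated with header `id, mother_id, sex, family, sampled`; empty
#' `mother_id` marks a founder, `sampled` is 0/1.
#'
#' @param path Input path.
#' @return A `pedigree`.
#' @export
read_pedigree_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""))
  df$sampled <- as.integer(df$sampled)
  load_pedigree(df)
}

#' @rdname read_pedigree_tsv
#' @param pedigree A `pedigree`.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  out <- as.data.frame(pedigree)[, c("id", "mother_id", "sex", "family",
                                     "sampled")]
  out$sampled <- as.integer(out$sampled)
  out$mother_id[is.na(out$mother_id)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert 6-column PED-format rows to the pedigree table
#'
#' Uses the family, individual, maternal and sex columns of the standard
#' PED layout (`fid iid pid mid sex phenotype`); the paternal column is
#' ignored, sex code 2 is female, and a maternal id of "0" marks a founder.
#' Every individual is marked sampled.
#'
#' @param ped_rows Data frame or matrix with at least 5 PED columns.
#' @return A `pedigree`.
#' @export
pedigree_from_ped <- function(ped_rows) {
  ped_rows <- as.data.frame(ped_rows, stringsAsFactors = FALSE)
  if (ncol(ped_rows) < 5L) stop("PED input needs at least 5 columns")
  mid <- as.character(ped_rows[[4]])
  mid[mid == "0"] <- NA
  sex <- c("U", "M", "F")[1 + suppressWarnings(as.integer(ped_rows[[5]])) %%
                            3]
  sex[is.na(sex)] <- "U"
  load_pedigree(data.frame(
    id = as.character(ped_rows[[2]]), mother_id = mid, sex = sex,
    family = as.character(ped_rows[[1]]), sampled = 1L,
    stringsAsFactors = FALSE))
}

#' Partition a pedigree into maternal clans
#'
#' A maternal clan is the set of all individuals tracing an unbroken
#' maternal line to the same founding mother; clan count equals founder
#' count.
#'
#' @param pedigree A `pedigree`.
#' @return Named list of character vectors of ids, named by founder id.
#' @export
maternal_clans <- function(pedigree) {
  split(pedigree$id, pedigree$clan)
}

# row indices of `i` and its strictly-maternal ancestor chain (self first)
.ancestor_chain <- function(midx, i) {
  out <- i
  while (!is.na(midx[i])) {
    i <- midx[i]
    out <- c(out, i)
  }
  out
}

# meiosis count from precomputed mother-index vector and two row indices
.meioses_idx <- function(midx, ia, ib) {
  ca <- .ancestor_chain(midx, ia)
  cb <- .ancestor_chain(midx, ib)
  hit <- match(ca, cb)
  j <- which(!is.na(hit))[1]
  if (is.na(j)) return(NA_integer_)
  (j - 1L) + (hit[j] - 1L)
}

# ids of the strictly-maternal ancestor chain of `id`, starting at the
# mother; empty for a founder
.maternal_ancestors <- function(pedigree, id) {
  i <- match(id, pedigree$id)
  if (is.na(i)) stop("unknown individual '", id, "'")
  midx <- match(pedigree$mother_id, pedigree$id)
  pedigree$id[.ancestor_chain(midx, i)[-1]]
}

#' Meiosis count between two maternal relatives
#'
#' The number of mother-to-child transmissions on the maternal path joining
#' `a` and `b` through their most recent common maternal ancestor (MRCMA):
#' mother-child pairs are 1 meiosis apart, full siblings 2.
#'
#' @param pedigree A `pedigree`.
#' @param a,b Distinct individual ids in the same maternal clan.
#' @return Positive integer.
#' @export
meioses_between <- function(pedigree, a, b) {
  if (identical(a, b)) stop("a and b must differ")
  ia <- match(a, pedigree$id); ib <- match(b, pedigree$id)
  if (is.na(ia)) stop("unknown individual '", a, "'")
  if (is.na(ib)) stop("unknown individual '", b, "'")
  midx <- match(pedigree$mother_id, pedigree$id)
  m <- .meioses_idx(midx, ia, ib)
  if (is.na(m)) {
    stop("'", a, "' and '", b, "' share no common maternal ancestor")
  }
  m
}

#' Enumerate all sampled maternally related pairs
#'
#' All unordered pairs of sampled individuals within each maternal clan,
#' each with its meiosis count, plus the histogram of pairs per meiosis
#' category. Unsampled individuals route maternal paths but never appear in
#' pairs; total pair count is the sum of C(k, 2) over sampled clan sizes k.
#'
#' @param pedigree A `pedigree`.
#' @return List with `pairs` (data frame `id_a`, `id_b`, `clan`, `meioses`)
#'   and `histogram` (data frame `meioses`, `count`).
#' @export
enumerate_pairs <- function(pedigree) {
  sampled <- pedigree[pedigree$sampled, , drop = FALSE]
  clans <- split(sampled$id, sampled$clan)
  midx <- match(pedigree$mother_id, pedigree$id)
  res <- list()
  for (cl in names(clans)) {
    ids <- sort(clans[[cl]])
    k <- length(ids)
    if (k < 2L) next
    idx <- utils::combn(k, 2)
    rowidx <- match(ids, pedigree$id)
    res[[cl]] <- data.frame(
      id_a = ids[idx[1, ]], id_b = ids[idx[2, ]], clan = cl,
      meioses = vapply(seq_len(ncol(idx)), function(j) {
        .meioses_idx(midx, rowidx[idx[1, j]], rowidx[idx[2, j]])
      }, integer(1)),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(res)) do.call(rbind, res) else {
    data.frame(id_a = character(0), id_b = character(0),
               clan = character(0), meioses = integer(0))
  }
  rownames(pairs) <- NULL
  tab <- table(factor(pairs$meioses,
                      levels = seq_len(max(c(pairs$meioses, 1L)))))
  list(pairs = pairs,
       histogram = data.frame(meioses = as.integer(names(tab)),
                              count = as.integer(tab)))
}
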