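#' Deterministic two-family demonstration fixture
#'
#' Builds, with no randomness, a pair of maternal clans mirroring the
#' published Family-8 / Family-12 case structure for whole-mtGenome
#' kinship interpretation:
#' \itemize{
#'   \item a 7-member sampled clan whose one childless member carries the
#'     homoplasmic substitution A16247G (HVI);
#'   \item a 59-member sampled clan with one childless member carrying the
#'     homoplasmic substitution A8817G (coding region) and two members
#'     carrying the point heteroplasmy A2833R, with minor alleles A at MAF
#'     0.39 and G at MAF 0.27 respectively;
#' }
#' all other sampled members reference-identical. Under the ISFG
#' shared-allele rule this yields exactly 64 inconclusive pairs (6 + 58)
#' and no exclusions; the strict rule adds the heteroplasmy carriers'
#' pairs as differences.
#'
#' @param reference A `mito_reference` (must carry A at 16247, 8817 and
#'   2833, as the bundled [synthetic_rcrs()] does).
#' @return List `pedigree` (a `pedigree`), `haplotypes` (named list of
#'   normalized `mito_haplotype` for all sampled members).
#' @export
build_two_family_fixture <- function(reference = synthetic_rcrs()) {
  rows <- list()
  add <- function(id, mother, sex, fam, sampled) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, mother_id = mother, sex = sex, family = fam,
      sampled = sampled, stringsAsFactors = FALSE)
  }
  # clan 1: founder (unsampled) -> 2 sampled daughters -> 5 grandchildren
  add("F08-0", NA, "F", "F08", 0L)
  add("F08-B", "F08-0", "F", "F08", 1L)
  add("F08-C", "F08-0", "F", "F08", 1L)
  add("F08-D", "F08-B", "F", "F08", 1L)
  add("F08-E", "F08-B", "M", "F08", 1L)   # carries A16247G, childless
  add("F08-F", "F08-B", "M", "F08", 1L)
  add("F08-G", "F08-C", "F", "F08", 1L)
  add("F08-H", "F08-C", "M", "F08", 1L)
  # clan 2: founder (unsampled) -> 9 sampled daughters -> 50 grandchildren
  add("F12-0", NA, "F", "F12", 0L)
  grandkids <- c(6L, 6L, 6L, 6L, 6L, 5L, 5L, 5L, 5L)
  for (d in seq_along(grandkids)) {
    did <- sprintf("F12-D%d", d)
    add(did, "F12-0", "F", "F12", 1L)
    for (k in seq_len(grandkids[d])) {
      sex <- if (k %% 2 == 0) "M" else "F"
      add(sprintf("F12-D%d-%d", d, k), did, sex, "F12", 1L)
    }
  }
  ped <- load_pedigree(do.call(rbind, rows))

  sampled_ids <- ped$id[ped$sampled]
  haplotypes <- stats::setNames(
    lapply(sampled_ids, function(id) mito_haplotype(id, NULL, reference)),
    sampled_ids)
  haplotypes[["F08-E"]] <- parse_haplotype("A16247G", reference, "F08-E")
  haplotypes[["F12-D9-5"]] <- parse_haplotype("A8817G", reference, "F12-D9-5")
  het1 <- parse_haplotype("A2833R", reference, "F12-D1-1")
  het1$variants$maf <- 0.39
  het1$variants$minor <- "A"
  haplotypes[["F12-D1-1"]] <- het1
  het2 <- parse_haplotype("A2833R", reference, "F12-D2-1")
  het2$variants$maf <- 0.27
  het2$variants$minor <- "G"
  haplotypes[["F12-D2-1"]] <- het2
  haplotypes <- lapply(haplotypes, normalize_haplotype, reference = reference)
  list(pedigree = ped, haplotypes = haplotypes)
}
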