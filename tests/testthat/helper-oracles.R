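# Shared fixtures and independent brute-force oracles.

# small reference with known homopolymer runs:
# pos: 123456789012345678901234
#      ACCCCGTTAGGCAAAATCGATCGA   (length 24, no masking)
tiny_ref <- function(masked = NULL) {
  mito_reference("ACCCCGTTAGGCAAAATCGATCGA", name = "tiny",
                 masked_ranges = masked)
}

# random homopolymer-rich reference of length <= 200
random_runny_ref <- function(len = 120) {
  runs <- character(0)
  total <- 0
  while (total < len) {
    b <- sample(c("A", "C", "G", "T"), 1)
    k <- sample(1:6, 1, prob = c(3, 2, 1, 1, 1, 1))
    runs <- c(runs, rep(b, k))
    total <- total + k
  }
  mito_reference(runs[1:len], name = "runny", masked_ranges = NULL)
}

# brute-force 3'-most placement of a single-base deletion: enumerate every
# deletion position producing the same edited string, take the maximum
oracle_del_3p <- function(ref, pos) {
  target <- paste(ref$bases[-pos], collapse = "")
  hits <- which(vapply(seq_len(ref$length), function(p) {
    paste(ref$bases[-p], collapse = "") == target
  }, logical(1)))
  max(hits)
}

# brute-force 3'-most anchor of inserting base b after position pos
oracle_ins_3p <- function(ref, pos, b) {
  target <- paste(append(ref$bases, b, after = pos), collapse = "")
  hits <- which(vapply(seq_len(ref$length), function(p) {
    paste(append(ref$bases, b, after = p), collapse = "") == target
  }, logical(1)))
  max(hits)
}

# random haplotype of point variants only (<= max_var), unmasked positions
random_point_haplotype <- function(ref, id, max_var = 10) {
  unmasked <- setdiff(seq_len(ref$length),
                      which(is_masked(seq_len(ref$length), ref)))
  k <- sample(0:max_var, 1)
  pos <- sort(sample(unmasked, min(k, length(unmasked))))
  tokens <- vapply(pos, function(p) {
    rb <- ref_base(p, ref)
    if (runif(1) < 0.5) {
      paste0(rb, p, sample(setdiff(c("A", "C", "G", "T"), rb), 1))
    } else {
      alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      paste0(rb, p, iupac_encode(c(rb, alt)))
    }
  }, character(1))
  parse_haplotype(paste(tokens, collapse = " "), ref, id)
}

# position-by-position full-reference scan counting differing positions
oracle_count_diffs <- function(h1, h2, mode, ref) {
  n <- 0L
  for (p in seq_len(ref$length)) {
    if (is_masked(p, ref)) next
    c1 <- call_at(h1, p, ref)
    c2 <- call_at(h2, p, ref)
    a1 <- c1$alleles; a2 <- c2$alleles
    differs <- if (length(a1) == 1 && length(a2) == 1) {
      a1 != a2
    } else if (mode == "strict") {
      !identical(a1, a2)
    } else {
      length(intersect(a1, a2)) == 0
    }
    if (differs) n <- n + 1L
  }
  n
}

# random maternal pedigree of <= n_max individuals; every individual is
# sampled, mothers drawn from existing females (or founder)
random_pedigree <- function(n_max = 60) {
  n <- sample(5:n_max, 1)
  id <- paste0("I", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4))
  mother <- rep(NA_character_, n)
  for (i in 2:n) {
    females <- which(sex[1:(i - 1)] == "F")
    if (length(females) > 0 && runif(1) < 0.85) {
      mother[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  load_pedigree(data.frame(id = id, mother_id = mother, sex = sex,
                           family = "R", sampled = 1L,
                           stringsAsFactors = FALSE))
}

# independent meiosis oracle: undirected graph distance over mother-child
# edges (the unique path in a maternal forest passes through the MRCA)
oracle_meioses <- function(ped, a, b) {
  edges <- ped[!is.na(ped$mother_id), c("id", "mother_id")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = ped$id)
  d <- igraph::distances(g, v = a, to = b)[1, 1]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}
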