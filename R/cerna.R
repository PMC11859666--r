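## Canonical miRNA seed-site detection, shared-sponge identification and
## ORF finding. Sites use exact complementarity to the miRNA seed (no
## wobble pairing), with the four canonical types:
##   6mer     = transcript match to revcomp(miRNA positions 2-7)
##   7mer-m8  = 6mer extended by complementarity to miRNA position 8
##   7mer-A1  = 6mer plus an A in the transcript opposite miRNA position 1
##   8mer     = both extensions
## Overlapping calls of one miRNA at a locus are collapsed to the highest
## type (8mer > 7mer-m8 > 7mer-A1 > 6mer).

SITE_PRIORITY <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Find canonical miRNA seed sites in a transcript
#'
#' @param transcript_seq Transcript sequence, 5'->3' (DNA or RNA alphabet).
#' @param mirna_seq Mature miRNA sequence, 5'->3' (>= 8 nt).
#' @param mirna_id Optional id carried into the result.
#' @param transcript_id Optional id carried into the result.
#' @return Tibble: `transcript_id`, `mirna_id`, `site_type`, `start`
#'   (0-based on the transcript, leftmost base of the site),
#'   `site_sequence` (in the transcript's input alphabet).
#' @export
find_seed_sites <- function(transcript_seq, mirna_seq,
                            mirna_id = NA_character_,
                            transcript_id = NA_character_) {
  if (nchar(mirna_seq) < 8) stop("find_seed_sites: miRNA shorter than 8 nt")
  was_rna <- grepl("U", toupper(transcript_seq), fixed = TRUE)
  tx <- norm_dna(transcript_seq)
  mi <- norm_dna(mirna_seq)
  seed27 <- substr(mi, 2, 7)
  m8 <- substr(mi, 8, 8)
  core6 <- revcomp_dna(seed27)            # transcript-sense 6mer
  m8c <- revcomp_dna(m8)                  # base pairing miRNA pos 8

  n <- nchar(tx)
  starts <- integer(0)
  if (n >= 6) {
    ## all (possibly overlapping) core-6mer matches via a lookahead scan
    m <- gregexpr(paste0("(?=", core6, ")"), tx, perl = TRUE)[[1]]
    if (m[1] != -1L) starts <- as.integer(m)
  }
  if (!length(starts)) {
    return(tibble(transcript_id = character(), mirna_id = character(),
                  site_type = character(), start = integer(),
                  core_start = integer(), site_sequence = character()))
  }
  ## pos-8 pairing sits immediately 5' of the core on the transcript; the A
  ## opposite miRNA position 1 sits immediately 3' of it
  has_m8 <- starts >= 2 & substring(tx, starts - 1L, starts - 1L) == m8c
  has_a1 <- starts + 6L <= n & substring(tx, starts + 6L, starts + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
                 ifelse(has_m8, "7mer-m8",
                        ifelse(has_a1, "7mer-A1", "6mer")))
  from <- ifelse(has_m8, starts - 1L, starts)
  to <- ifelse(has_a1, starts + 6L, starts + 5L)
  out <- tibble(
    transcript_id = transcript_id, mirna_id = mirna_id, site_type = type,
    start = as.integer(from) - 1L, core_start = starts - 1L,
    site_sequence = substring(tx, from, to))
  if (was_rna) out$site_sequence <- render_rna(out$site_sequence)
  out
}

#' Shared-sponge miRNAs between a pseudogene and its parent
#'
#' Reports miRNAs with at least one canonical seed site in each sequence,
#' plus Venn counts (pseudogene-only / shared / parent-only).
#'
#' @param pseudogene_seq,parent_seq Transcript sequences (the parent's
#'   3'UTR is typical).
#' @param mirnas Tibble `mirna_id`, `sequence`.
#' @return List: `shared` (tibble of co-binding miRNAs with per-sequence
#'   site counts), `venn` (tibble with the three counts).
#' @export
shared_mirnas <- function(pseudogene_seq, parent_seq, mirnas) {
  stopifnot(nchar(pseudogene_seq) > 0, nchar(parent_seq) > 0)
  if (!nrow(mirnas)) {
    return(list(shared = tibble(mirna_id = character(),
                                n_sites_pseudogene = integer(),
                                n_sites_parent = integer()),
                venn = tibble(pseudogene_only = 0L, shared = 0L,
                              parent_only = 0L)))
  }
  count_sites <- function(mi, tx) {
    ## fast path: count core-6mer loci (every canonical type contains one)
    core6 <- revcomp_dna(substr(norm_dna(mi), 2, 7))
    m <- gregexpr(paste0("(?=", core6, ")"), norm_dna(tx), perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  per <- tibble(
    mirna_id = mirnas$mirna_id,
    n_sites_pseudogene = vapply(mirnas$sequence, count_sites,
                                integer(1), tx = pseudogene_seq,
                                USE.NAMES = FALSE),
    n_sites_parent = vapply(mirnas$sequence, count_sites, integer(1),
                            tx = parent_seq, USE.NAMES = FALSE))
  shared <- per |> filter(.data$n_sites_pseudogene > 0,
                          .data$n_sites_parent > 0)
  venn <- tibble(
    pseudogene_only = sum(per$n_sites_pseudogene > 0 &
                            per$n_sites_parent == 0),
    shared = nrow(shared),
    parent_only = sum(per$n_sites_parent > 0 &
                        per$n_sites_pseudogene == 0))
  list(shared = shared, venn = venn)
}

#' Find open reading frames in the forward frames
#'
#' Scans the three forward frames for ATG...stop ORFs. `aa_length` counts
#' codons from the ATG (inclusive) to the stop (exclusive). Nested starts
#' within a frame each report their own ORF to the same stop.
#'
#' @param seq Nucleotide sequence (DNA or RNA alphabet).
#' @return Tibble of class `pg_orfs`: `start`, `end` (0-based half-open,
#'   stop codon included in the span), `frame` (0/1/2), `aa_length`; sorted
#'   by decreasing `aa_length`. Empty when no ORF exists.
#' @export
find_orfs <- function(seq) {
  s <- norm_dna(seq)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  orfs <- list()
  for (frame in 0:2) {
    starts_open <- integer(0)
    pos <- frame + 1L
    while (pos + 2L <= n) {
      codon <- substr(s, pos, pos + 2L)
      if (codon == "ATG") starts_open <- c(starts_open, pos)
      if (codon %in% stops && length(starts_open)) {
        for (st in starts_open) {
          orfs[[length(orfs) + 1L]] <- tibble(
            start = st - 1L, end = pos + 2L, frame = frame,
            aa_length = (pos - st) %/% 3L)
        }
        starts_open <- integer(0)
      }
      pos <- pos + 3L
    }
  }
  out <- if (length(orfs)) {
    bind_rows(orfs) |> arrange(desc(.data$aa_length), .data$start)
  } else {
    tibble(start = integer(), end = integer(), frame = integer(),
           aa_length = integer())
  }
  structure(out, class = c("pg_orfs", class(tibble())))
}

#' Longest forward-frame ORF
#'
#' @param seq Nucleotide sequence.
#' @return One-row tibble (the longest ORF) or an empty tibble.
#' @export
longest_orf <- function(seq) {
  head(find_orfs(seq), 1)
}
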