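## Discriminative ungapped motif discovery, DREME-style: enumerate exact
## words (widths 4-8) present in the target peak sequences, test each with a
## one-sided exact test of sequence-level (ZOOPS) presence against
## per-sequence mononucleotide-shuffled controls, generalize the best word
## over the IUPAC alphabet, erase its matches and repeat.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

norm_dna <- function(x) chartr("Uu", "Tt", toupper(x))
render_rna <- function(x) chartr("T", "U", x)

#' Mononucleotide shuffle of sequences
#'
#' Shuffles each sequence independently, preserving its length and exact
#' base multiset (the nucleotide frequencies), to build the control set for
#' discriminative motif discovery.
#'
#' @param sequences Character vector (DNA or RNA; case preserved as upper).
#' @param seed Integer seed; same seed gives identical controls.
#' @return Character vector of shuffled sequences, same alphabet as input.
#' @export
shuffle_controls <- function(sequences, seed = 1L) {
  stopifnot(length(sequences) > 0)
  was_rna <- any(grepl("U", toupper(sequences), fixed = TRUE))
  seqs <- norm_dna(sequences)
  out <- with_substream(seed, "shuffle", {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  if (was_rna) render_rna(out) else out
}

## per-sequence sets of distinct words of width w
seq_word_sets <- function(seqs, w) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    ws <- unique(substring(s, 1:(n - w + 1), w:n))
    ws[!grepl("[^ACGT]", ws)]
  })
}

## sequence-level presence counts of `words` given per-sequence word sets
count_presence <- function(words, word_sets) {
  tab <- table(unlist(word_sets, use.names = FALSE))
  out <- as.integer(tab[words])
  out[is.na(out)] <- 0L
  out
}

iupac_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

count_pattern_presence <- function(pattern, seqs) {
  sum(stringr::str_detect(seqs, iupac_regex(pattern)))
}

motif_p <- function(n_t, n_c, N_t, N_c) {
  ## one-sided exact enrichment p of presence/absence counts
  hyper_p_greater(n_t, N_t - n_t, n_c, N_c - n_c)
}

#' Discriminative motif discovery
#'
#' Enumerates every exact word of widths `widths` occurring in the target
#' sequences, scores each with a one-sided exact test of the number of
#' target vs control sequences containing it, generalizes the best word
#' position-by-position over IUPAC codes (accepting a degenerate position
#' only when it improves the p-value), reports the motif, erases its matches
#' from the targets and repeats, up to `max_motifs` motifs or until the best
#' candidate fails a Bonferroni-corrected `alpha` over the number of words
#' tested in that round.
#'
#' @param targets Character vector of target (peak) sequences.
#' @param controls Character vector of control sequences, e.g. from
#'   [shuffle_controls()].
#' @param widths Integer vector of word widths (default 4:8).
#' @param max_motifs Maximum motifs reported.
#' @param alpha Family-wise significance level for the stopping rule.
#' @return Tibble of class `pg_motifs`: `rank`, `pattern` (IUPAC, RNA
#'   alphabet), `width`, `n_target`, `n_control`, `p_value`, `matches_rrach`.
#' @export
find_motifs <- function(targets, controls, widths = 4:8, max_motifs = 5L,
                        alpha = 0.05) {
  if (!length(targets)) return(empty_motifs())
  stopifnot(all(widths >= 4), all(widths <= 8))
  targets <- norm_dna(targets)
  controls <- norm_dna(controls)
  results <- list()

  for (round in seq_len(max_motifs)) {
    N_t <- length(targets); N_c <- length(controls)

    best <- NULL; n_words <- 0L
    for (w in widths) {
      sets_t <- seq_word_sets(targets, w)
      words <- unique(unlist(sets_t, use.names = FALSE))
      if (!length(words)) next
      n_words <- n_words + length(words)
      n_t <- count_presence(words, sets_t)
      n_c <- count_presence(words, seq_word_sets(controls, w))
      p <- motif_p(n_t, n_c, N_t, N_c)
      i <- which.min(p)
      if (is.null(best) || p[i] < best$p) {
        best <- list(word = words[i], p = p[i], n_t = n_t[i], n_c = n_c[i])
      }
    }
    if (is.null(best) || best$p >= alpha / max(1L, n_words)) break

    ## greedy IUPAC generalization of the best word
    pat <- strsplit(best$word, "")[[1]]
    cur_p <- best$p
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (pos in seq_along(pat)) {
        cand_codes <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) {
          all(IUPAC_SETS[[pat[pos]]] %in% s) &&
            length(s) > length(IUPAC_SETS[[pat[pos]]])
        }, logical(1))]
        for (code in cand_codes) {
          trial <- pat; trial[pos] <- code
          tp <- paste(trial, collapse = "")
          p_new <- motif_p(count_pattern_presence(tp, targets),
                           count_pattern_presence(tp, controls), N_t, N_c)
          if (p_new < cur_p) {
            pat <- trial; cur_p <- p_new; improved <- TRUE
          }
        }
      }
    }
    pattern <- paste(pat, collapse = "")
    n_t_final <- count_pattern_presence(pattern, targets)
    n_c_final <- count_pattern_presence(pattern, controls)
    results[[round]] <- tibble(
      rank = round, pattern = render_rna(pattern),
      width = nchar(pattern), n_target = n_t_final, n_control = n_c_final,
      p_value = cur_p, matches_rrach = match_rrach(pattern))

    ## erase matched occurrences from the targets and continue
    rex <- iupac_regex(pattern)
    hit <- stringr::str_detect(targets, rex)
    if (!any(hit)) break
    targets[hit] <- stringr::str_replace_all(targets[hit], rex,
                                             strrep("N", nchar(pattern)))
  }
  if (!length(results)) return(empty_motifs())
  structure(bind_rows(results), class = c("pg_motifs", "tbl_df", "tbl",
                                          "data.frame"))
}

empty_motifs <- function() {
  structure(
    tibble(rank = integer(), pattern = character(), width = integer(),
           n_target = integer(), n_control = integer(), p_value = double(),
           matches_rrach = logical()),
    class = c("pg_motifs", "tbl_df", "tbl", "data.frame"))
}

#' Does a motif lie within the RRACH consensus?
#'
#' `TRUE` when the pattern's match set is a subset of RRACH's
#' (R = A/G, H = A/C/U) at some alignment offset: a pattern of width 5 or
#' more must contain a full RRACH window position-by-position; a shorter
#' pattern (discriminative motifs can be as short as 4 nt) must align
#' position-by-position inside a sub-window of RRACH.
#'
#' @param pattern IUPAC string (DNA or RNA alphabet).
#' @return Logical flag.
#' @export
#' @examples
#' match_rrach("GGACU")
#' match_rrach("UUUUU")
match_rrach <- function(pattern) {
  pat <- strsplit(norm_dna(pattern), "")[[1]]
  if (any(!pat %in% names(IUPAC_SETS))) {
    stop("match_rrach: non-IUPAC symbol in pattern")
  }
  rrach <- strsplit("RRACH", "")[[1]]
  w <- length(pat)
  subset_at <- function(p_idx, r_idx) {
    all(vapply(seq_along(p_idx), function(k) {
      all(IUPAC_SETS[[pat[p_idx[k]]]] %in% IUPAC_SETS[[rrach[r_idx[k]]]])
    }, logical(1)))
  }
  if (w >= 5) {
    for (off in 0:(w - 5)) {
      if (subset_at(off + 1:5, 1:5)) return(TRUE)
    }
  } else {
    for (off in 0:(5 - w)) {
      if (subset_at(seq_len(w), off + seq_len(w))) return(TRUE)
    }
  }
  FALSE
}

#' Extract peak sequences from a genome
#'
#' Strand-aware: sequences of peaks on the minus strand are
#' reverse-complemented so they read in the gene's sense orientation.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `strand`).
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of DNA sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- substr(genome[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i])
    if (peaks$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    s
  }, character(1))
}
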