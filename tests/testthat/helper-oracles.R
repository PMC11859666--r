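# Independent oracles used to validate the package's statistics. These are
# deliberately naive (enumeration / closed forms), sharing no code with the
# implementation paths they check.

# one-sided upper-tail probability of a = table [a b; c d] under the
# hypergeometric null, by explicit summation of point masses
oracle_hyper_tail <- function(a, b, c, d) {
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # column-1 total
  lo <- max(0, k - n); hi <- min(m, k)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  sum(exp(logp(a:hi)))
}

# two-sided Fisher p: sum of point masses not exceeding the observed one
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(m, k)
  pm <- exp(lchoose(m, lo:hi) + lchoose(n, k - (lo:hi)) - lchoose(m + n, k))
  obs <- pm[a - lo + 1]
  sum(pm[pm <= obs * (1 + 1e-7)])
}

# Spearman rho as Pearson correlation of average ranks (tie-corrected form)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments of the pooled observations (no ties expected)
oracle_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  ew <- n1 * length(y) / 2
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}

# Efron partial log-likelihood for a single covariate
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(beta * x[D])
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sR - l / d * sD)
    }
  }
  ll
}

# coarse-to-fine grid maximization of the Efron partial likelihood
oracle_cox_grid <- function(time, event, x, lim = 5) {
  grid1 <- seq(-lim, lim, by = 0.01)
  ll1 <- vapply(grid1, oracle_efron_loglik, numeric(1),
                time = time, event = event, x = x)
  b1 <- grid1[which.max(ll1)]
  grid2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  ll2 <- vapply(grid2, oracle_efron_loglik, numeric(1),
                time = time, event = event, x = x)
  grid2[which.max(ll2)]
}

# two-group log-rank chi-square from expected-event tables
oracle_logrank <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# position-by-position brute-force region labeler with precedence
oracle_label_position <- function(pos, chrom, catalog, flank = 1000,
                                  precedence = c("3UTR", "5UTR", "exon",
                                                 "TSS", "TTS", "intron",
                                                 "intergenic")) {
  labs <- character(0)
  for (i in seq_len(nrow(catalog$genes))) {
    g <- catalog$genes[i, ]
    if (g$chrom != chrom) next
    ex <- catalog$exons[catalog$exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    cd <- catalog$cds[catalog$cds$gene_id == g$gene_id, ]
    in_exon <- any(pos >= ex$start & pos < ex$end)
    if (in_exon) {
      if (nrow(cd)) {
        lo <- min(cd$start); hi <- max(cd$end)
        if (pos < lo) {
          labs <- c(labs, if (g$strand == "+") "5UTR" else "3UTR")
        } else if (pos >= hi) {
          labs <- c(labs, if (g$strand == "+") "3UTR" else "5UTR")
        } else {
          labs <- c(labs, "exon")
        }
      } else {
        labs <- c(labs, "exon")
      }
    } else if (pos >= g$start && pos < g$end) {
      labs <- c(labs, "intron")
    }
    tss <- if (g$strand == "+") g$start else g$end
    tts <- if (g$strand == "+") g$end else g$start
    if (pos >= tss - flank && pos < tss + flank) labs <- c(labs, "TSS")
    if (pos >= tts - flank && pos < tts + flank) labs <- c(labs, "TTS")
  }
  labs <- c(labs, "intergenic")
  precedence[min(match(labs, precedence))]
}

# brute-force sliding-window canonical seed-site scan
oracle_seed_sites <- function(tx, mi) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  tx <- chartr("Uu", "Tt", toupper(tx)); mi <- chartr("Uu", "Tt", toupper(mi))
  core <- rc(substr(mi, 2, 7))
  m8pair <- rc(substr(mi, 8, 8))
  n <- nchar(tx)
  out <- NULL
  for (s in seq_len(max(0, n - 5))) {
    if (substr(tx, s, s + 5) != core) next
    m8 <- s > 1 && substr(tx, s - 1, s - 1) == m8pair
    a1 <- s + 6 <= n && substr(tx, s + 6, s + 6) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-A1" else "6mer"
    out <- rbind(out, data.frame(core_start = s - 1L, site_type = type))
  }
  out
}

# brute-force three-frame ORF scan
oracle_longest_orf <- function(seq) {
  s <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i
    while (j + 2 <= n) {
      if (substr(s, j, j + 2) %in% stops && j > i) {
        best <- max(best, (j - i) %/% 3L)
        break
      }
      j <- j + 3
    }
  }
  best
}

# small fixed catalog used by several tests: two genes on chr1
toy_catalog <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(1000L, 5000L), end = c(2000L, 6200L),
    strand = c("+", "-"),
    biotype = c("protein_coding", "processed_pseudogene"),
    subtype = c(NA, "processed"),
    is_pseudogene = c(FALSE, TRUE),
    parent_gene_id = NA_character_,
    unpaired = c(FALSE, TRUE))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(1000L, 1600L, 5000L), end = c(1400L, 2000L, 6200L),
    strand = c("+", "+", "-"))
  cds <- tibble::tibble(
    gene_id = "gA", chrom = "chr1", start = 1100L, end = 1900L,
    strand = "+")
  pseudom6a:::new_catalog(genes, exons, cds)
}

# window-count container built directly from a matrix of pooled counts:
# one gene, w windows, given per-window IP/input counts for one condition
toy_windowcounts <- function(ip, input, condition = "tumour",
                             gene_id = "g1", window_size = 50L,
                             step = 50L) {
  w <- length(ip)
  tl <- tibble::tibble(
    gene_id = gene_id, window_index = seq_len(w), chrom = "chr1",
    start = (seq_len(w) - 1L) * step, end = (seq_len(w) - 1L) * step +
      window_size, strand = "+")
  counts <- dplyr::bind_rows(
    dplyr::mutate(tl, sample = paste0(condition, "_IP_1"), assay = "IP",
                  condition = condition, count = as.integer(ip)),
    dplyr::mutate(tl, sample = paste0(condition, "_input_1"),
                  assay = "input", condition = condition,
                  count = as.integer(input)))
  libs <- counts |>
    dplyr::group_by(sample, assay, condition) |>
    dplyr::summarise(lib_size = sum(count), .groups = "drop")
  structure(list(counts = counts, lib_sizes = libs),
            class = "pg_windowcounts")
}
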