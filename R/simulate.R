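## Synthetic multi-omics generator.
##
## Emulates the statistical structure of the real study design -- MeRIP-seq
## IP/input window counts with enrichment at planted RRACH sites, NB
## expression counts with condition effects, pseudogene-parent (ceRNA)
## coupling, m6A-expression coupling, survival hazard tied to expression,
## and sparse genetic alteration matrices -- so every downstream stage is
## testable offline with a known planted truth.

#' Simulation configuration
#'
#' Builds the parameter set for the synthetic multi-omics generator. Defaults
#' describe a desk-scale cohort with the qualitative structure of a
#' high-grade serous ovarian carcinoma MeRIP/expression/survival study:
#' mostly processed pseudogenes, a minority of genes m6A-methylated with
#' tumour/normal hyper- and hypomethylation, NB counts, positive
#' pseudogene-parent coupling, and hazard increasing with the planted risk
#' gene's expression.
#'
#' @param n_genes Number of genes (>= 2).
#' @param pseudogene_fraction Fraction of genes that are pseudogenes.
#' @param subtype_proportions Named proportions over the four pseudogene
#'   subtypes; default 72% processed (the dominant class genome-wide),
#'   20% unprocessed, 5% unitary, 3% polymorphic.
#' @param n_merip Named vector: MeRIP replicate pairs (IP + input) per
#'   condition.
#' @param n_expr Named vector: expression samples per condition.
#' @param window_size,step Window tiling for MeRIP counts, nt.
#' @param mean_depth Mean input reads per window.
#' @param nb_dispersion NB dispersion phi (variance mu + phi mu^2).
#' @param peak_enrichment_fold IP/input fold at methylated windows.
#' @param fraction_methylated Fraction of genes carrying an m6A site.
#' @param fraction_hyper,fraction_hypo Fractions of methylated genes whose
#'   methylation is tumour-specific (hyper) or normal-specific (hypo).
#' @param de_fraction,de_log2fc Fraction of genes differentially expressed
#'   and their absolute log2 fold change.
#' @param cerna_coupling_rho Latent log-scale correlation between a
#'   pseudogene and its parent across samples.
#' @param cerna_m6a_attenuation If > 0, pair coupling shrinks linearly with
#'   the pseudogene's m6A level rank (0 = no attenuation).
#' @param m6a_expression_gamma Coupling strength: gene expression mean is
#'   scaled by exp(-gamma * m6A level).
#' @param survival_beta Log hazard ratio per SD of the risk gene's
#'   expression; default log(2).
#' @param censor_fraction Target fraction of censored samples.
#' @param n_survival Number of survival samples.
#' @param mutation_rate,cnv_rate Per-gene-per-sample alteration
#'   probabilities.
#' @param n_genetic_samples Samples in the mutation/CNV matrices.
#' @param planted_motif Motif planted at methylation sites (DNA alphabet;
#'   default GGACT, i.e. GGACU, the canonical RRACH core).
#' @param expr_mean_log,expr_sd_log Log-normal baseline for gene expression
#'   means.
#' @param sigma_log Per-sample biological log-noise SD.
#' @param plant_driver Plant one "driver" processed pseudogene that is
#'   hypomethylated, up-regulated, prognostic-risk and genetically
#'   unaltered (the candidate the filter cascade should surface).
#' @param seed Master seed; every generator draws from a named substream of
#'   it, so outputs are bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       pseudogene_fraction = 0.5,
                       subtype_proportions = c(processed = 0.72,
                                               unprocessed = 0.20,
                                               unitary = 0.05,
                                               polymorphic = 0.03),
                       n_merip = c(tumour = 3, normal = 3),
                       n_expr = c(tumour = 50, normal = 30),
                       window_size = 50, step = 25,
                       mean_depth = 30,
                       nb_dispersion = 0.1,
                       peak_enrichment_fold = 4,
                       fraction_methylated = 0.3,
                       fraction_hyper = 0.25,
                       fraction_hypo = 0.25,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       cerna_coupling_rho = 0.6,
                       cerna_m6a_attenuation = 0,
                       m6a_expression_gamma = 0.3,
                       survival_beta = log(2),
                       censor_fraction = 0.2,
                       n_survival = 200,
                       mutation_rate = 0.005,
                       cnv_rate = 0.03,
                       n_genetic_samples = 100,
                       planted_motif = "GGACT",
                       expr_mean_log = log(100),
                       expr_sd_log = 1,
                       sigma_log = 0.5,
                       plant_driver = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(cfg$pseudogene_fraction, cfg$fraction_methylated, cfg$fraction_hyper,
          cfg$fraction_hypo, cfg$de_fraction, cfg$censor_fraction,
          cfg$subtype_proportions)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$peak_enrichment_fold > 0,
            cfg$nb_dispersion > 0, cfg$n_genes >= 2,
            abs(sum(cfg$subtype_proportions) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

rnb <- function(n, mu, phi) {
  ## NB with variance mu + phi mu^2
  rnbinom(n, size = 1 / phi, mu = mu)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant_subseq <- function(genome, chrom, pos0, subseq, strand = "+") {
  ## overwrite genome[chrom][pos0, pos0+nchar) with subseq (0-based);
  ## on "-" the gene-sense motif is planted as its reverse complement
  if (strand == "-") {
    subseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(subseq)))
  }
  s <- genome[[chrom]]
  substr(s, pos0 + 1L, pos0 + nchar(subseq)) <- subseq
  genome[[chrom]] <- s
  genome
}

#' Simulate a genome annotation, sequence and planted m6A truth
#'
#' Generates random gene models on a handful of chromosomes, labels
#' pseudogenes with subtypes at the configured proportions (processed
#' pseudogenes are intronless, mirroring their retrotransposed origin),
#' pairs each pseudogene with a parent gene, and emits random chromosome
#' sequences with the configured motif planted at every designated
#' methylation site. The planted truth (which genes are methylated, their
#' hyper/hypo state, DE status, the driver gene) is returned as a tibble so
#' downstream recovery tests are self-contained.
#'
#' @param config A [sim_config()].
#' @return A list with elements `catalog` (a `pg_catalog`), `genome` (named
#'   character vector of chromosome sequences), `truth` (per-gene tibble) and
#'   `meth_windows` (tibble of planted methylated windows).
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 2) stop("n_genes must be >= 2")
  with_substream(config$seed, "annotation", {
    n <- config$n_genes
    n_pg <- round(n * config$pseudogene_fraction)
    chroms <- paste0("chr", 1:4)
    gene_chrom <- sample(chroms, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("G%04d", seq_len(n))
    is_pg <- c(rep(TRUE, n_pg), rep(FALSE, n - n_pg))
    subtype <- rep(NA_character_, n)
    subtype[is_pg] <- sample(names(config$subtype_proportions), n_pg,
                             replace = TRUE,
                             prob = config$subtype_proportions)
    ## ensure at least one processed pseudogene to host the driver
    if (config$plant_driver && n_pg > 0 && !any(subtype %in% "processed")) {
      subtype[which(is_pg)[1]] <- "processed"
    }
    ids[is_pg] <- sprintf("PG%04d", seq_len(n_pg))

    genes <- list(); exons <- list()
    cursor <- setNames(rep(2000L, length(chroms)), chroms)
    for (i in seq_len(n)) {
      intronless <- is_pg[i] && subtype[i] == "processed"
      n_ex <- if (intronless) 1L else sample(2:4, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      ex_len <- pmax(ex_len, 150L)
      intron_len <- if (n_ex > 1) sample(100:500, n_ex - 1, TRUE) else integer(0)
      ch <- gene_chrom[i]
      s0 <- cursor[[ch]]
      starts <- s0 + cumsum(c(0L, head(ex_len, -1) + intron_len))
      ends <- starts + ex_len
      cursor[[ch]] <- max(ends) + sample(2500:4000, 1)
      genes[[i]] <- tibble(
        gene_id = ids[i], chrom = ch, start = min(starts),
        end = max(ends), strand = strand[i],
        biotype = if (is_pg[i]) paste0(subtype[i], "_pseudogene") else
          "protein_coding",
        subtype = subtype[i], is_pseudogene = is_pg[i],
        parent_gene_id = NA_character_, unpaired = is_pg[i])
      exons[[i]] <- tibble(gene_id = ids[i], chrom = ch,
                           start = as.integer(starts), end = as.integer(ends),
                           strand = strand[i])
    }
    catalog <- new_catalog(bind_rows(genes), bind_rows(exons))

    ## parent pairing: each pseudogene mapped to a random non-pseudogene
    ## gene; parents are drawn without replacement where possible so each
    ## pair carries its own independent coupling
    parents <- ids[!is_pg]
    pairing <- tibble(
      pseudogene_id = ids[is_pg],
      parent_gene_id = sample(parents, n_pg,
                              replace = n_pg > length(parents)))
    catalog <- suppressWarnings(pair_parents(catalog, pairing))

    ## genome sequence per chromosome
    genome <- setNames(
      vapply(chroms, function(ch) random_dna(max(cursor[[ch]], 3000L) + 2000L),
             character(1)),
      chroms)

    ## m6A truth: methylated genes, hyper/hypo states, one window per gene
    meth <- sample(ids, round(n * config$fraction_methylated))
    state <- setNames(rep("none", n), ids)
    state[meth] <- "stable"
    n_h <- round(length(meth) * config$fraction_hyper)
    n_l <- round(length(meth) * config$fraction_hypo)
    shuf <- sample(meth)
    state[shuf[seq_len(n_h)]] <- "hyper"
    state[shuf[n_h + seq_len(n_l)]] <- "hypo"

    ## DE truth
    de <- setNames(rep("ns", n), ids)
    n_de <- round(n * config$de_fraction)
    de_genes <- sample(ids, n_de)
    de[de_genes] <- sample(c("up", "down"), n_de, replace = TRUE)

    ## the planted driver: processed pseudogene, paired, hypo + up + risk
    driver <- NA_character_
    if (config$plant_driver && n_pg > 0) {
      cand <- catalog$genes |>
        filter(.data$is_pseudogene, .data$subtype == "processed",
               !.data$unpaired)
      driver <- cand$gene_id[1]
      state[driver] <- "hypo"
      de[driver] <- "up"
    }

    tiling <- window_tiling(catalog, config$window_size, config$step)
    meth_ids <- names(state)[state != "none"]
    meth_windows <- tiling |>
      filter(.data$gene_id %in% meth_ids) |>
      group_by(.data$gene_id) |>
      ## prefer an interior full-width window so the motif fits
      filter(.data$end - .data$start == config$window_size) |>
      dplyr::slice_sample(n = 1) |>
      ungroup()

    ## plant the motif (gene-sense) at each methylated window's centre
    motif <- config$planted_motif
    for (i in seq_len(nrow(meth_windows))) {
      w <- meth_windows[i, ]
      centre <- w$start + (w$end - w$start) %/% 2 - nchar(motif) %/% 2
      genome <- plant_subseq(genome, w$chrom, centre, motif, w$strand)
    }

    ## plant a shared miRNA seed site (UUGGCA-like) in driver and its parent
    if (!is.na(driver)) {
      par_id <- catalog$genes$parent_gene_id[catalog$genes$gene_id == driver]
      for (gid in c(driver, par_id)) {
        ex1 <- catalog$exons |> filter(.data$gene_id == gid) |> head(1)
        st <- catalog$genes$strand[catalog$genes$gene_id == gid]
        genome <- plant_subseq(genome, ex1$chrom, ex1$start + 20L,
                               "TTGGCA", st)
      }
    }

    truth <- catalog$genes |>
      select("gene_id", "is_pseudogene", "subtype", "parent_gene_id") |>
      mutate(m6a_state = unname(state[.data$gene_id]),
             methylated = .data$m6a_state != "none",
             de_status = unname(de[.data$gene_id]),
             true_log2fc = dplyr::case_when(
               de_status == "up" ~ config$de_log2fc,
               de_status == "down" ~ -config$de_log2fc,
               TRUE ~ 0),
             is_driver = .data$gene_id %in% driver,
             risk_gene = .data$is_driver)

    list(catalog = catalog, genome = genome, truth = truth,
         meth_windows = meth_windows)
  })
}

#' Simulate MeRIP-seq IP/input window counts
#'
#' Input counts are NB around a gene-level depth; IP counts at planted
#' methylated windows are inflated by the configured enrichment fold. Genes
#' in the `hyper` state are enriched in tumour only, `hypo` in normal only,
#' `stable` in both.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @param config The same [sim_config()].
#' @return A `pg_windowcounts`: list with `counts` (long tibble: `gene_id`,
#'   `window_index`, `chrom`, `start`, `end`, `strand`, `sample`, `assay`,
#'   `condition`, `count`) and `lib_sizes` (per-sample totals).
#' @export
simulate_merip <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "merip", {
    tiling <- window_tiling(sim$catalog, config$window_size, config$step)
    truth <- sim$truth
    meth_key <- sim$meth_windows |>
      mutate(meth = TRUE) |>
      select("gene_id", "window_index", "meth")
    tiling <- tiling |>
      left_join(meth_key, by = c("gene_id", "window_index")) |>
      mutate(meth = !is.na(.data$meth)) |>
      left_join(truth |> select("gene_id", "m6a_state"), by = "gene_id")

    gene_depth <- with_substream(config$seed, "merip_depth",
      setNames(exp(rnorm(nrow(truth), log(config$mean_depth), 0.3)),
               truth$gene_id))

    ## Biological replicate noise acts at the gene level: the gene's total
    ## count is NB, and reads are then placed multinomially along its
    ## windows (weighted by window length, and by the enrichment fold at
    ## methylated windows in the IP). Conditional on the gene totals,
    ## within-gene window counts are therefore exchangeable-multinomial,
    ## which is the sampling model the exact window test assumes.
    gidx <- split(seq_len(nrow(tiling)), tiling$gene_id)
    wlen <- (tiling$end - tiling$start) / config$window_size

    out <- list(); libs <- list()
    for (cond in names(config$n_merip)) {
      enr_on <- tiling$meth & (
        tiling$m6a_state == "stable" |
        (tiling$m6a_state == "hyper" & cond == "tumour") |
        (tiling$m6a_state == "hypo" & cond == "normal"))
      w_ip <- wlen * ifelse(enr_on, config$peak_enrichment_fold, 1)
      for (r in seq_len(config$n_merip[[cond]])) {
        for (assay in c("IP", "input")) {
          w <- if (assay == "IP") w_ip else wlen
          cnt <- integer(nrow(tiling))
          for (g in names(gidx)) {
            ii <- gidx[[g]]
            mu_g <- gene_depth[[g]] * sum(w[ii])
            tot <- rnb(1, mu_g, config$nb_dispersion)
            cnt[ii] <- as.integer(stats::rmultinom(1, tot,
                                                   prob = w[ii]))
          }
          smp <- sprintf("%s_%s_%d", cond, assay, r)
          out[[smp]] <- tiling |>
            select("gene_id", "window_index", "chrom", "start", "end",
                   "strand") |>
            mutate(sample = smp, assay = assay, condition = cond,
                   count = cnt)
          libs[[smp]] <- tibble(sample = smp, assay = assay,
                                condition = cond, lib_size = sum(cnt))
        }
      }
    }
    structure(list(counts = bind_rows(out), lib_sizes = bind_rows(libs)),
              class = "pg_windowcounts")
  })
}

#' Simulate an expression count matrix
#'
#' NB counts with a log-normal baseline, planted DE genes at the configured
#' fold change, optional m6A-expression coupling (gene mean scaled by
#' exp(-gamma * m6A level)), and pseudogene-parent coupling through a
#' bivariate Gaussian on the per-sample log-scale noise.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @param config A [sim_config()].
#' @param m6a_levels Optional tibble (`gene_id`, `level`); if given, the
#'   gene mean is scaled by `exp(-m6a_expression_gamma * level)`.
#' @return A `pg_expr`: list with `counts` (genes x samples integer matrix)
#'   and `samples` (tibble `sample_id`, `condition`).
#' @export
simulate_expression <- function(sim, config, m6a_levels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "expression", {
    truth <- sim$truth
    n <- nrow(truth)
    ids <- truth$gene_id
    base_log <- rnorm(n, config$expr_mean_log, config$expr_sd_log)
    names(base_log) <- ids
    if (!is.null(m6a_levels)) {
      lv <- setNames(m6a_levels$level, m6a_levels$gene_id)[ids]
      lv[is.na(lv)] <- 0
      base_log <- base_log - config$m6a_expression_gamma * lv
    }

    samples <- tibble(
      sample_id = c(sprintf("T%03d", seq_len(config$n_expr[["tumour"]])),
                    sprintf("N%03d", seq_len(config$n_expr[["normal"]]))),
      condition = rep(c("tumour", "normal"), config$n_expr))
    ns <- nrow(samples)
    tumour <- samples$condition == "tumour"

    ## per-gene per-sample log-noise; pairs get correlated noise
    eps <- matrix(rnorm(n * ns, 0, config$sigma_log), n, ns,
                  dimnames = list(ids, samples$sample_id))
    pairs <- sim$catalog$pairs
    if (nrow(pairs)) {
      rho0 <- config$cerna_coupling_rho
      att <- config$cerna_m6a_attenuation
      u <- rep(0, nrow(pairs))
      if (att > 0 && !is.null(m6a_levels)) {
        lv <- setNames(m6a_levels$level, m6a_levels$gene_id)
        pl <- lv[pairs$pseudogene_id]
        pl[is.na(pl)] <- min(lv, na.rm = TRUE)
        u <- (rank(pl) - 1) / max(1, length(pl) - 1)
      }
      for (k in seq_len(nrow(pairs))) {
        rho <- max(0, rho0 * (1 - att * u[k]))
        pg <- pairs$pseudogene_id[k]; pa <- pairs$parent_gene_id[k]
        z1 <- rnorm(ns); z2 <- rnorm(ns)
        eps[pg, ] <- config$sigma_log * z1
        eps[pa, ] <- config$sigma_log * (rho * z1 + sqrt(1 - rho^2) * z2)
      }
    }

    de_shift <- matrix(0, n, ns, dimnames = dimnames(eps))
    lfc <- setNames(truth$true_log2fc, truth$gene_id)
    de_shift[, tumour] <- matrix(rep(lfc * log(2), sum(tumour)),
                                 n, sum(tumour))

    size_fac <- exp(rnorm(ns, 0, 0.1))
    mu <- exp(base_log + eps + de_shift) %*% diag(size_fac)
    counts <- matrix(rnb(length(mu), as.vector(mu), config$nb_dispersion),
                     n, ns, dimnames = list(ids, samples$sample_id))
    structure(list(counts = counts, samples = samples), class = "pg_expr")
  })
}

#' Simulate survival records tied to expression
#'
#' Event times are exponential with hazard proportional to
#' `exp(survival_beta * z)` where `z` is the z-scored log2(CPM+1) expression
#' of the planted risk gene(s) in tumour samples; censoring is independent
#' uniform with its upper bound solved so the expected censored fraction
#' matches the configuration.
#'
#' @param expr A `pg_expr` from [simulate_expression()].
#' @param config A [sim_config()].
#' @param risk_genes Character vector of risk gene ids (default: the planted
#'   driver from `truth`).
#' @param truth Truth tibble from [simulate_genome_annotation()] (used for
#'   the default `risk_genes`).
#' @return Tibble: `sample_id`, `time`, `event` (1 event / 0 censored),
#'   `value` (the risk covariate).
#' @export
simulate_survival <- function(expr, config, risk_genes = NULL, truth = NULL) {
  stopifnot(inherits(expr, "pg_expr"), inherits(config, "sim_config"))
  if (is.null(risk_genes)) {
    if (is.null(truth)) stop("supply risk_genes or truth")
    risk_genes <- truth$gene_id[truth$risk_gene]
  }
  with_substream(config$seed, "survival", {
    tum <- expr$samples$sample_id[expr$samples$condition == "tumour"]
    cpm <- normalize_cpm(expr$counts[, tum, drop = FALSE])
    z <- log2(cpm[risk_genes, , drop = FALSE] + 1)
    z <- if (length(risk_genes)) rowMeans(scale(t(z))) else rep(0, length(tum))
    z[!is.finite(z)] <- 0

    lambda0 <- 0.1
    rate <- lambda0 * exp(config$survival_beta * z)
    t_event <- rexp(length(rate), rate)
    cf <- config$censor_fraction
    if (cf > 0) {
      ## P(censored) = P(C < T) under C ~ U(0, cmax):
      ## (1 - exp(-r cmax)) / (r cmax), averaged over the samples' rates
      f <- function(cmax) {
        mean((1 - exp(-rate * cmax)) / (rate * cmax)) - cf
      }
      cmax <- uniroot(f, c(1e-6, 1e6))$root
      cens <- runif(length(rate), 0, cmax)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    } else {
      event <- rep(1L, length(rate))
      time <- t_event
    }
    tibble(sample_id = tum, time = time, event = event, value = z)
  })
}

#' Simulate mutation and CNV matrices
#'
#' Bernoulli mutation calls and sparse integer CNV states in `{-2..2}`.
#' The planted driver gene is kept alteration-free so it survives the
#' genetic-confound filter.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @param config A [sim_config()].
#' @return List with `mutation` and `cnv` (genes x samples integer matrices).
#' @export
simulate_genetics <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "genetics", {
    ids <- sim$truth$gene_id
    n <- length(ids); ns <- config$n_genetic_samples
    smp <- sprintf("GS%03d", seq_len(ns))
    mut <- matrix(rbinom(n * ns, 1, config$mutation_rate), n, ns,
                  dimnames = list(ids, smp))
    cnv <- matrix(0L, n, ns, dimnames = list(ids, smp))
    hit <- matrix(rbinom(n * ns, 1, config$cnv_rate) == 1, n, ns)
    cnv[hit] <- sample(c(-2L, -1L, 1L, 2L), sum(hit), replace = TRUE)
    driver <- ids[sim$truth$is_driver]
    if (length(driver)) {
      mut[driver, ] <- 0L
      cnv[driver, ] <- 0L
    }
    list(mutation = mut, cnv = cnv)
  })
}

#' Simulate a complete multi-omics cohort
#'
#' Convenience wrapper chaining all generators off one master seed:
#' annotation + genome, MeRIP window counts for both conditions, expression
#' (with m6A coupling from the planted methylation states), survival and
#' genetic matrices, plus a small miRNA set containing one miRNA whose seed
#' matches the site planted in the driver pseudogene and its parent.
#'
#' @param config A [sim_config()].
#' @return A named list with every simulated layer and the planted truth.
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_genome_annotation(config)
  merip <- simulate_merip(sim, config)
  ## gene-level planted m6A levels used for the expression coupling:
  ## log2 enrichment ~ log2(fold) for methylated genes, 0 otherwise
  m6a_levels <- sim$truth |>
    mutate(level = if_else(.data$methylated,
                           log2(config$peak_enrichment_fold), 0)) |>
    select("gene_id", "level")
  expr <- simulate_expression(sim, config, m6a_levels = m6a_levels)
  surv <- simulate_survival(expr, config, truth = sim$truth)
  genetics <- simulate_genetics(sim, config)
  mirnas <- with_substream(config$seed, "mirnas", {
    ids <- sprintf("mir%02d", 1:10)
    seqs <- vapply(ids, function(i) {
      chartr("T", "U", random_dna(22))
    }, character(1))
    ## mirna 1 gets the miR-96-3p-like seed whose 6mer site is UUGGCA
    substr(seqs[1], 2, 7) <- "UGCCAA"
    tibble(mirna_id = ids, sequence = unname(seqs))
  })
  list(config = config, catalog = sim$catalog, genome = sim$genome,
       truth = sim$truth, meth_windows = sim$meth_windows, merip = merip,
       expression = expr, survival = surv, genetics = genetics,
       mirnas = mirnas)
}
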