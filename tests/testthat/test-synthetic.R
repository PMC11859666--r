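test_that("generator respects the configuration and is seed-deterministic", {
  cfg <- sim_config(n_genes = 100, pseudogene_fraction = 0.5, seed = 5)
  sim1 <- simulate_genome_annotation(cfg)
  expect_equal(sum(sim1$truth$is_pseudogene), 50)
  expect_equal(sort(unique(na.omit(sim1$truth$subtype))),
               sort(intersect(c("processed", "unprocessed", "unitary",
                                "polymorphic"),
                              unique(sim1$truth$subtype))))

  sim2 <- simulate_genome_annotation(cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$catalog$genes, sim2$catalog$genes)
  expect_identical(sim1$truth, sim2$truth)

  ## different seed, different output
  sim3 <- simulate_genome_annotation(sim_config(n_genes = 100, seed = 6))
  expect_false(identical(sim1$genome, sim3$genome))

  expect_error(simulate_genome_annotation(sim_config(n_genes = 1)))
})

test_that("every planted methylation site carries the planted motif", {
  cfg <- sim_config(n_genes = 60, seed = 11)
  sim <- simulate_genome_annotation(cfg)
  for (i in seq_len(nrow(sim$meth_windows))) {
    w <- sim$meth_windows[i, ]
    seq <- peak_sequences(w, sim$genome)
    expect_true(grepl(cfg$planted_motif, seq),
                info = paste("window of", w$gene_id))
  }
})

test_that("MeRIP counts are deterministic, integer, with library sums", {
  cfg <- sim_config(n_genes = 40, seed = 8)
  sim <- simulate_genome_annotation(cfg)
  wc1 <- simulate_merip(sim, cfg)
  wc2 <- simulate_merip(sim, cfg)
  expect_identical(wc1$counts, wc2$counts)
  expect_true(all(wc1$counts$count >= 0))
  libs <- wc1$counts |>
    dplyr::group_by(sample) |>
    dplyr::summarise(n = sum(count))
  expect_equal(sort(libs$n),
               sort(wc1$lib_sizes$lib_size))
})

test_that("realized IP enrichment at planted windows tracks the configured fold", {
  folds <- purrr::map_dbl(1:25, function(s) {
    cfg <- sim_config(n_genes = 25, seed = 100 + s, fraction_hyper = 0,
                      fraction_hypo = 0, plant_driver = FALSE)
    sim <- simulate_genome_annotation(cfg)
    wc <- simulate_merip(sim, cfg)
    pooled <- pseudom6a:::pool_condition(wc, "tumour")
    mw <- sim$meth_windows
    on <- dplyr::semi_join(pooled, mw, by = c("gene_id", "start", "end"))
    off <- dplyr::anti_join(
      dplyr::semi_join(pooled, mw, by = "gene_id"), mw,
      by = c("gene_id", "start", "end"))
    (sum(on$IP) / sum(on$input)) / (sum(off$IP) / sum(off$input))
  })
  expect_lt(abs(mean(folds) - 4) / 4, 0.15)

  ## with fold 1 the planted windows behave like background
  cfg0 <- sim_config(n_genes = 40, seed = 3, peak_enrichment_fold = 1,
                     plant_driver = FALSE)
  sim0 <- simulate_genome_annotation(cfg0)
  wc0 <- simulate_merip(sim0, cfg0)
  pooled0 <- pseudom6a:::pool_condition(wc0, "tumour")
  on0 <- dplyr::semi_join(pooled0, sim0$meth_windows,
                          by = c("gene_id", "start", "end"))
  ratio <- (sum(on0$IP) / sum(on0$input)) /
    (sum(pooled0$IP) / sum(pooled0$input))
  expect_lt(abs(log2(ratio)), 0.5)
})

test_that("expression generator plants fold changes and pair coupling", {
  cfg <- sim_config(n_genes = 200, seed = 21, de_log2fc = 2,
                    n_expr = c(tumour = 20, normal = 20),
                    m6a_expression_gamma = 0)
  sim <- simulate_genome_annotation(cfg)
  ex <- simulate_expression(sim, cfg)
  expect_identical(ex$counts, simulate_expression(sim, cfg)$counts)
  expect_true(all(ex$counts >= 0))

  cpm <- normalize_cpm(ex$counts)
  tum <- ex$samples$condition == "tumour"
  lfc <- log2((rowMeans(cpm[, tum]) + 1) / (rowMeans(cpm[, !tum]) + 1))
  up <- sim$truth$gene_id[sim$truth$de_status == "up"]
  dn <- sim$truth$gene_id[sim$truth$de_status == "down"]
  expect_lt(abs(mean(lfc[up]) - 2), 0.2)
  expect_lt(abs(mean(lfc[dn]) + 2), 0.2)

  ## rho = 0: pair Spearman distribution centred at zero
  cfg0 <- sim_config(n_genes = 1000, seed = 22, cerna_coupling_rho = 0,
                     de_fraction = 0, plant_driver = FALSE,
                     n_expr = c(tumour = 30, normal = 5))
  sim0 <- simulate_genome_annotation(cfg0)
  ex0 <- simulate_expression(sim0, cfg0)
  tum0 <- ex0$samples$sample_id[ex0$samples$condition == "tumour"]
  cr <- spearman_pairs(ex0, sim0$catalog$pairs, samples = tum0)
  expect_gt(nrow(cr), 400)
  expect_lt(abs(mean(cr$rho, na.rm = TRUE)), 0.05)
})

test_that("survival generator honours the null, the hazard and censoring", {
  cfg <- sim_config(n_genes = 20, seed = 31, survival_beta = 0,
                    n_expr = c(tumour = 500, normal = 5),
                    censor_fraction = 0.2)
  sim <- simulate_genome_annotation(cfg)
  ex <- simulate_expression(sim, cfg)
  sv <- simulate_survival(ex, cfg, truth = sim$truth)
  expect_identical(sv, simulate_survival(ex, cfg, truth = sim$truth))
  expect_equal(nrow(sv), 500)
  ## realized censoring within 5 points of the configured fraction
  expect_lt(abs(mean(1 - sv$event) - 0.2), 0.05)
  ## beta = 0 truth: fitted |log HR| small
  cx <- cox_univariate(sv)
  expect_lt(abs(cx$beta), 0.15)
})

test_that("genetic matrices have configured rates and an unaltered driver", {
  cfg <- sim_config(n_genes = 60, seed = 41, mutation_rate = 0,
                    cnv_rate = 0)
  sim <- simulate_genome_annotation(cfg)
  g0 <- simulate_genetics(sim, cfg)
  expect_true(all(g0$mutation == 0))
  expect_true(all(g0$cnv == 0))

  cfg2 <- sim_config(n_genes = 200, seed = 42, mutation_rate = 0.06,
                     n_genetic_samples = 100, plant_driver = FALSE)
  sim2 <- simulate_genome_annotation(cfg2)
  g2 <- simulate_genetics(sim2, cfg2)
  expect_identical(g2, simulate_genetics(sim2, cfg2))
  freq <- rowMeans(g2$mutation)
  ## per-gene frequencies inside the binomial 95% envelope around 6%
  ci <- qbinom(c(0.0005, 0.9995), 100, 0.06) / 100
  expect_gt(mean(freq >= ci[1] & freq <= ci[2]), 0.95)
  expect_lt(abs(mean(freq) - 0.06), 0.01)

  cfg3 <- sim_config(n_genes = 60, seed = 43)
  sim3 <- simulate_genome_annotation(cfg3)
  g3 <- simulate_genetics(sim3, cfg3)
  drv <- sim3$truth$gene_id[sim3$truth$is_driver]
  expect_true(all(g3$mutation[drv, ] == 0))
  expect_true(all(g3$cnv[drv, ] == 0))
})
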