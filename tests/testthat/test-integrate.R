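test_that("CPM normalization is exact and scale-invariant", {
  m <- matrix(c(10), 1, 1, dimnames = list("g", "s"))
  expect_equal(normalize_cpm(m)[1, 1], 1e6)

  m2 <- matrix(c(3, 7, 10, 30), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- normalize_cpm(m2)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(unname(cpm[, 1]), c(3, 7) / 10 * 1e6)
  expect_equal(normalize_cpm(m2 * 2)[, 1], cpm[, 1])

  m2[, 2] <- 0
  expect_error(normalize_cpm(m2), "zero-depth")
})

test_that("element-wise identical groups give exactly zero fold change", {
  set.seed(20)
  cnt <- matrix(rnbinom(50 * 4, mu = 50, size = 10), 50, 4)
  cnt <- cbind(cnt, cnt)
  rownames(cnt) <- paste0("g", 1:50)
  colnames(cnt) <- paste0("s", 1:8)
  de <- differential_expression(
    cnt, condition = rep(c("tumour", "normal"), each = 4))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$direction == "ns"))

  ## an all-zero gene is ns with zero fold change
  cnt[1, ] <- 0
  de2 <- differential_expression(
    cnt, condition = rep(c("tumour", "normal"), each = 4))
  expect_equal(unname(de2$log2fc[de2$gene_id == "g1"]), 0)
  expect_equal(de2$direction[de2$gene_id == "g1"], "ns")
})

test_that("DE test is calibrated on null NB data and powered for 4-fold", {
  set.seed(21)
  n <- 1200; nt <- 10; nn <- 10
  mu <- exp(rnorm(n, log(100), 1))
  cnt <- cbind(matrix(rnbinom(n * nt, mu = mu, size = 10), n),
               matrix(rnbinom(n * nn, mu = mu, size = 10), n))
  dimnames(cnt) <- list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:(nt + nn)))
  de <- differential_expression(
    cnt, condition = rep(c("tumour", "normal"), c(nt, nn)))
  frac <- mean(de$p_value < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])

  idx <- 1:60
  cnt2 <- cnt
  cnt2[idx, 1:nt] <- matrix(rnbinom(60 * nt, mu = mu[idx] * 4, size = 10),
                            60)
  de2 <- differential_expression(
    cnt2, condition = rep(c("tumour", "normal"), c(nt, nn)))
  expect_gte(mean(de2$q_value[idx] < 0.05 & de2$log2fc[idx] > 0), 0.9)
})

test_that("Spearman pair classification matches the rank-formula oracle", {
  set.seed(22)
  cnt <- matrix(rpois(4 * 8, 100), 4, 8,
                dimnames = list(c("p1", "p2", "p3", "g1"),
                                paste0("s", 1:8)))
  cnt["p1", ] <- 1:8 * 10          # strictly increasing with g1
  cnt["g1", ] <- (1:8)^2
  pairs <- tibble::tibble(pseudogene_id = c("p1", "p2"),
                          parent_gene_id = c("g1", "g1"))
  cr <- spearman_pairs(cnt, pairs)
  expect_equal(cr$rho[1], 1)
  expect_equal(cr$sign_class[1], "Positive")

  ## toy vectors vs the brute-force rank formula
  for (i in 1:20) {
    x <- sample(1:40, 6); y <- sample(1:40, 6)
    lgx <- log2(normalize_cpm(rbind(x, y,
                                    matrix(100, 2, 6,
                                           dimnames = list(c("a", "b"),
                                                           NULL)))) + 1)
    cr2 <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(unname(cr2$estimate), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }

  ## a constant analyzed vector is degenerate: class No, rho missing
  ## (equal column totals make the CPM of the constant row constant too)
  p1v <- 1:8 * 10
  cnt2 <- rbind(p1 = p1v, g1 = rep(50L, 8),
                filler = 1000L - p1v - 50L)
  colnames(cnt2) <- paste0("s", 1:8)
  cr3 <- spearman_pairs(cnt2, pairs[1, ])
  expect_equal(cr3$sign_class, "No")
  expect_true(is.na(cr3$rho))
})

test_that("sign classes follow the rho/p rule", {
  n <- 40
  p1v <- 1:n * 10L
  g1v <- as.integer((1:n)^2)
  g2v <- (n:1) * 10L
  g3v <- rep(c(100L, 200L), n / 2)          # rank-uncorrelated with p1
  filler <- 100000L - p1v - g1v - g2v - g3v # equal totals preserve ranks
  cnt <- rbind(p1 = p1v, g1 = g1v, g2 = g2v, g3 = g3v, filler = filler)
  colnames(cnt) <- paste0("s", 1:n)
  pairs <- tibble::tibble(pseudogene_id = "p1",
                          parent_gene_id = c("g1", "g2", "g3"))
  cr <- suppressWarnings(spearman_pairs(cnt, pairs))
  expect_equal(cr$sign_class, c("Positive", "Negative", "No"))
})

test_that("tristile integration recovers the planted m6A-expression coupling", {
  cfg <- sim_config(n_genes = 300, seed = 7, m6a_expression_gamma = 0.5)
  sim <- simulate_genome_annotation(cfg)
  wc <- simulate_merip(sim, cfg)
  pk <- call_peaks(wc, "tumour")
  lv <- gene_m6a_level(wc, pk, "tumour")
  ex <- simulate_expression(sim, cfg,
                            m6a_levels = lv[, c("gene_id", "level")])
  tri <- suppressWarnings(tristile_integration(lv, ex))

  med <- tri$gene_values |>
    dplyr::group_by(tertile) |>
    dplyr::summarise(m = median(expression))
  expect_gt(med$m[med$tertile == "low"], med$m[med$tertile == "high"])
  p_lh <- tri$tests$p_value[tri$tests$group1 == "low" &
                              tri$tests$group2 == "high"]
  expect_lt(p_lh, 0.05)

  ## the CDF reaches 1 at the top of the grid for every tertile
  top <- tri$cdf |>
    dplyr::group_by(tertile) |>
    dplyr::summarise(endpoint = cdf[which.max(expression)])
  expect_true(all(top$endpoint == 1))

  ## every gene sits in exactly one tertile
  expect_equal(nrow(tri$gene_values),
               dplyr::n_distinct(tri$gene_values$gene_id))
})

test_that("small tertiles are skipped and flagged", {
  lv <- tibble::tibble(gene_id = paste0("g", 1:4),
                       tertile = c("low", "low", "median", "high"),
                       level = 1:4)
  cnt <- matrix(rpois(4 * 10, 50), 4, 10,
                dimnames = list(lv$gene_id, paste0("s", 1:10)))
  ex <- structure(list(counts = cnt,
                       samples = tibble::tibble(
                         sample_id = paste0("s", 1:10),
                         condition = rep("tumour", 10))),
                  class = "pg_expr")
  tri <- tristile_integration(lv, ex)
  expect_true(all(tri$tests$skipped))
})

test_that("stratified correlation detects planted attenuation by m6A level", {
  cfg <- sim_config(n_genes = 300, seed = 7, m6a_expression_gamma = 0,
                    cerna_m6a_attenuation = 0.9)
  sim <- simulate_genome_annotation(cfg)
  wc <- simulate_merip(sim, cfg)
  lv <- gene_m6a_level(wc, call_peaks(wc, "tumour"), "tumour")
  ex <- simulate_expression(sim, cfg,
                            m6a_levels = lv[, c("gene_id", "level")])
  tum <- ex$samples$sample_id[ex$samples$condition == "tumour"]
  cr <- spearman_pairs(ex, sim$catalog$pairs, samples = tum)
  st <- correlation_by_m6a_strata(
    cr, lv, subtype_table = sim$catalog$genes[, c("gene_id", "subtype")])
  pr <- st$summary[st$summary$subtype == "processed", ]
  expect_gt(pr$mean_rho[pr$tertile == "low"],
            pr$mean_rho[pr$tertile == "high"])

  ## Wilcoxon on small rho sets equals exhaustive rank-sum enumeration
  set.seed(30)
  for (i in 1:10) {
    a <- runif(6); b <- runif(5)
    expect_equal(wilcox.test(a, b)$p.value, oracle_wilcoxon(a, b),
                 tolerance = 1e-10)
  }
})

test_that("correspondence tables reproduce the Sankey-style contrast", {
  fa <- rep(c("m6A+", "m6A-"), c(1000, 1000))
  fb <- c(rep(c("parent+", "parent-"), c(579, 421)),
          rep(c("parent+", "parent-"), c(403, 597)))
  ct <- correspondence_tables(fa, fb)
  props <- ct$row_proportions[, "parent+"]
  expect_equal(unname(props["m6A+"]), 0.579)
  expect_equal(unname(props["m6A-"]), 0.403)
  expect_lt(ct$test$p_value, 0.001)

  ## independence-generated table: odds ratio near 1, p large
  set.seed(31)
  a2 <- sample(c("x", "y"), 2000, TRUE)
  b2 <- sample(c("u", "v"), 2000, TRUE)
  ct2 <- correspondence_tables(a2, b2)
  or <- (ct2$table[1, 1] * ct2$table[2, 2]) /
    (ct2$table[1, 2] * ct2$table[2, 1])
  expect_lt(abs(log(or)), 0.3)

  expect_error(correspondence_tables(rep("x", 10), rep(c("u", "v"), 5)),
               "levels")
  ## small expected cells fall back to Fisher's exact test
  ct3 <- correspondence_tables(rep(c("x", "y"), c(4, 4)),
                               c("u", "u", "u", "v", "v", "v", "v", "u"))
  expect_equal(ct3$test$method, "fisher")
})

test_that("genetic summaries compute frequencies and CNV-expression rho", {
  mut <- matrix(0L, 2, 50, dimnames = list(c("g1", "g2"),
                                           paste0("s", 1:50)))
  cnv <- mut
  mut["g1", 1:3] <- 1L
  gs <- genetic_summary(mut, cnv)
  expect_equal(unname(gs$mutation_frequency), c(0.06, 0))
  expect_equal(unname(gs$cnv_frequency), c(0, 0))

  ## CNV states perfectly ordered with expression give rho 1
  cnv["g2", ] <- rep(c(-2L, -1L, 0L, 1L, 2L), each = 10)
  expr <- matrix(rep(c(10, 20, 40, 80, 160), each = 10), 2, 50,
                 byrow = TRUE, dimnames = dimnames(mut))
  expr["g1", ] <- 100
  gs2 <- genetic_summary(mut, cnv, expr = expr)
  expect_equal(gs2$cnv_expression_rho[gs2$gene_id == "g2"], 1)

  colnames(expr) <- paste0("zz", 1:50)
  expect_error(genetic_summary(mut, cnv, expr = expr), "disjoint")
})
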