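test_that("window tiling follows the (size, step) rule with partial-window cut", {
  cat <- toy_catalog()
  ## restrict to a single 100-nt exon
  cat$genes <- cat$genes[1, ]; cat$genes$end <- 1100L
  cat$exons <- cat$exons[1, ]; cat$exons$end <- 1100L
  cat$cds <- cat$cds[0, ]
  tl <- window_tiling(cat, window_size = 50, step = 25)
  expect_equal(tl$start - 1000L, c(0L, 25L, 50L))
  expect_equal(tl$end - tl$start, c(50L, 50L, 50L))

  ## step = size gives a non-overlapping tiling
  tl2 <- window_tiling(cat, window_size = 50, step = 50)
  expect_equal(tl2$start - 1000L, c(0L, 50L))
  expect_true(all(tl2$start[-1] >= head(tl2$end, -1)))
})

test_that("coverage is summed into windows and empty coverage yields none", {
  cat <- toy_catalog()
  cat$genes <- cat$genes[1, ]; cat$genes$end <- 1100L
  cat$exons <- cat$exons[1, ]; cat$exons$end <- 1100L
  cat$cds <- cat$cds[0, ]
  cov <- tibble::tibble(sample = "s1", assay = "IP", condition = "tumour",
                        chrom = "chr1", start = 1000L, end = 1050L,
                        value = 2)
  wc <- count_windows(cov, cat, window_size = 50, step = 50)
  cnt <- wc$counts[wc$counts$assay == "IP", ]
  expect_equal(cnt$count, c(100L, 0L))

  wc0 <- count_windows(cov[0, ], cat)
  expect_equal(nrow(wc0$counts), 0)
})

test_that("window exact test matches the hypergeometric tail-sum oracle", {
  ## the spec's worked window: ip 50 of 1000 vs input 10 of 1000
  p <- pseudom6a:::hyper_p_greater(50, 950, 10, 990)
  expect_equal(p, oracle_hyper_tail(50, 950, 10, 990), tolerance = 1e-12)
  expect_lt(p, 0.05)

  set.seed(7)
  for (i in 1:200) {
    tot <- sample(4:200, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    expect_equal(pseudom6a:::hyper_p_greater(a, b, c, d),
                 oracle_hyper_tail(a, b, c, d), tolerance = 1e-10,
                 info = paste(a, b, c, d))
  }
})

test_that("null IP/input proportions produce no peaks", {
  wc <- toy_windowcounts(ip = rep(100L, 12), input = rep(100L, 12))
  expect_equal(nrow(call_peaks(wc, "tumour")), 0)
})

test_that("adjacent significant windows merge into a single peak", {
  ip <- c(rep(10L, 4), 400L, 400L, rep(10L, 4))
  input <- rep(10L, 10)
  wc <- toy_windowcounts(ip, input, step = 50L)
  pk <- call_peaks(wc, "tumour", step = 50L)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(200L, 300L))
  expect_equal(pk$n_windows, 2L)
  expect_gt(pk$log2_enrichment, 0)
})

test_that("an all-zero input library is an error", {
  wc <- toy_windowcounts(ip = rep(10L, 4), input = rep(0L, 4))
  expect_error(call_peaks(wc, "tumour"), "input")
})

test_that("differential methylation reproduces the worked 2x2 example", {
  ## one strongly tumour-enriched peak over a flat background, so library
  ## scaling is mild and the 80/20-vs-20/80 style contrast survives
  bg <- rep(100L, 20)
  wc_t <- toy_windowcounts(c(bg, 400L), c(bg, 100L),
                           condition = "tumour", step = 50L)
  wc_n <- toy_windowcounts(c(bg, 100L), c(bg, 400L),
                           condition = "normal", step = 50L)
  wc <- structure(
    list(counts = dplyr::bind_rows(wc_t$counts, wc_n$counts),
         lib_sizes = dplyr::bind_rows(wc_t$lib_sizes, wc_n$lib_sizes)),
    class = "pg_windowcounts")
  pk <- dplyr::bind_rows(call_peaks(wc, "tumour", step = 50L),
                         call_peaks(wc, "normal", step = 50L))
  dm <- diff_methylation(wc, wc, pk)
  expect_equal(nrow(dm), 1)
  expect_equal(dm$direction, "hyper")
  expect_lt(dm$p_value, 0.001)
  ## direct check of the 2x2 mechanics on the spec's numbers
  m <- matrix(c(80, 20, 20, 80), 2)
  expect_equal((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]), 16)
  expect_equal(fisher.test(m)$p.value,
               oracle_fisher_two_sided(80, 20, 20, 80), tolerance = 1e-9)
})

test_that("identical condition tables give zero fold change and p = 1", {
  ip <- c(5L, 200L, 5L); input <- c(5L, 50L, 5L)
  wc_t <- toy_windowcounts(ip, input, condition = "tumour", step = 50L)
  wc_n <- toy_windowcounts(ip, input, condition = "normal", step = 50L)
  wc <- structure(
    list(counts = dplyr::bind_rows(wc_t$counts, wc_n$counts),
         lib_sizes = dplyr::bind_rows(wc_t$lib_sizes, wc_n$lib_sizes)),
    class = "pg_windowcounts")
  pk <- call_peaks(wc, "tumour", step = 50L)
  dm <- diff_methylation(wc, wc, pk)
  expect_equal(dm$diff_log2fc, 0)
  expect_equal(dm$p_value, 1)
})

test_that("significance of differential peaks follows the raw p < .05 rule", {
  dm <- tibble::tibble(p_value = c(0.04, 0.06))
  expect_equal(dm$p_value < 0.05, c(TRUE, FALSE))
  ## and the full path flags accordingly on constructed strong/weak contrasts
  wc_t <- toy_windowcounts(c(5L, 300L, 5L), c(5L, 60L, 5L),
                           condition = "tumour", step = 50L)
  wc_n <- toy_windowcounts(c(5L, 60L, 5L), c(5L, 60L, 5L),
                           condition = "normal", step = 50L)
  wc <- structure(
    list(counts = dplyr::bind_rows(wc_t$counts, wc_n$counts),
         lib_sizes = dplyr::bind_rows(wc_t$lib_sizes, wc_n$lib_sizes)),
    class = "pg_windowcounts")
  pk <- call_peaks(wc, "tumour", step = 50L)
  dm2 <- diff_methylation(wc, wc, pk)
  expect_equal(dm2$significant, dm2$p_value < 0.05)
})

test_that("gene m6A level follows the CPM pseudocount formula", {
  ## equal CPM -> level 0 (single gene; CPM is forced equal by pooling)
  wc <- toy_windowcounts(ip = c(40L, 40L), input = c(40L, 40L))
  lv <- gene_m6a_level(wc, pseudom6a:::empty_peaks(), "tumour")
  expect_equal(lv$level, 0)

  ## the closed form: IP CPM 40, input CPM 10, alpha 1 -> log2(41/11)
  expect_equal(log2((40 + 1) / (10 + 1)), 1.898, tolerance = 1e-3)
})

test_that("tertile cut is a 3/3/3 partition in rank order for 9 genes", {
  set.seed(2)
  base <- toy_windowcounts(ip = rep(10L, 2), input = rep(10L, 2))
  counts <- purrr::map_dfr(1:9, function(g) {
    ## IP share grows quadratically, input linearly -> strictly increasing
    ## IP/input ratio across genes
    dplyr::mutate(base$counts, gene_id = paste0("g", g),
                  count = ifelse(assay == "IP", .env$g^2 * 5L,
                                 .env$g * 10L))
  })
  libs <- counts |>
    dplyr::group_by(sample, assay, condition) |>
    dplyr::summarise(lib_size = sum(count), .groups = "drop")
  wc <- structure(list(counts = counts, lib_sizes = libs),
                  class = "pg_windowcounts")
  lv <- gene_m6a_level(wc, pseudom6a:::empty_peaks(), "tumour")
  expect_equal(as.integer(table(lv$tertile)[c("low", "median", "high")]),
               c(3L, 3L, 3L))
  ord <- lv[order(lv$level), ]
  expect_equal(ord$tertile, rep(c("low", "median", "high"), each = 3))
  ## a partition: every gene in exactly one tertile
  expect_equal(sort(unique(lv$tertile)), c("high", "low", "median"))
  expect_equal(nrow(lv), 9)
})
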