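test_that("median-ratio size factors behave under scaling", {
  set.seed(1)
  base <- matrix(rpois(400, 100), 200, 2,
                 dimnames = list(sprintf("g%03d", 1:200), c("a", "b")))
  base[, 2] <- base[, 1]
  nr <- normalize_counts(base)
  expect_equal(nr$size_factors[["a"]], nr$size_factors[["b"]])
  expect_equal(nr$normalized[, "a"], nr$normalized[, "b"])

  doubled <- base
  doubled[, 2] <- 2L * base[, 1]
  nr2 <- normalize_counts(doubled)
  expect_equal(unname(nr2$size_factors[["b"]] / nr2$size_factors[["a"]]), 2)
  expect_equal(nr2$normalized[, "a"], nr2$normalized[, "b"])
})

test_that("size factors recover known depth ratios on simulated counts", {
  cfg <- small_cfg(n_genes = 100, seed = 31, depth = 800,
                   nb_dispersion = 0.01)
  lib <- simulate_library(cfg)
  sim <- simulate_screen_counts(lib, simulate_sample_sheet(cfg), cfg)
  mat <- sim$counts$counts[, 1:3]
  mat[, 2] <- 3L * mat[, 2]          # exact 3x depth on sample 2
  nr <- normalize_counts(mat)
  expect_equal(nr$method_used, "median-ratio")
  ratio <- nr$size_factors[2] / nr$size_factors[1]
  expect_lt(abs(ratio / 3 - 1), 0.02)
})

test_that("median-ratio agrees with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  cfg <- small_cfg(seed = 8)
  lib <- simulate_library(cfg)
  sim <- simulate_screen_counts(lib, simulate_sample_sheet(cfg), cfg)
  mat <- sim$counts$counts
  ours <- normalize_counts(mat)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("tiny matrices fall back to total-count scaling; all-zero samples error", {
  m <- matrix(c(10L, 20L, 5L, 10L), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  nr <- normalize_counts(m)
  expect_equal(nr$method_used, "total")
  z <- m; z[, 2] <- 0L
  expect_error(normalize_counts(z), "all-zero sample")
})

test_that("guide LFC and the low-count rule follow the <5-in-both-arms truth table", {
  lib <- guide_library(sprintf("g%d", 1:4), rep("A", 4), rep("targeting", 4))
  sheet <- validate_sample_sheet(data.frame(
    sample_id = c("L1_v", "L1_d"), cell_line = "L1",
    condition = c("vehicle", "drug"), drug = c("", "dox"),
    group = "case", drug_class = "dna_damage"))
  # per guide: (vehicle, drug) raw counts and the expected flag
  vehicle <- c(4L, 500L, 3L, 600L)
  drug    <- c(3L, 3L, 500L, 500L)
  m <- cbind(L1_v = vehicle, L1_d = drug)
  rownames(m) <- lib$guide_id
  sc <- screen_counts(m, library = lib)
  gfc <- guide_lfc(sc, sheet, lib, norm = list(normalized = m), min_count = 5)
  expect_identical(gfc$flag, c("low_count", "kept", "kept", "kept"))
  # equal normalized counts give exactly zero LFC
  eq <- matrix(50L, 4, 2, dimnames = dimnames(m))
  gfc0 <- guide_lfc(screen_counts(eq, library = lib), sheet, lib,
                    norm = list(normalized = eq))
  expect_true(all(gfc0$lfc == 0))
})

test_that("Dixon flags the worked opposite-sign outlier and respects directionality", {
  x <- c(0.10, 0.12, 0.09, 0.11, 0.10, -1.50)
  tst <- dixon_q_test(x)
  expect_equal(tst$statistic, (0.09 - (-1.50)) / (0.12 - (-1.50)),
               tolerance = 1e-12)   # Q = 0.981...
  expect_lt(tst$p.value, 0.05)
  expect_identical(which(dixon_filter(x)), 6L)
  # same magnitude but same sign as the rest: never flagged
  expect_false(any(dixon_filter(c(0.10, 0.12, 0.09, 0.11, 0.10, 1.50))))
  # degenerate: zero range
  expect_false(any(dixon_filter(rep(0.3, 6))))
  # too few observations: kept, no test
  expect_false(any(dixon_filter(c(-1, 5))))
})

test_that("Dixon flags at most one guide and never when all signs agree", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    x <- rnorm(n, sd = 0.3) + sample(c(-4, 0, 4), 1) * (runif(1) < 0.2) *
      (seq_len(n) == 1)
    fl <- dixon_filter(x)
    expect_lte(sum(fl), 1L)
    if (all(sign(x) >= 0) || all(sign(x) <= 0)) expect_false(any(fl))
  }
})

test_that("filtering order is low-count first, then Dixon, then aggregation", {
  lib <- guide_library(sprintf("g%d", 1:6), rep("A", 6), rep("targeting", 6))
  gfc <- data.frame(guide_id = lib$guide_id, gene = "A", category = "targeting",
                    cell_line = "L1", drug = "dox",
                    lfc = c(0.10, 0.12, 0.09, 0.11, 0.10, -1.50),
                    flag = c("kept", "kept", "kept", "kept", "kept", "low_count"),
                    stringsAsFactors = FALSE)
  # the extreme guide is already low_count: by default Dixon never sees it
  out <- filter_guides(gfc)
  expect_identical(out$flag[6], "low_count")
  expect_true(all(out$flag[1:5] == "kept"))
  # with dixon_first the test sees all guides and flags the extreme instead
  out2 <- filter_guides(gfc, dixon_first = TRUE)
  expect_identical(out2$flag[6], "dixon_outlier")
})

test_that("gene aggregation produces the documented mean and squared SE", {
  gfc <- data.frame(guide_id = c("a", "b", "c", "d", "e"),
                    gene = c("G1", "G1", "G1", "G2", "G2"),
                    category = "targeting", cell_line = "L", drug = "d",
                    lfc = c(-1, -1, -1, 0, 2), flag = "kept",
                    stringsAsFactors = FALSE)
  agg <- aggregate_gene(gfc)
  g1 <- agg[agg$gene == "G1", ]
  expect_equal(g1$y, -1)
  expect_equal(g1$se2, 0)
  g2 <- agg[agg$gene == "G2", ]
  expect_equal(g2$y, 1)
  expect_equal(g2$se2, 1)     # var({0,2}) = 2, /n = 1
  # singleton genes are dropped and reported
  gfc$flag[5] <- "dixon_outlier"
  agg2 <- aggregate_gene(gfc)
  expect_false("G2" %in% agg2$gene)
  expect_identical(attr(agg2, "dropped")$gene, "G2")
})

test_that("aggregated estimates recover a planted effect within sampling error", {
  lines <- sprintf("NB%02d", 1:4)
  cfg <- small_cfg(effect = planted_effect("GENE0003", lines), seed = 77)
  lib <- simulate_library(cfg)
  sheet <- simulate_sample_sheet(cfg)
  sim <- simulate_screen_counts(lib, sheet, cfg)
  gt <- preprocess_screen(sim$counts, sheet, lib)
  tgt <- gt[gt$gene == "GENE0003" & gt$cell_line %in% lines, ]
  expect_equal(nrow(tgt), 4L)
  for (r in seq_len(nrow(tgt)))
    expect_lt(abs(tgt$y[r] - (-1)), 3 * sqrt(tgt$se2[r]) + 0.25)
})
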