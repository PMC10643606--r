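# records builder for direct model-level tests (bypasses the count stage)
make_records <- function(y, x, se2, drug = "dox") {
  data.frame(gene = "G", cell_line = sprintf("L%02d", seq_along(y)),
             drug = drug, y = y, se2 = se2, n_guides = 6,
             stringsAsFactors = FALSE)
}
enc_for <- function(x) {
  e <- as.numeric(x)
  names(e) <- sprintf("L%02d", seq_along(x))
  e
}

test_that("a symmetric null gives alpha near 0 with p_nonzero near 0", {
  rec <- make_records(rep(0, 12), rep(0, 12), rep(1e-6, 12))
  spec <- fast_spec("overall", group_encoding = enc_for(rep(0, 12)), seed = 3)
  fit <- fit_gene(rec, spec)
  a <- fit[fit$parameter == "alpha", ]
  expect_lt(abs(a$mean), 0.01)
  expect_lt(a$p_nonzero, 0.25)
  expect_gt(a$p_neg, 0.3); expect_lt(a$p_neg, 0.7)
})

test_that("with negligible SE and large fixed df the fit matches OLS", {
  set.seed(14)
  x <- rep(c(0, 1), c(10, 8))
  y <- -1 + 0.5 * x + rnorm(18, 0, 0.2)
  rec <- make_records(y, x, rep(1e-8, 18))
  spec <- model_spec("per_drug", group_encoding = enc_for(x), seed = 5,
                     chains = 2, warmup = 1000, draws = 3000, adapt = 500,
                     nu_fixed = 1000)
  fit <- fit_gene(rec, spec)
  ols <- coef(lm(y ~ x))
  expect_lt(abs(fit$mean[fit$parameter == "alpha"] - ols[1]), 0.02)
  expect_lt(abs(fit$mean[fit$parameter == "beta"] - ols[2]), 0.02)
})

test_that("the t likelihood resists a single corrupted observation", {
  set.seed(8)
  x <- rep(c(0, 1), c(10, 8))
  y <- -1 + 0.5 * x + rnorm(18, 0, 0.1)
  y[4] <- 10                                  # gross corruption
  rec <- make_records(y, x, rep(0.01, 18))
  robust <- fit_gene(rec, fast_spec("per_drug", group_encoding = enc_for(x),
                                    seed = 6))
  gauss <- fit_gene(rec, fast_spec("per_drug", group_encoding = enc_for(x),
                                   seed = 6, nu_fixed = 1000))
  a_rob <- robust$mean[robust$parameter == "alpha"]
  a_gau <- gauss$mean[gauss$parameter == "alpha"]
  expect_lt(abs(a_rob - (-1)), abs(a_gau - (-1)))
  expect_lt(abs(a_rob - (-1)), 0.15)
})

test_that("credible intervals widen monotonically with measurement error", {
  set.seed(23)
  x <- rep(c(0, 1), c(6, 6))
  y <- -0.5 + 0.3 * x + rnorm(12, 0, 0.1)
  rec1 <- make_records(y, x, rep(0.01, 12))
  rec2 <- make_records(y, x, rep(1, 12))      # 100x inflated se2
  spec <- fast_spec("per_drug", group_encoding = enc_for(x), seed = 7)
  f1 <- fit_gene(rec1, spec)
  f2 <- fit_gene(rec2, spec)
  w <- function(f) {
    a <- f[f$parameter == "alpha", ]
    a$q97.5 - a$q2.5
  }
  expect_gt(w(f2), w(f1))
})

test_that("summaries are invariant to input row order under a fixed seed", {
  set.seed(30)
  x <- rep(c(0, 1), c(5, 5))
  rec <- make_records(-0.8 + 0.4 * x + rnorm(10, 0, 0.1), x, rep(0.02, 10))
  spec <- fast_spec("per_drug", group_encoding = enc_for(x), seed = 11)
  f1 <- fit_gene(rec, spec)
  perm <- rec[sample(nrow(rec)), ]
  f2 <- fit_gene(perm, spec)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("the joint hierarchy shrinks per-drug effects toward the shared mean", {
  set.seed(41)
  drugs <- c("dox", "cis", "eto")
  x <- rep(c(0, 1), c(6, 4))
  recs <- do.call(rbind, lapply(drugs, function(d) {
    r <- make_records(-1 + 0.5 * x + rnorm(10, 0, 0.25), x, rep(0.01, 10),
                      drug = d)
    r
  }))
  enc <- enc_for(x)
  joint <- fit_gene(recs, fast_spec("joint_shared", drugs = drugs,
                                    group_encoding = enc, seed = 12))
  mu <- joint$mean[joint$parameter == "mu_alpha"]
  shrink_ok <- vapply(drugs, function(d) {
    solo <- fit_gene(recs[recs$drug == d, ],
                     fast_spec("per_drug", group_encoding = enc, seed = 13))
    a_solo <- solo$mean[solo$parameter == "alpha"]
    a_joint <- joint$mean[joint$parameter == paste0("alpha.", d)]
    abs(a_joint - mu) <= abs(a_solo - mu) + 0.05
  }, logical(1))
  expect_true(all(shrink_ok))
  # shared effect near the common truth
  expect_lt(abs(mu - (-1)), 0.3)
})

test_that("fit_all handles empty tables, flags failures, and is deterministic", {
  empty <- data.frame(gene = character(0), cell_line = character(0),
                      drug = character(0), y = numeric(0), se2 = numeric(0))
  expect_equal(nrow(fit_all(empty, fast_spec("overall"))), 0L)

  set.seed(52)
  gt <- do.call(rbind, lapply(c("G1", "G2"), function(g)
    data.frame(gene = g, cell_line = sprintf("L%02d", 1:6), drug = "dox",
               y = rnorm(6, -0.5, 0.2), se2 = 0.02)))
  # G3 has too few records: must be flagged, not dropped
  gt <- rbind(gt, data.frame(gene = "G3", cell_line = "L01", drug = "dox",
                             y = 0, se2 = 0.01))
  spec <- fast_spec("overall", group_encoding = enc_for(rep(0, 6)), seed = 2)
  out <- fit_all(gt, spec)
  expect_equal(out$gene, c("G1", "G2", "G3"))
  expect_false(out$converged[out$gene == "G3"])
  expect_match(out$error[out$gene == "G3"], ">= 3 cell lines")
  out2 <- fit_all(gt[sample(nrow(gt)), ], spec)
  expect_equal(out, out2)
})

test_that("gene ranking orders effects and breaks ties by name", {
  sm <- data.frame(gene = c("B", "A", "C"),
                   alpha_mean = c(0, -2, 1),
                   alpha_p_nonzero = c(0.1, 0.99, 0.8))
  r <- rank_genes(sm, "sensitize", "mean_effect")
  expect_equal(r$gene, c("A", "B", "C"))
  expect_equal(rank_genes(sm, "resist", "mean_effect")$gene, c("C", "B", "A"))
  rp <- rank_genes(sm, "sensitize", "p_nonzero")
  expect_equal(rp$gene[1], "A")   # only negative-effect gene, high p_nonzero
  tie <- data.frame(gene = c("Z", "Y"), alpha_mean = c(-1, -1),
                    alpha_p_nonzero = c(0.9, 0.9))
  expect_equal(rank_genes(tie, "sensitize", "mean_effect")$gene, c("Y", "Z"))
})

test_that("selectivity table reports case potency and the sign-flipped differential", {
  sm <- data.frame(gene = c("G1", "G2"),
                   alpha_mean = c(-1, -0.2),
                   beta_mean = c(1, 0),
                   beta_p_nonzero = c(0.97, 0.05))
  st <- selectivity_table(sm)
  # beta = outgroup-minus-case LFC shift; +1 means the case group's fold
  # change is 1 unit lower (more sensitized) -> positive differential
  expect_equal(st$case_potency, c(-1, -0.2))
  expect_equal(st$differential, c(1, 0))
})

test_that("case-only sensitization yields a positive differential (and vice versa)", {
  set.seed(61)
  x <- rep(c(0, 1), c(8, 6))
  sel_diff <- function(y) {
    rec <- make_records(y, x, rep(0.01, 14))
    f <- fit_gene(rec, fast_spec("per_drug", group_encoding = enc_for(x),
                                 seed = 21))
    selectivity_table(data.frame(
      gene = "G", alpha_mean = f$mean[f$parameter == "alpha"],
      beta_mean = f$mean[f$parameter == "beta"],
      beta_p_nonzero = f$p_nonzero[f$parameter == "beta"]))$differential
  }
  # knockout sensitizes only the case group -> positive differential
  expect_gt(sel_diff(ifelse(x == 0, -1, 0) + rnorm(14, 0, 0.1)), 0.5)
  # only the outgroup -> negative differential
  expect_lt(sel_diff(ifelse(x == 1, -1, 0) + rnorm(14, 0, 0.1)), -0.5)
})
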