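#' Simulation studies validating the pipeline
#'
#' These functions run the package's standard self-checks: posterior
#' coverage of the measurement-error model, its least-squares limit, the
#' calibration of the empirical-null gene-set test, and end-to-end recovery
#' of planted sensitizers from a synthetic screen. They are the same
#' studies exercised by the test suite and the acceptance script.
#'
#' @name validation
NULL

#' @describeIn validation Generates replicate datasets from the
#'   measurement-error model itself (default truth: alpha = -1, beta = 0.5,
#'   sigma = 0.1, nu = 10, over 10 case + 8 outgroup cell lines with known
#'   per-observation standard errors) and reports the fraction of
#'   replicates whose 95% credible interval covers each true parameter.
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @param alpha,beta,sigma,nu true generative parameter values.
#' @param n_case,n_out cell lines per group.
#' @param chains,warmup,draws,adapt sampler settings per fit.
#' @export
recovery_study <- function(n_rep = 50, seed = 101, alpha = -1, beta = 0.5,
                           sigma = 0.1, nu = 10, n_case = 10, n_out = 8,
                           chains = 2, warmup = 500, draws = 1000,
                           adapt = 300) {
  n <- n_case + n_out
  x <- rep(c(0, 1), c(n_case, n_out))
  enc <- stats::setNames(x, sprintf("L%02d", seq_len(n)))
  cover_a <- cover_b <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seed + r)
    se2 <- stats::runif(n, 0.05, 0.15)^2
    y <- alpha + beta * x + sqrt(se2 + sigma^2) * stats::rt(n, df = nu)
    rec <- data.frame(gene = "G", cell_line = names(enc), drug = "drug",
                      y = y, se2 = se2, stringsAsFactors = FALSE)
    spec <- model_spec("per_drug", group_encoding = enc, chains = chains,
                       warmup = warmup, draws = draws, adapt = adapt,
                       seed = (seed + 17L * r) %% 2147483647L)
    f <- fit_gene(rec, spec)
    a <- f[f$parameter == "alpha", ]
    b <- f[f$parameter == "beta", ]
    cover_a[r] <- a$q2.5 <= alpha && alpha <= a$q97.5
    cover_b[r] <- b$q2.5 <= beta && beta <= b$q97.5
  }
  c(alpha = mean(cover_a), beta = mean(cover_b))
}

#' @describeIn validation With negligible measurement error and the t
#'   degrees of freedom held large, the posterior means of (alpha, beta)
#'   must agree with ordinary least squares; returns the absolute
#'   deviations.
#' @export
ols_limit_check <- function(seed = 14, n_case = 10, n_out = 8,
                            draws = 3000) {
  set.seed(seed)
  n <- n_case + n_out
  x <- rep(c(0, 1), c(n_case, n_out))
  y <- -1 + 0.5 * x + stats::rnorm(n, 0, 0.2)
  enc <- stats::setNames(x, sprintf("L%02d", seq_len(n)))
  rec <- data.frame(gene = "G", cell_line = names(enc), drug = "drug",
                    y = y, se2 = rep(1e-8, n), stringsAsFactors = FALSE)
  spec <- model_spec("per_drug", group_encoding = enc, chains = 2,
                     warmup = 1000, draws = draws, adapt = 500,
                     seed = seed, nu_fixed = 1000)
  f <- fit_gene(rec, spec)
  ols <- stats::coef(stats::lm(y ~ x))
  c(alpha = abs(f$mean[f$parameter == "alpha"] - unname(ols[1])),
    beta = abs(f$mean[f$parameter == "beta"] - unname(ols[2])))
}

#' @describeIn validation Simulates a null screen (non-targeting guides
#'   only, no planted effects), derives the 66 null pseudo-gene effects
#'   through the standard preprocessing path, then repeatedly tests random
#'   subsets of the null genes against the remainder; returns the fraction
#'   of draws rejected at \code{level} (which should be close to
#'   \code{level}).
#' @param n_draws number of random subset draws.
#' @param subset_size null genes per tested subset.
#' @param level nominal test level.
#' @export
null_calibration_study <- function(n_draws = 2000, subset_size = 20,
                                   level = 0.05, seed = 7) {
  cfg <- sim_config(n_genes = 2, guides_per_gene = 6, n_nontargeting = 400,
                    n_panessential_genes = 0, panessential_guides = 0,
                    n_case_lines = 6, n_outgroup_lines = 0,
                    drugs = c(drug = "other"), mean_depth = 500,
                    seed = seed)
  lib <- simulate_library(cfg)
  sheet <- simulate_sample_sheet(cfg)
  sim <- simulate_screen_counts(lib, sheet, cfg)
  ng <- build_null_genes(lib, seed = seed + 1L)
  gt <- preprocess_screen(sim$counts, sheet, lib, null_genes = ng)
  nt <- gt[grepl("^NTNULL", gt$gene), , drop = FALSE]
  effects <- tapply(nt$y, nt$gene, mean)
  effects <- stats::setNames(as.numeric(effects), names(effects))
  set.seed(seed + 2L)
  rej <- logical(n_draws)
  for (b in seq_len(n_draws)) {
    idx <- sample(length(effects), subset_size)
    p <- test_gene_set(names(effects)[idx], effects, effects[-idx],
                       min_overlap = 2L)$p
    rej[b] <- p < level
  }
  mean(rej)
}

#' @describeIn validation End-to-end recovery: simulates a screen with
#'   planted sensitizer genes (default 10 of 200 genes at delta = -1,
#'   depth 500x), runs preprocessing and the overall-effect model for every
#'   gene including the null pseudo-genes, and reports the fraction of
#'   planted genes whose sensitization evidence exceeds the null genes'
#'   95th percentile.
#' @param n_genes,n_planted,delta,depth screen-scale parameters.
#' @export
ranking_study <- function(n_genes = 200, n_planted = 10, delta = -1,
                          depth = 500, n_case = 6, seed = 19,
                          chains = 2, warmup = 400, draws = 800,
                          adapt = 300) {
  planted <- sprintf("GENE%04d", seq_len(n_planted))
  lines <- sprintf("NB%02d", seq_len(n_case))
  eff <- expand.grid(gene = planted, drug = "drug", cell_line = lines,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$delta <- delta
  cfg <- sim_config(n_genes = n_genes, guides_per_gene = 6,
                    n_nontargeting = 400, n_panessential_genes = 0,
                    panessential_guides = 0, n_case_lines = n_case,
                    n_outgroup_lines = 0, drugs = c(drug = "other"),
                    mean_depth = depth, effect_table = eff, seed = seed)
  lib <- simulate_library(cfg)
  sheet <- simulate_sample_sheet(cfg)
  sim <- simulate_screen_counts(lib, sheet, cfg)
  ng <- build_null_genes(lib, seed = seed + 1L)
  gt <- preprocess_screen(sim$counts, sheet, lib, null_genes = ng)
  spec <- model_spec("overall", group_encoding = encode_groups(sheet),
                     chains = chains, warmup = warmup, draws = draws,
                     adapt = adapt, seed = seed)
  sm <- fit_all(gt, spec, sheet = sheet)
  # sensitization evidence: p_nonzero signed by the effect direction
  score <- ifelse(sm$alpha_mean < 0, sm$alpha_p_nonzero, -sm$alpha_p_nonzero)
  null_scores <- score[grepl("^NTNULL", sm$gene)]
  thr <- stats::quantile(null_scores, 0.95, na.rm = TRUE)
  list(fraction_above = mean(score[sm$gene %in% planted] > thr),
       threshold = unname(thr),
       summaries = sm)
}
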