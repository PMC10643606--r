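#' Model specification for the hierarchical Bayesian sensitization model
#'
#' The likelihood is a Student-t measurement-error model on gene-level mean
#' log2 fold changes \code{y} with known squared standard errors \code{se2}:
#' \deqn{y_i \sim t(\nu, \alpha_{d_i} + \beta_{d_i} x_i,
#'   \sqrt{SE^2_{y_i} + \sigma^2_{d_i}})}
#' where \code{x} encodes case (0, e.g. neuroblastoma) vs outgroup (1), so
#' \code{alpha} is the sensitizing potency in the case group and \code{beta}
#' the outgroup-minus-case differential. Location parameters get weakly
#' informative N(0, sd 5) priors, scale parameters half-N(0, sd 5), and the
#' degrees of freedom nu ~ Gamma(2, 0.1), which keeps the fit robust to
#' occasional outlying fold changes.
#'
#' @param variant \code{"per_drug"} (single drug, alpha + beta directly),
#'   \code{"overall"} (single drug or pooled, alpha only — the "general
#'   sensitizing effect" sub-variant with no group term), or
#'   \code{"joint_shared"} (hierarchy across >= 2 drugs with shared
#'   \code{mu_alpha}, \code{mu_beta}).
#' @param drugs drugs in scope (required, length >= 2, for
#'   \code{joint_shared}; a single drug otherwise, NULL = use all present).
#' @param group_encoding named numeric vector mapping cell line to x in
#'   {0, 1}; default encodes \code{"case"} lines as 0 via the sample sheet.
#' @param chains,warmup,draws,adapt MCMC settings (defaults 4 x 1000 warmup
#'   + 1000 draws, 500 adaptation steps).
#' @param seed integer seed; chain RNGs are derived from it.
#' @param nu_fixed optionally hold the t degrees of freedom fixed at this
#'   value (e.g. a large value approximates a Gaussian likelihood).
#' @param rhat_max,ess_min convergence gate; fits failing it after one retry
#'   with doubled draws are flagged, never silently dropped.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(variant = c("per_drug", "overall", "joint_shared"),
                       drugs = NULL, group_encoding = NULL,
                       chains = 4L, warmup = 1000L, draws = 1000L,
                       adapt = 500L, seed = 1L, nu_fixed = NULL,
                       rhat_max = 1.01, ess_min = 400) {
  variant <- match.arg(variant)
  if (variant == "joint_shared" && (is.null(drugs) || length(drugs) < 2L))
    stop("joint_shared requires >= 2 drugs in scope")
  structure(list(variant = variant, drugs = drugs,
                 group_encoding = group_encoding,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), adapt = as.integer(adapt),
                 seed = as.integer(seed), nu_fixed = nu_fixed,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "model_spec")
}

# Group encoding: x = 0 for case, 1 for outgroup (alpha is then literally
# the potency in the case group)
encode_groups <- function(sheet) {
  lines <- unique(sheet$cell_line)
  x <- ifelse(sheet$group[match(lines, sheet$cell_line)] == "case", 0, 1)
  names(x) <- lines
  x
}

jags_model_file <- function(name) {
  f <- system.file("jags", name, package = "chemosens")
  if (!nzchar(f)) stop("model file not found: ", name)
  f
}

run_jags <- function(file, data, monitors, spec, seed) {
  inits <- lapply(seq_len(spec$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + 1000L * k) %% 2147483647L))
  jm <- rjags::jags.model(file, data = data, inits = inits,
                          n.chains = spec$chains, n.adapt = spec$adapt,
                          quiet = TRUE)
  update(jm, spec$warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = spec$draws,
                      progress.bar = "none")
}

mcmc_diagnostics <- function(samp) {
  mat <- as.matrix(samp)
  keep <- apply(mat, 2, function(v) stats::sd(v) > 0)
  rhat <- if (length(samp) >= 2 && any(keep)) {
    gd <- try(coda::gelman.diag(samp[, names(which(keep)), drop = FALSE],
                                autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (inherits(gd, "try-error")) NA_real_ else max(gd$psrf[, 1], na.rm = TRUE)
  } else NA_real_
  ess <- if (any(keep))
    min(coda::effectiveSize(samp[, names(which(keep)), drop = FALSE]))
  else NA_real_
  # divergence counts are an HMC-specific diagnostic; not defined for this
  # Gibbs/slice sampler
  list(max_rhat = rhat, min_ess = ess, divergences = NA_integer_)
}

summarize_draws <- function(samp) {
  mat <- as.matrix(samp)
  out <- lapply(colnames(mat), function(p) {
    v <- mat[, p]
    p_neg <- mean(v < 0)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               q2.5 = unname(stats::quantile(v, 0.025)),
               q97.5 = unname(stats::quantile(v, 0.975)),
               p_neg = p_neg,
               p_nonzero = 2 * max(p_neg, 1 - p_neg) - 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the sensitization model for one gene
#'
#' @param records data.frame with columns \code{cell_line}, \code{drug},
#'   \code{y}, \code{se2} for one gene (output rows of
#'   \code{\link{aggregate_gene}}).
#' @param spec a \code{\link{model_spec}}.
#' @param sheet optional \code{sample_sheet} used to derive the group
#'   encoding when \code{spec$group_encoding} is NULL.
#' @param seed per-fit seed override (defaults to \code{spec$seed}).
#' @return a \code{posterior_summary}: data.frame of per-parameter
#'   summaries (mean, sd, 2.5/97.5% quantiles, \code{p_neg},
#'   \code{p_nonzero}) with attributes \code{diagnostics} (max R-hat, min
#'   effective sample size, divergences) and \code{converged}.
#' @export
fit_gene <- function(records, spec, sheet = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(is.finite(records$se2)))
    stop("all se2 must be finite")
  enc <- spec$group_encoding
  if (is.null(enc)) {
    if (is.null(sheet))
      stop("need group_encoding in spec or a sample sheet")
    enc <- encode_groups(sheet)
  }
  drugs <- spec$drugs
  if (is.null(drugs)) drugs <- sort(unique(records$drug))
  records <- records[records$drug %in% drugs, , drop = FALSE]
  # canonical order: input row order must not affect the draws
  records <- records[order(records$drug, records$cell_line), , drop = FALSE]
  x <- enc[records$cell_line]
  if (any(is.na(x))) stop("cell line(s) missing from group encoding")

  if (spec$variant == "per_drug") {
    if (length(unique(records$drug)) != 1L)
      stop("per_drug variant needs records for exactly one drug")
    if (length(unique(x)) < 2L)
      stop("per_drug (case/control) variant needs both groups present")
    if (nrow(records) < 3L) stop("need >= 3 cell lines with records")
    data <- list(y = records$y, x = unname(x), se2 = records$se2,
                 N = nrow(records))
    file <- jags_model_file("t_case_control.jags")
    monitors <- c("alpha", "beta", "sigma", "nu")
  } else if (spec$variant == "overall") {
    if (nrow(records) < 3L) stop("need >= 3 cell lines with records")
    data <- list(y = records$y, se2 = records$se2, N = nrow(records))
    file <- jags_model_file("t_overall.jags")
    monitors <- c("alpha", "sigma", "nu")
  } else {
    if (length(unique(records$drug)) < 2L)
      stop("joint_shared needs records for >= 2 in-scope drugs")
    d <- match(records$drug, drugs)
    data <- list(y = records$y, x = unname(x), se2 = records$se2,
                 N = nrow(records), d = d, D = length(drugs))
    file <- jags_model_file("t_joint.jags")
    monitors <- c("alpha", "beta", "sigma", "mu_alpha", "mu_beta",
                  "sigma_alpha", "sigma_beta", "nu")
  }
  if (!is.null(spec$nu_fixed)) {
    data$nu <- spec$nu_fixed
    monitors <- setdiff(monitors, "nu")
  }

  samp <- run_jags(file, data, monitors, spec, seed)
  diag <- mcmc_diagnostics(samp)
  converged <- is.na(diag$max_rhat) || diag$max_rhat <= spec$rhat_max
  if (!converged) {                       # one retry with doubled draws
    spec2 <- spec
    spec2$draws <- spec$draws * 2L
    spec2$warmup <- spec$warmup * 2L
    samp <- run_jags(file, data, monitors, spec2, seed + 7L)
    diag <- mcmc_diagnostics(samp)
    converged <- is.na(diag$max_rhat) || diag$max_rhat <= spec$rhat_max
  }
  out <- summarize_draws(samp)
  if (spec$variant == "joint_shared") {
    # label per-drug parameters by drug name
    out$parameter <- vapply(out$parameter, function(p) {
      m <- regmatches(p, regexec("^(alpha|beta|sigma)\\[(\\d+)\\]$", p))[[1]]
      if (length(m)) paste0(m[2], ".", drugs[as.integer(m[3])]) else p
    }, character(1))
  }
  attr(out, "diagnostics") <- diag
  attr(out, "converged") <- converged
  attr(out, "draws") <- as.matrix(samp)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Fit the model independently for every gene in a table
#'
#' Genes are processed in sorted order with per-gene seeds derived from
#' \code{spec$seed}, so reruns are reproducible and row order of the input
#' does not matter. Genes whose fit fails or does not converge are flagged
#' in the output, never dropped silently.
#'
#' @param gene_table gene-level table from \code{\link{aggregate_gene}}.
#' @param spec a \code{\link{model_spec}}.
#' @param sheet optional \code{sample_sheet} for the group encoding.
#' @param verbose print progress every 50 genes.
#' @return data.frame, one row per gene, with columns
#'   \code{<parameter>_mean}, \code{<parameter>_sd}, \code{<parameter>_q2.5},
#'   \code{<parameter>_q97.5}, \code{<parameter>_p_neg},
#'   \code{<parameter>_p_nonzero} for each model parameter, plus
#'   \code{max_rhat}, \code{min_ess}, \code{converged}, \code{error}.
#' @export
fit_all <- function(gene_table, spec, sheet = NULL, verbose = FALSE) {
  genes <- sort(unique(gene_table$gene))
  if (!length(genes)) {
    return(data.frame(gene = character(0)))
  }
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    rec <- gene_table[gene_table$gene == g, , drop = FALSE]
    seed_g <- (spec$seed + 131L * gi) %% 2147483647L
    fit <- try(fit_gene(rec, spec, sheet = sheet, seed = seed_g),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      rows[[gi]] <- data.frame(gene = g, converged = FALSE,
                               error = conditionMessage(attr(fit, "condition")),
                               stringsAsFactors = FALSE)
    } else {
      d <- attr(fit, "diagnostics")
      wide <- list(gene = g)
      for (r in seq_len(nrow(fit))) {
        p <- fit$parameter[r]
        for (col in c("mean", "sd", "q2.5", "q97.5", "p_neg", "p_nonzero"))
          wide[[paste0(p, "_", col)]] <- fit[[col]][r]
      }
      wide$max_rhat <- d$max_rhat
      wide$min_ess <- d$min_ess
      wide$converged <- attr(fit, "converged")
      wide$error <- NA_character_
      rows[[gi]] <- as.data.frame(wide, stringsAsFactors = FALSE,
                                  check.names = FALSE)
    }
    if (verbose && gi %% 50L == 0L)
      message(sprintf("fit %d/%d genes", gi, length(genes)))
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm, names(r))) r[[m]] <- NA
    r[, nm, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank genes for sensitization or resistance
#'
#' @param summaries output of \code{\link{fit_all}}.
#' @param direction \code{"sensitize"} (negative fold-change effects first)
#'   or \code{"resist"}.
#' @param statistic \code{"mean_effect"} ranks by the posterior mean effect;
#'   \code{"p_nonzero"} ranks genes whose effect sign matches the requested
#'   direction by descending posterior probability of a nonzero effect.
#' @param param which effect to rank on (default \code{"alpha"}; use
#'   \code{"mu_alpha"} for joint fits).
#' @return the table sorted accordingly with a \code{rank} column; ties
#'   broken by gene name for stability.
#' @export
rank_genes <- function(summaries, direction = c("sensitize", "resist"),
                       statistic = c("mean_effect", "p_nonzero"),
                       param = "alpha") {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  mcol <- paste0(param, "_mean")
  pcol <- paste0(param, "_p_nonzero")
  if (!mcol %in% names(summaries)) stop("missing column: ", mcol)
  sgn <- if (direction == "sensitize") 1 else -1
  if (statistic == "mean_effect") {
    o <- order(sgn * summaries[[mcol]], summaries$gene)
  } else {
    if (!pcol %in% names(summaries)) stop("missing column: ", pcol)
    right_sign <- sgn * summaries[[mcol]] < 0
    # right-signed genes first by descending p_nonzero, then the rest
    o <- order(!right_sign,
               ifelse(right_sign, -summaries[[pcol]], summaries[[pcol]]),
               summaries$gene)
  }
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Case-group potency and differential sensitization per gene
#'
#' Reports, per gene, the posterior mean sensitizing effect in the case
#' group (\code{alpha}) and the differential on the plotting convention
#' where positive values mean greater sensitization in the case group.
#' With cases encoded x = 0, \code{beta} is the outgroup-minus-case shift
#' in log2 fold change; sensitization is a negative fold change, so a
#' positive \code{beta} already means the case group is more sensitized
#' and the differential reported is \code{+beta}.
#'
#' @param summaries output of \code{\link{fit_all}} for a variant that
#'   includes \code{beta}.
#' @param param_alpha,param_beta parameter names (use \code{"mu_alpha"},
#'   \code{"mu_beta"} for joint fits).
#' @return data.frame: gene, case_potency, differential,
#'   differential_p_nonzero.
#' @export
selectivity_table <- function(summaries, param_alpha = "alpha",
                              param_beta = "beta") {
  acol <- paste0(param_alpha, "_mean")
  bcol <- paste0(param_beta, "_mean")
  pcol <- paste0(param_beta, "_p_nonzero")
  stopifnot(acol %in% names(summaries), bcol %in% names(summaries))
  data.frame(gene = summaries$gene,
             case_potency = summaries[[acol]],
             differential = summaries[[bcol]],
             differential_p_nonzero =
               if (pcol %in% names(summaries)) summaries[[pcol]] else NA_real_,
             stringsAsFactors = FALSE)
}
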