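#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir directory for stage outputs.
#' @param sim a \code{\link{sim_config}} (synthetic run) or NULL when
#'   reading counts from disk.
#' @param counts_path,sheet_path,library_path input files for a real run.
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("preprocess", "fit", "geneset", "synergy")}.
#' @param model a \code{\link{model_spec}}.
#' @param collections named list of gene-set collections for the geneset
#'   stage.
#' @param dose_matrices list of \code{dose_matrix} objects for the synergy
#'   stage.
#' @param alpha_dixon,min_count,pseudocount,min_overlap thresholds.
#' @param grouping_seed seed for null pseudo-gene construction.
#' @param effect_source \code{"posterior"} (model estimates) or
#'   \code{"raw"} (aggregated fold changes) fed to the gene-set stage.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir = tempfile("chemosens_run_"),
                       sim = NULL, counts_path = NULL, sheet_path = NULL,
                       library_path = NULL,
                       stages = c("preprocess", "fit", "geneset"),
                       model = model_spec("overall"),
                       collections = NULL, dose_matrices = NULL,
                       alpha_dixon = 0.05, min_count = 5L, pseudocount = 1,
                       min_overlap = 5L, grouping_seed = 1L,
                       effect_source = c("posterior", "raw")) {
  effect_source <- match.arg(effect_source)
  structure(list(out_dir = out_dir, sim = sim, counts_path = counts_path,
                 sheet_path = sheet_path, library_path = library_path,
                 stages = stages, model = model, collections = collections,
                 dose_matrices = dose_matrices, alpha_dixon = alpha_dixon,
                 min_count = as.integer(min_count), pseudocount = pseudocount,
                 min_overlap = as.integer(min_overlap),
                 grouping_seed = as.integer(grouping_seed),
                 effect_source = effect_source),
            class = "run_config")
}

#' Orchestrate simulate/load -> preprocess -> fit -> geneset -> synergy
#'
#' Runs the enabled stages in order, writing one TSV per stage under
#' \code{config$out_dir} plus a run manifest recording the package version,
#' the config hash and per-stage status. Deterministic given the seeds in
#' the config. A stage failure aborts with an error naming the stage.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisible list with the in-memory stage results (\code{library},
#'   \code{sheet}, \code{counts}, \code{gene_table}, \code{summaries},
#'   \code{genesets}, \code{synergy}, \code{manifest}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(utils::packageVersion("chemosens")),
                   config_hash = config_hash(config), stages = list())
  res <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = as.numeric(Sys.time() - t0, units = "secs"))
    val
  }

  if (!is.null(config$sim)) {
    inp <- stage("simulate", {
      lib <- simulate_library(config$sim)
      sheet <- simulate_sample_sheet(config$sim)
      simres <- simulate_screen_counts(lib, sheet, config$sim)
      write_library(lib, file.path(config$out_dir, "library.tsv"))
      write_sample_sheet(sheet, file.path(config$out_dir, "samples.csv"))
      write_counts(simres$counts, file.path(config$out_dir, "counts.tsv"))
      if (!is.null(simres$truth$effect_table))
        write_results(simres$truth$effect_table,
                      file.path(config$out_dir, "ground_truth.tsv"), config)
      list(library = lib, sheet = sheet, counts = simres$counts,
           truth = simres$truth)
    })
  } else {
    inp <- stage("load", {
      lib <- read_library(config$library_path)
      sheet <- read_sample_sheet(config$sheet_path)
      counts <- read_counts(config$counts_path, library = lib)
      validate_screen(counts, lib, sheet)
      list(library = lib, sheet = sheet, counts = counts, truth = NULL)
    })
  }
  res[c("library", "sheet", "counts", "truth")] <-
    inp[c("library", "sheet", "counts", "truth")]

  null_genes <- build_null_genes(inp$library, seed = config$grouping_seed)

  if ("preprocess" %in% config$stages) {
    res$gene_table <- stage("preprocess", {
      gt <- preprocess_screen(inp$counts, inp$sheet, inp$library,
                              alpha_dixon = config$alpha_dixon,
                              min_count = config$min_count,
                              pseudocount = config$pseudocount,
                              null_genes = null_genes)
      write_results(gt, file.path(config$out_dir, "gene_lfc.tsv"), config)
      gt
    })
  }

  if ("fit" %in% config$stages) {
    res$summaries <- stage("fit", {
      sm <- fit_all(res$gene_table, config$model, sheet = inp$sheet)
      write_results(sm, file.path(config$out_dir, "posterior.tsv"), config)
      sm
    })
  }

  if ("geneset" %in% config$stages && !is.null(config$collections)) {
    res$genesets <- stage("geneset", {
      eff <- pipeline_effects(res, config)
      is_null <- grepl("^NTNULL", names(eff))
      gs <- run_collections(config$collections, eff[!is_null], eff[is_null],
                            min_overlap = config$min_overlap)
      write_results(gs, file.path(config$out_dir, "genesets.tsv"), config)
      gs
    })
  }

  if ("synergy" %in% config$stages && !is.null(config$dose_matrices)) {
    res$synergy <- stage("synergy", {
      sy <- do.call(rbind, lapply(seq_along(config$dose_matrices), function(i) {
        dm <- config$dose_matrices[[i]]
        ss <- zip_delta(dm)
        data.frame(matrix_id = i, drug_row = dm$drug_row,
                   drug_col = dm$drug_col, mean_delta = ss$mean_delta,
                   max_window_score = ss$max_window_score)
      }))
      write_results(sy, file.path(config$out_dir, "synergy.tsv"), config)
      sy
    })
  }

  res$manifest <- manifest
  mf <- file.path(config$out_dir, "manifest.tsv")
  mdf <- data.frame(stage = names(manifest$stages),
                    status = vapply(manifest$stages, `[[`, "", "status"),
                    seconds = vapply(manifest$stages, `[[`, 0, "seconds"))
  write_results(mdf, mf, config)
  invisible(res)
}

# effect vector (gene -> estimate) for the gene-set stage
pipeline_effects <- function(res, config) {
  if (config$effect_source == "posterior" && !is.null(res$summaries)) {
    col <- if ("alpha_mean" %in% names(res$summaries)) "alpha_mean"
           else "mu_alpha_mean"
    eff <- res$summaries[[col]]
    names(eff) <- res$summaries$gene
  } else {
    agg <- tapply(res$gene_table$y, res$gene_table$gene, mean)
    eff <- as.numeric(agg)
    names(eff) <- names(agg)
  }
  eff[!is.na(eff)]
}

#' Count genes crossing a score threshold per drug and per cell line
#'
#' Accepts any per-(gene, cell line, drug) score table, e.g. externally
#' computed RRA-like scores or this package's posterior probabilities; the
#' pipeline never computes RRA itself.
#'
#' @param scores data.frame with columns \code{gene}, \code{cell_line},
#'   \code{drug}, \code{score}.
#' @param threshold scores strictly below this count as hits.
#' @return list: \code{per_gene} (hits per gene across cell lines x drugs),
#'   \code{per_cell_line}, \code{per_drug}, \code{total}.
#' @export
hit_counts <- function(scores, threshold) {
  stopifnot(all(c("gene", "cell_line", "drug", "score") %in% names(scores)))
  hit <- scores$score < threshold
  list(per_gene = tapply(hit, scores$gene, sum),
       per_cell_line = tapply(hit, scores$cell_line, sum),
       per_drug = tapply(hit, scores$drug, sum),
       total = sum(hit))
}

#' Permutation p-value for a hit-count statistic
#'
#' Shuffles all scores across the full table and recomputes the observed
#' statistic each time; the p-value uses the add-one correction
#' \code{(1 + #(permuted >= observed)) / (1 + n_perm)} so it is never 0.
#'
#' @param scores score table as in \code{\link{hit_counts}}.
#' @param observed the observed count statistic.
#' @param stat_fun function(score table) -> statistic; by default the
#'   maximum per-gene hit count at \code{threshold}.
#' @param threshold hit threshold used by the default statistic.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
permutation_pvalue <- function(scores, observed, stat_fun = NULL,
                               threshold = 0.05, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.null(stat_fun))
    stat_fun <- function(s) max(hit_counts(s, threshold)$per_gene)
  set.seed(seed)
  ge <- 0L
  perm <- scores
  for (b in seq_len(n_perm)) {
    perm$score <- sample(scores$score)
    if (stat_fun(perm) >= observed) ge <- ge + 1L
  }
  (1 + ge) / (1 + n_perm)
}
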