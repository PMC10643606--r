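#' Simulation configuration for synthetic screens
#'
#' The defaults reproduce the structure of the study design this package
#' analyzes: 655 druggable genes with 6 guides each, 400 non-targeting
#' guides, 55 pan-essential genes (326 guides), 10 case (neuroblastoma) and
#' 8 outgroup cell lines, and 8 drugs plus vehicle per line.
#'
#' @param n_genes number of (non-essential) targeted genes.
#' @param guides_per_gene guides designed per targeted gene.
#' @param n_nontargeting number of non-targeting control guides.
#' @param n_panessential_genes number of pan-essential control genes.
#' @param panessential_guides total guides across pan-essential genes.
#' @param n_case_lines,n_outgroup_lines cell lines per group.
#' @param drugs named character vector: drug name -> drug class
#'   (\code{"dna_damage"} or \code{"other"}).
#' @param mean_depth expected reads per guide per sample.
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @param baseline_sdlog log-normal sd of per-guide baseline abundance.
#' @param effect_table data.frame (gene, drug, cell_line, delta) of true
#'   log2 fold-change shifts applied in the drug arm; NULL for a null screen.
#' @param essential_dropout log2 shift applied to pan-essential guides in
#'   both arms (viability dropout).
#' @param outlier_fraction fraction of targeting guides planted as
#'   opposite-sign outliers (exercises the Dixon filter).
#' @param outlier_shift absolute log2 shift given to planted outlier guides,
#'   signed opposite to their gene's delta.
#' @param seed integer seed; fully determines the simulated screen.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 655L, guides_per_gene = 6L,
                       n_nontargeting = 400L, n_panessential_genes = 55L,
                       panessential_guides = 326L,
                       n_case_lines = 10L, n_outgroup_lines = 8L,
                       drugs = c(doxorubicin = "dna_damage",
                                 etoposide = "dna_damage",
                                 cisplatin = "dna_damage",
                                 topotecan = "dna_damage",
                                 vincristine = "dna_damage",
                                 phosphoramide_mustard = "dna_damage",
                                 atra = "other", jqad1 = "other"),
                       mean_depth = 500, nb_dispersion = 0.05,
                       baseline_sdlog = 0.5,
                       effect_table = NULL, essential_dropout = -2,
                       outlier_fraction = 0, outlier_shift = 1.5,
                       seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_nontargeting >= 0,
            n_panessential_genes >= 0, n_case_lines >= 1,
            n_outgroup_lines >= 0, mean_depth > 0, nb_dispersion >= 0,
            length(drugs) >= 1, !is.null(names(drugs)))
  if (guides_per_gene < 2L)
    warning("guides_per_gene < 2: gene-level standard errors are undefined downstream")
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_nontargeting = as.integer(n_nontargeting),
              n_panessential_genes = as.integer(n_panessential_genes),
              panessential_guides = as.integer(panessential_guides),
              n_case_lines = as.integer(n_case_lines),
              n_outgroup_lines = as.integer(n_outgroup_lines),
              drugs = drugs, mean_depth = mean_depth,
              nb_dispersion = nb_dispersion, baseline_sdlog = baseline_sdlog,
              effect_table = effect_table,
              essential_dropout = essential_dropout,
              outlier_fraction = outlier_fraction,
              outlier_shift = outlier_shift, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a guide library with the configured category structure
#'
#' @param config a \code{sim_config}.
#' @return a \code{guide_library} with \code{n_genes * guides_per_gene}
#'   targeting guides, the configured non-targeting guides, and pan-essential
#'   guides spread as evenly as possible across pan-essential genes.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  tg <- data.frame(
    guide_id = sprintf("%s_g%d", rep(genes, each = config$guides_per_gene),
                       rep(seq_len(config$guides_per_gene), config$n_genes)),
    gene = rep(genes, each = config$guides_per_gene),
    category = "targeting", stringsAsFactors = FALSE)
  nt <- if (config$n_nontargeting > 0)
    data.frame(guide_id = sprintf("NT_g%03d", seq_len(config$n_nontargeting)),
               gene = NT_SENTINEL, category = "non_targeting",
               stringsAsFactors = FALSE)
  else NULL
  pe <- NULL
  if (config$n_panessential_genes > 0) {
    pg <- sprintf("ESS%03d", seq_len(config$n_panessential_genes))
    # spread the guide total as evenly as possible (e.g. 326 over 55 genes)
    per <- rep(config$panessential_guides %/% config$n_panessential_genes,
               config$n_panessential_genes)
    extra <- config$panessential_guides %% config$n_panessential_genes
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    pe <- data.frame(
      guide_id = unlist(lapply(seq_along(pg), function(i)
        sprintf("%s_g%d", pg[i], seq_len(per[i])))),
      gene = rep(pg, per), category = "pan_essential",
      stringsAsFactors = FALSE)
  }
  validate_guide_library(rbind(tg, nt, pe))
}

#' Simulate a sample sheet with the configured design
#'
#' One vehicle and one sample per drug for every cell line.
#'
#' @param config a \code{sim_config}.
#' @return a \code{sample_sheet}.
#' @export
simulate_sample_sheet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lines <- c(sprintf("NB%02d", seq_len(config$n_case_lines)),
             sprintf("OG%02d", seq_len(config$n_outgroup_lines)))
  grp <- rep(c("case", "outgroup"),
             c(config$n_case_lines, config$n_outgroup_lines))
  conds <- c("vehicle", names(config$drugs))
  df <- expand.grid(cell_line = lines, cond = conds,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$group <- grp[match(df$cell_line, lines)]
  df$condition <- ifelse(df$cond == "vehicle", "vehicle", "drug")
  df$drug <- ifelse(df$cond == "vehicle", "", df$cond)
  df$drug_class <- ifelse(df$cond == "vehicle", "other",
                          unname(config$drugs[df$cond]))
  df$drug_class[is.na(df$drug_class)] <- "other"
  df$sample_id <- ifelse(df$condition == "vehicle",
                         paste0(df$cell_line, "_vehicle"),
                         paste0(df$cell_line, "_", df$drug))
  validate_sample_sheet(df[, c("sample_id", "cell_line", "condition",
                               "drug", "group", "drug_class")])
}

#' Simulate screen counts with known ground truth
#'
#' Counts are drawn per guide and sample from a negative binomial whose mean
#' is a depth-scaled log-normal baseline abundance, shifted multiplicatively
#' by \code{2^delta} in the drug arm for guides of genes with a planted
#' effect, and by \code{2^essential_dropout} in both arms for pan-essential
#' guides. Non-targeting guides are never shifted. Optionally a fraction of
#' targeting guides is planted as outliers: they receive an extra per-guide
#' shift with sign opposite to their gene's delta (so the Dixon
#' directionality rule can catch them).
#'
#' @param library a \code{guide_library}.
#' @param sheet a \code{sample_sheet}.
#' @param config a \code{sim_config}; its \code{effect_table} must reference
#'   only genes/drugs/cell lines present in the inputs.
#' @return list with elements \code{counts} (a \code{screen_counts}) and
#'   \code{truth} (list: \code{effect_table}, \code{baseline},
#'   \code{outlier_guides}).
#' @export
simulate_screen_counts <- function(library, sheet, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  eff <- config$effect_table
  if (!is.null(eff)) {
    stopifnot(all(c("gene", "drug", "cell_line", "delta") %in% names(eff)))
    bad_gene <- setdiff(eff$gene, library$gene)
    if (length(bad_gene))
      stop("effect_table references unknown gene(s): ",
           paste(bad_gene[1:5], collapse = ", "))
    bad_drug <- setdiff(eff$drug, sheet$drug)
    if (length(bad_drug))
      stop("effect_table references unknown drug(s): ",
           paste(bad_drug, collapse = ", "))
    bad_line <- setdiff(eff$cell_line, sheet$cell_line)
    if (length(bad_line))
      stop("effect_table references unknown cell line(s): ",
           paste(bad_line, collapse = ", "))
  }
  G <- nrow(library)
  baseline <- stats::rlnorm(G, meanlog = 0, sdlog = config$baseline_sdlog)
  baseline <- baseline / mean(baseline)          # depth carries the scale
  names(baseline) <- library$guide_id

  outlier_guides <- character(0)
  if (config$outlier_fraction > 0 && !is.null(eff)) {
    cand <- library$guide_id[library$category == "targeting" &
                               library$gene %in% eff$gene]
    n_out <- floor(length(cand) * config$outlier_fraction)
    if (n_out > 0) outlier_guides <- sample(cand, n_out)
  }

  is_ess <- library$category == "pan_essential"
  mu0 <- config$mean_depth * baseline
  mu0[is_ess] <- mu0[is_ess] * 2^config$essential_dropout

  counts <- matrix(0L, G, nrow(sheet),
                   dimnames = list(library$guide_id, sheet$sample_id))
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  for (s in seq_len(nrow(sheet))) {
    mu <- mu0
    if (sheet$condition[s] == "drug" && !is.null(eff)) {
      here <- eff[eff$drug == sheet$drug[s] &
                    eff$cell_line == sheet$cell_line[s], , drop = FALSE]
      if (nrow(here)) {
        for (k in seq_len(nrow(here))) {
          gi <- library$gene == here$gene[k]
          d <- rep(here$delta[k], sum(gi))
          ids <- library$guide_id[gi]
          flip <- ids %in% outlier_guides
          # planted outliers move against their gene's effect
          d[flip] <- -sign(here$delta[k]) * config$outlier_shift
          mu[gi] <- mu[gi] * 2^d
        }
      }
    }
    counts[, s] <- if (is.finite(size))
      stats::rnbinom(G, mu = mu, size = size)
    else stats::rpois(G, lambda = mu)
  }
  sc <- screen_counts(counts, gene = library$gene, library = library)
  list(counts = sc,
       truth = list(effect_table = eff, baseline = baseline,
                    outlier_guides = outlier_guides))
}

#' Simulate a dense dose-response combination matrix
#'
#' Monotherapy responses follow four-parameter logistic (4PL) curves on the
#' cytotoxicity scale; the combination response is the Bliss-additive
#' expectation plus a constant interaction shift \code{delta0} and Gaussian
#' noise, clipped to [0, 1]. The default grid mirrors a dense 10 x 10 layout
#' with 1:3 dilution and a 0-dose anchor row/column for monotherapy.
#'
#' @param curve1,curve2 numeric vectors \code{c(min, max, ec50, hill)} on the
#'   inhibition (cytotoxicity) scale, \code{0 <= min <= max <= 1}.
#' @param delta0 constant interaction shift added to every combination cell.
#' @param doses1,doses2 dose vectors (excluding the 0 anchor, which is added).
#' @param noise_sd Gaussian noise sd on the response scale.
#' @param seed integer seed.
#' @param drug_row,drug_col drug names for labeling.
#' @return a \code{dose_matrix}: list with \code{doses_row}, \code{doses_col}
#'   (including 0), \code{response} matrix, drug names.
#' @export
simulate_dose_matrix <- function(curve1, curve2, delta0 = 0,
                                 doses1 = 0.1 * 3^(0:8),
                                 doses2 = 0.1 * 3^(0:8),
                                 noise_sd = 0, seed = 1L,
                                 drug_row = "drugA", drug_col = "drugB") {
  stopifnot(length(curve1) == 4, length(curve2) == 4,
            curve1[1] >= 0, curve1[2] <= 1, curve1[1] <= curve1[2],
            curve2[1] >= 0, curve2[2] <= 1, curve2[1] <= curve2[2])
  set.seed(seed)
  dr <- c(0, sort(doses1))
  dc <- c(0, sort(doses2))
  y1 <- four_pl(dr, curve1[1], curve1[2], curve1[3], curve1[4])
  y2 <- four_pl(dc, curve2[1], curve2[2], curve2[3], curve2[4])
  y1[1] <- 0; y2[1] <- 0                        # untreated anchor
  resp <- outer(y1, y2, function(a, b) a + b - a * b)
  combo <- outer(dr > 0, dc > 0, `&`)
  resp[combo] <- resp[combo] + delta0
  if (noise_sd > 0)
    resp <- resp + matrix(stats::rnorm(length(resp), 0, noise_sd),
                          nrow(resp), ncol(resp))
  resp <- pmin(pmax(resp, 0), 1)
  dimnames(resp) <- list(format(dr, trim = TRUE), format(dc, trim = TRUE))
  structure(list(drug_row = drug_row, drug_col = drug_col,
                 doses_row = dr, doses_col = dc, response = resp),
            class = "dose_matrix")
}

# 4PL on the log-dose scale; dose 0 maps to the lower asymptote
four_pl <- function(dose, lo, hi, ec50, hill) {
  y <- rep(lo, length(dose))
  pos <- dose > 0
  y[pos] <- lo + (hi - lo) / (1 + exp(-hill * (log(dose[pos]) - log(ec50))))
  y
}
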