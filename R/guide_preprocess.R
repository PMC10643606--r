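#' Normalize a count matrix
#'
#' Median-ratio normalization (the DESeq-style size factor): the reference
#' for each guide is its geometric mean across the samples being normalized,
#' computed on guides with all-nonzero counts, and each sample's size factor
#' is the median of count/reference over those guides. When fewer than 100
#' all-nonzero guides are available the method falls back to total-count
#' scaling (size factor proportional to column sum, geometric mean 1).
#'
#' @param counts a \code{screen_counts} or integer matrix.
#' @param method \code{"median-ratio"} (with automatic fallback) or
#'   \code{"total"}.
#' @param min_ref_guides minimum all-nonzero guides for the median-ratio
#'   branch.
#' @return list with \code{normalized} (real matrix), \code{size_factors}
#'   and \code{method_used}.
#' @export
normalize_counts <- function(counts, method = c("median-ratio", "total"),
                             min_ref_guides = 100L) {
  method <- match.arg(method)
  mat <- if (inherits(counts, "screen_counts")) counts$counts else counts
  if (any(colSums(mat) == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(mat)[colSums(mat) == 0], collapse = ", "))
  method_used <- method
  if (method == "median-ratio") {
    nz <- rowSums(mat == 0) == 0L
    if (sum(nz) < min_ref_guides) {
      method_used <- "total"
    } else {
      sub <- mat[nz, , drop = FALSE]
      logref <- rowMeans(log(sub))
      sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - logref)))
    }
  }
  if (method_used == "total") {
    cs <- colSums(mat)
    sf <- cs / exp(mean(log(cs)))   # geometric mean 1, like median-ratio
  }
  norm <- sweep(mat, 2, sf, "/")
  list(normalized = norm, size_factors = sf, method_used = method_used)
}

#' Guide-level drug-vs-vehicle log2 fold changes
#'
#' For every drug sample and its matching vehicle sample from the same cell
#' line, computes \code{log2((n_drug + c) / (n_vehicle + c))} on normalized
#' counts with pseudocount \code{c}. Guides whose raw count is below
#' \code{min_count} in both arms are flagged \code{low_count} (unstable
#' estimates); all others are \code{kept}.
#'
#' @param counts a \code{screen_counts}.
#' @param sheet a \code{sample_sheet}.
#' @param library a \code{guide_library} (provides gene per guide).
#' @param norm normalization output of \code{\link{normalize_counts}}; if
#'   NULL it is computed here with defaults.
#' @param pseudocount added on the normalized scale.
#' @param min_count raw-count threshold of the low-count rule.
#' @return data.frame with columns guide_id, gene, category, cell_line,
#'   drug, lfc, flag.
#' @export
guide_lfc <- function(counts, sheet, library, norm = NULL,
                      pseudocount = 1, min_count = 5L) {
  if (is.null(norm)) norm <- normalize_counts(counts)
  nm <- norm$normalized
  raw <- counts$counts
  dr <- sheet[sheet$condition == "drug", , drop = FALSE]
  out <- vector("list", nrow(dr))
  for (k in seq_len(nrow(dr))) {
    veh_id <- sheet$sample_id[sheet$condition == "vehicle" &
                                sheet$cell_line == dr$cell_line[k]]
    if (length(veh_id) != 1L)
      stop(sprintf("expected exactly one vehicle sample for cell line '%s', found %d",
                   dr$cell_line[k], length(veh_id)))
    s_id <- dr$sample_id[k]
    lfc <- log2((nm[, s_id] + pseudocount) / (nm[, veh_id] + pseudocount))
    low <- raw[, s_id] < min_count & raw[, veh_id] < min_count
    out[[k]] <- data.frame(
      guide_id = counts$guides,
      gene = library$gene[match(counts$guides, library$guide_id)],
      category = library$category[match(counts$guides, library$guide_id)],
      cell_line = dr$cell_line[k], drug = dr$drug[k],
      lfc = unname(lfc),
      flag = ifelse(low, "low_count", "kept"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Two-sided critical values of Dixon's r10 ("Q") statistic, n = 3..10
# (Dixon 1953; Rorabaugh 1991). Rows: n; columns: two-sided alpha.
dixon_crit <- local({
  m <- rbind(
    c(0.886, 0.941, 0.970, 0.988, 0.994),
    c(0.679, 0.765, 0.829, 0.889, 0.926),
    c(0.557, 0.642, 0.710, 0.780, 0.821),
    c(0.482, 0.560, 0.625, 0.698, 0.740),
    c(0.434, 0.507, 0.568, 0.637, 0.680),
    c(0.399, 0.468, 0.526, 0.590, 0.634),
    c(0.370, 0.437, 0.493, 0.555, 0.598),
    c(0.349, 0.412, 0.466, 0.527, 0.568))
  dimnames(m) <- list(3:10, c("0.2", "0.1", "0.05", "0.02", "0.01"))
  m
})

#' Dixon Q test for a single small sample
#'
#' Computes the r10 statistic Q = gap/range for the most extreme value and
#' an approximate two-sided p-value by linear interpolation in alpha between
#' the published critical values for n = 3..10. Beyond the tabulated range
#' the p-value is clamped (reported as 0.001 past the 0.01 column, 1 below
#' the 0.2 column's reach).
#'
#' @param x numeric vector, 3 <= length(x) <= 10.
#' @return list: \code{statistic} (Q), \code{p.value}, \code{candidate}
#'   (index into \code{x} of the extreme value).
#' @export
dixon_q_test <- function(x) {
  n <- length(x)
  if (n < 3L || n > 10L)
    stop("Dixon r10 test requires 3 to 10 observations")
  s <- sort(x)
  rng <- s[n] - s[1]
  if (rng == 0)
    return(list(statistic = NA_real_, p.value = 1, candidate = NA_integer_))
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_low >= q_high) {
    q <- q_low; cand <- which.min(x)
  } else {
    q <- q_high; cand <- which.max(x)
  }
  crit <- dixon_crit[as.character(n), ]
  alphas <- as.numeric(colnames(dixon_crit))
  if (q >= crit[length(crit)]) p <- 0.001
  else if (q <= crit[1]) {
    # extrapolate linearly toward Q = 0 <-> p = 1
    p <- min(1, 0.2 + (1 - 0.2) * (crit[1] - q) / crit[1])
  } else {
    i <- max(which(crit <= q))
    p <- alphas[i] + (alphas[i + 1] - alphas[i]) *
      (q - crit[i]) / (crit[i + 1] - crit[i])
  }
  list(statistic = unname(q), p.value = unname(p), candidate = cand)
}

#' Dixon outlier filter for one gene in one cell line x drug
#'
#' Flags at most one guide: the extreme-gap guide by Dixon's r10 statistic,
#' and only when its two-sided p-value is below \code{alpha} AND its fold
#' change disagrees in sign with the mean of the remaining guides (the
#' directionality rule). With fewer than 3 values no test is run and all
#' guides are kept.
#'
#' @param lfc numeric vector of kept guide log2 fold changes for one gene in
#'   one condition.
#' @param alpha nominal two-sided level (default 0.05).
#' @return logical vector, TRUE where the guide is flagged as a Dixon
#'   outlier.
#' @export
dixon_filter <- function(lfc, alpha = 0.05) {
  flags <- rep(FALSE, length(lfc))
  if (length(lfc) < 3L) return(flags)
  if (length(lfc) > 10L) return(flags)   # outside r10's tabulated range
  tst <- dixon_q_test(lfc)
  if (is.na(tst$statistic) || tst$p.value >= alpha) return(flags)
  cand <- tst$candidate
  others_mean <- mean(lfc[-cand])
  # sign disagreement; a zero mean of others only counts when the candidate
  # itself is nonzero
  disagree <- sign(lfc[cand]) != sign(others_mean) && lfc[cand] != 0
  if (disagree) flags[cand] <- TRUE
  flags
}

#' Apply low-count and Dixon filters to a guide fold-change table
#'
#' Filtering order is low-count first, then the Dixon test per gene x cell
#' line x drug on the surviving guides (order configurable). Non-targeting
#' guides are exempt from the Dixon test (they have no shared gene-level
#' signal) unless grouped into pseudo-genes upstream.
#'
#' @param gfc table from \code{\link{guide_lfc}}.
#' @param alpha Dixon two-sided level.
#' @param dixon_first if TRUE the Dixon test runs before the low-count flag
#'   is honored (both flags are still recorded; Dixon then sees all guides).
#' @return the table with the \code{flag} column updated to
#'   \code{dixon_outlier} where applicable.
#' @export
filter_guides <- function(gfc, alpha = 0.05, dixon_first = FALSE) {
  key <- interaction(gfc$gene, gfc$cell_line, gfc$drug, drop = TRUE)
  groups <- split(seq_len(nrow(gfc)), key)
  for (idx in groups) {
    if (gfc$gene[idx[1]] == NT_SENTINEL) next
    usable <- if (dixon_first) idx else idx[gfc$flag[idx] == "kept"]
    if (length(usable) < 3L) next
    fl <- dixon_filter(gfc$lfc[usable], alpha = alpha)
    gfc$flag[usable[fl]] <- "dixon_outlier"
  }
  gfc
}

#' Aggregate kept guide fold changes to gene level
#'
#' For each gene x cell line x drug, the gene-level estimate is the mean of
#' kept guide log2 fold changes and its squared standard error is
#' \code{var/n} (sample variance). Genes reduced to fewer than 2 kept guides
#' are dropped (a finite standard error is required downstream) and listed
#' in the \code{dropped} attribute.
#'
#' @param gfc filtered guide table (\code{flag == "kept"} rows are used).
#' @return data.frame with columns gene, cell_line, drug, y, se2, n_guides;
#'   attribute \code{dropped} lists gene x condition combinations removed.
#' @export
aggregate_gene <- function(gfc) {
  kept <- gfc[gfc$flag == "kept", , drop = FALSE]
  key <- interaction(kept$gene, kept$cell_line, kept$drug, drop = TRUE)
  sp <- split(seq_len(nrow(kept)), key)
  first <- vapply(sp, `[`, 0L, 1L)
  n <- lengths(sp)
  out <- data.frame(
    gene = kept$gene[first], cell_line = kept$cell_line[first],
    drug = kept$drug[first],
    y = vapply(sp, function(idx) mean(kept$lfc[idx]), 0),
    se2 = ifelse(n >= 2L,
                 vapply(sp, function(idx) stats::var(kept$lfc[idx]), 0) / n,
                 NA_real_),
    n_guides = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  dropped <- out[out$n_guides < 2L, c("gene", "cell_line", "drug")]
  out <- out[out$n_guides >= 2L, , drop = FALSE]
  out <- out[order(out$gene, out$cell_line, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Preprocess a screen end to end
#'
#' Convenience wrapper: normalize, compute guide fold changes, filter
#' (low-count then Dixon), and aggregate to gene level. Non-targeting guides
#' can optionally be grouped into pseudo-genes first (see
#' \code{\link{build_null_genes}}) so they flow through the identical path.
#'
#' @param counts a \code{screen_counts}.
#' @param sheet a \code{sample_sheet}.
#' @param library a \code{guide_library}.
#' @param alpha_dixon,min_count,pseudocount,norm_method tuning knobs, see the
#'   stage functions.
#' @param null_genes optional \code{NullGeneSet} from
#'   \code{\link{build_null_genes}}: non-targeting guides in these groups are
#'   relabeled to their pseudo-gene before filtering/aggregation.
#' @return gene-level table as from \code{\link{aggregate_gene}}.
#' @export
preprocess_screen <- function(counts, sheet, library, alpha_dixon = 0.05,
                              min_count = 5L, pseudocount = 1,
                              norm_method = "median-ratio",
                              null_genes = NULL) {
  norm <- normalize_counts(counts, method = norm_method)
  gfc <- guide_lfc(counts, sheet, library, norm = norm,
                   pseudocount = pseudocount, min_count = min_count)
  if (!is.null(null_genes)) {
    for (pg in names(null_genes$groups)) {
      gfc$gene[gfc$guide_id %in% null_genes$groups[[pg]]] <- pg
    }
  }
  gfc <- filter_guides(gfc, alpha = alpha_dixon)
  aggregate_gene(gfc)
}
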