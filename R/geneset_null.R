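#' Group non-targeting guides into null pseudo-genes
#'
#' Randomly partitions the library's non-targeting guides into disjoint
#' pseudo-genes of \code{group_size} guides each (e.g. 400 guides at size 6
#' give 66 pseudo-genes with 4 guides discarded). Processed through the
#' identical preprocessing and model path, these provide the empirical null
#' distribution for gene-set testing.
#'
#' @param library a \code{guide_library}.
#' @param group_size guides per pseudo-gene (default 6, matching the
#'   targeting-guide design).
#' @param seed integer seed for the random grouping.
#' @return list of class \code{null_gene_set}: \code{groups} (named list of
#'   guide-id vectors, names \code{NTNULL001}, ...), \code{discarded},
#'   \code{seed}.
#' @export
build_null_genes <- function(library, group_size = 6L, seed = 1L) {
  nt <- library$guide_id[library$category == "non_targeting"]
  if (length(nt) < group_size)
    stop(sprintf("need >= %d non-targeting guides to form one pseudo-gene, have %d",
                 group_size, length(nt)))
  set.seed(seed)
  perm <- sample(nt)
  n_groups <- length(nt) %/% group_size
  used <- perm[seq_len(n_groups * group_size)]
  groups <- split(used, rep(seq_len(n_groups), each = group_size))
  names(groups) <- sprintf("NTNULL%03d", seq_len(n_groups))
  structure(list(groups = groups,
                 discarded = setdiff(nt, used), seed = as.integer(seed)),
            class = "null_gene_set")
}

# Shared rank-sum helper: exact two-sided Wilcoxon when both samples are
# small (<= 25) and tie-free, normal approximation with continuity
# correction otherwise.
rank_sum_test <- function(a, b) {
  exact <- length(a) <= 25 && length(b) <= 25 && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Test one gene set against the empirical null
#'
#' Compares the effect estimates of the set's genes (those present in the
#' library) against the null pseudo-gene effects with a two-sided Wilcoxon
#' rank-sum test. The reported \code{diff} is the median set effect minus
#' the median null effect — negative values mean the set's knockouts
#' sensitize more than non-targeting controls.
#'
#' @param set_genes character vector of gene symbols in the set.
#' @param effects named numeric vector: gene -> effect estimate (e.g.
#'   posterior mean fold change).
#' @param null_effects numeric vector of null pseudo-gene effects.
#' @param min_overlap minimum genes with effect estimates required to test
#'   (smaller overlaps are emitted flagged \code{skipped}).
#' @return one-row data.frame: set_name-less result with \code{n_in_library},
#'   \code{diff}, \code{p}, \code{skipped}.
#' @export
test_gene_set <- function(set_genes, effects, null_effects,
                          min_overlap = 5L) {
  hit <- intersect(set_genes, names(effects))
  n <- length(hit)
  if (n < min_overlap) {
    return(data.frame(n_in_library = n, diff = NA_real_, p = NA_real_,
                      skipped = TRUE))
  }
  ev <- unname(effects[hit])
  data.frame(n_in_library = n,
             diff = stats::median(ev) - stats::median(null_effects),
             p = rank_sum_test(ev, null_effects),
             skipped = FALSE)
}

#' Run gene-set analysis for one or more collections
#'
#' Tests every set in every collection against the null pseudo-gene effects
#' and adjusts p-values within each collection by Benjamini-Hochberg.
#'
#' @param collections named list of \code{gene_set_collection}s (or a single
#'   collection).
#' @param effects named numeric vector: gene -> effect estimate.
#' @param null_effects numeric vector of null pseudo-gene effects.
#' @param min_overlap see \code{\link{test_gene_set}}.
#' @return data.frame: collection, set_name, n_in_library, diff, p, fdr,
#'   skipped. FDR is computed within each collection over its tested sets.
#' @export
run_collections <- function(collections, effects, null_effects,
                            min_overlap = 5L) {
  if (inherits(collections, "gene_set_collection"))
    collections <- list(sets = collections)
  out <- lapply(names(collections), function(cn) {
    coll <- collections[[cn]]
    res <- do.call(rbind, lapply(names(coll), function(sn) {
      r <- test_gene_set(coll[[sn]], effects, null_effects,
                         min_overlap = min_overlap)
      cbind(data.frame(collection = cn, set_name = sn,
                       stringsAsFactors = FALSE), r)
    }))
    res$fdr <- NA_real_
    tested <- !res$skipped
    res$fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
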