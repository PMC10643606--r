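#' Combinatorial design-space arithmetic
#'
#' Exact integer counts of the drug-combination search space and of a
#' CRISPR-drug screen's perturbation pairs. All arithmetic is exact (no
#' floating-point binomials): \code{k_combinations} uses the multiplicative
#' rule with integer division at each step.
#'
#' @param n number of drugs (>= 2).
#' @return number of unordered drug pairs, \code{n(n-1)/2}.
#' @examples
#' pairwise_combinations(600)   # 179700
#' @export
pairwise_combinations <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 1 || is.na(n) || n != floor(n) || n < 2)
    stop("n must be a single integer >= 2")
  n * (n - 1) / 2
}

#' @rdname pairwise_combinations
#' @param k subset size, \code{0 <= k <= n}.
#' @export
k_combinations <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (any(c(n, k) != floor(c(n, k))) || k < 0 || k > n)
    stop("need integers 0 <= k <= n")
  k <- min(k, n - k)
  acc <- 1
  for (i in seq_len(k)) {
    acc <- acc * (n - k + i) / i   # exact: product of i consecutive ints
  }
  round(acc)
}

#' @rdname pairwise_combinations
#' @param n_cell_lines,n_drugs,n_genes screen design dimensions (all >= 1).
#' @return \code{perturbation_pairs}: total unique combination-cell-line
#'   pairs, the product of the three design dimensions.
#' @examples
#' perturbation_pairs(18, 8, 655)   # 94320
#' @export
perturbation_pairs <- function(n_cell_lines, n_drugs, n_genes) {
  v <- c(n_cell_lines, n_drugs, n_genes)
  if (any(v != floor(v)) || any(v < 1))
    stop("all design dimensions must be integers >= 1")
  n_cell_lines * n_drugs * n_genes
}
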