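# Shared fixture builders; everything is generated in code at test time.

# small screen config: 1 drug, case + outgroup lines, optional planted effect
small_cfg <- function(n_genes = 20, n_case = 4, n_out = 2, effect = NULL,
                      seed = 42, depth = 500, guides_per_gene = 6, ...) {
  sim_config(n_genes = n_genes, guides_per_gene = guides_per_gene,
             n_nontargeting = 60,
             n_panessential_genes = 5, panessential_guides = 30,
             n_case_lines = n_case, n_outgroup_lines = n_out,
             drugs = c(doxorubicin = "dna_damage"),
             mean_depth = depth, effect_table = effect, seed = seed, ...)
}

planted_effect <- function(genes, lines, drug = "doxorubicin", delta = -1) {
  eff <- expand.grid(gene = genes, drug = drug, cell_line = lines,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$delta <- delta
  eff
}

# fast sampler settings for tests; the convergence gate still applies
fast_spec <- function(...) {
  model_spec(..., chains = 2, warmup = 400, draws = 800, adapt = 300)
}

# independent enumeration oracle for the exact two-sided rank-sum p-value:
# enumerates all choose(n1+n2, n1) assignments of the pooled ranks
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  all_sums <- apply(utils::combn(length(pooled), n1), 2,
                    function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-12)
}
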