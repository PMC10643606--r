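# Hierarchical variant sharing information across drugs (e.g. the six
# DNA-damaging agents): per-drug alpha[d], beta[d] are drawn from shared
# Normal distributions whose means mu_alpha, mu_beta are the shared
# sensitizing and differential effects of the knockout across the drug
# group. d[i] indexes the drug of observation i.
model {
  for (i in 1:N) {
    y[i] ~ dt(alpha[d[i]] + beta[d[i]] * x[i],
              1 / (se2[i] + sigma[d[i]]^2), nu)
  }
  for (j in 1:D) {
    alpha[j] ~ dnorm(mu_alpha, 1 / sigma_alpha^2)
    beta[j] ~ dnorm(mu_beta, 1 / sigma_beta^2)
    sigma[j] ~ dnorm(0, 0.04) T(0,)
  }
  mu_alpha ~ dnorm(0, 0.04)
  mu_beta ~ dnorm(0, 0.04)
  sigma_alpha ~ dnorm(0, 0.04) T(0,)
  sigma_beta ~ dnorm(0, 0.04) T(0,)
  nu ~ dgamma(2, 0.1)
}
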