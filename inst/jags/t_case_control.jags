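# Robust measurement-error model with case/outgroup selectivity.
# x[i] = 0 for case (neuroblastoma) lines, 1 for the outgroup, so alpha is
# the sensitizing potency in the case group and beta the differential effect
# outgroup-minus-case. Scale combines the known per-estimate error se2[i]
# with a shared residual sigma^2 under a Student-t of nu df.
model {
  for (i in 1:N) {
    y[i] ~ dt(alpha + beta * x[i], 1 / (se2[i] + sigma^2), nu)
  }
  alpha ~ dnorm(0, 0.04)
  beta ~ dnorm(0, 0.04)
  sigma ~ dnorm(0, 0.04) T(0,)
  nu ~ dgamma(2, 0.1)
}
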