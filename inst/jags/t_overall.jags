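# Robust measurement-error model, overall-effect variant (no group term).
# y[i]: gene-level mean log2 fold change in cell line i; se2[i]: its squared
# standard error (known). alpha is the knockout's general sensitizing effect.
# Priors: alpha ~ N(0, sd 5); sigma ~ half-N(0, sd 5); nu ~ Gamma(2, 0.1).
# When nu is supplied in the data it is held fixed (observed).
model {
  for (i in 1:N) {
    y[i] ~ dt(alpha, 1 / (se2[i] + sigma^2), nu)
  }
  alpha ~ dnorm(0, 0.04)
  sigma ~ dnorm(0, 0.04) T(0,)
  nu ~ dgamma(2, 0.1)
}
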