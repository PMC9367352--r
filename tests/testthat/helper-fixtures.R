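# Shared fixtures: reference parameter values and small simulation helpers.

table1 <- list(r = 0.01, K = 4e6, mu_A = 2e-12, a = 2e3, mu_E = 4e-5,
               p = 4e-14, c = 1e2, mu_EA = 4e-15, mu_EC = 417, b = 5e6)

# Drug-free, immune-free parameter set whose tumor equation is pure logistic.
logistic_params <- function(r = 0.01, K = 4e6) {
  model_parameters(r = r, K = K, mu_A = 0, mu_AC = 0, mu_CA = 0)
}

# Inhibition of a protocol under defaults, sharing one control per call site.
arm_inhibition <- function(name, mu_AC = NULL) {
  pr <- bundled_protocol(name)
  if (is.null(mu_AC)) mu_AC <- pr$mu_AC
  protocol_inhibition(pr, mu_AC = mu_AC)
}
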