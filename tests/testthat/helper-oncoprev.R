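# Baseline parameters used across tests; N is a per-analysis choice.
baseline_params <- function(N, ...) {
  model_params(N = N, ...)
}

# Single-type reduction: one driver class, no resistance pathway.
single_type_params <- function(s = 0.004) {
  model_params(N = 0, s = s, v = 0)
}

untreated <- treatment_policy("none")

# Relative error helper for comparisons against reported statistics.
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
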