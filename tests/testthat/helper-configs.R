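# Small shared scenario builders for the test suite.

# a scaled-down scenario that still exercises every rule
tiny_config <- function(nf = 40L, nm = 40L, ...) {
  simulation_config(n_females = nf, n_males = nm, ...)
}

# selectively neutral control: both phenotypes are parameterized as MFCL
# and the juvenile differential is off, so the tracked allele drifts
neutral_config <- function(nf = 40L, nm = 40L, p0 = 0.5, ...) {
  simulation_config(
    spillover_strategy = "MFCL", different = 1, initial = p0,
    n_females = nf, n_males = nm, environment = "rich", ...
  )
}
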