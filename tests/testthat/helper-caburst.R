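# shared fixtures: default parameter set and independent oracles

default_p <- model_params()
default_dc <- derive_constants(default_p)

# brute-force burst-length oracle: smallest cycle count at which the active
# cell's subthreshold potential has fallen to the silent cell's (switch on
# "equal to or less than"); independent of the quadratic-formula path
nspb_oracle <- function(x0, y0, p, dc, nmax = 5000) {
  for (n in seq_len(nmax)) {
    va <- vsub(ca_active(x0, n, dc), 0, p)
    vs <- vsub(ca_silent(y0, n, dc), dc$siEnd, p)
    if (va <= vs) return(as.numeric(n))
  }
  Inf
}

# cycle-by-cycle calcium recursion: spike increment then exponential decay
ca_loop <- function(a0, n, p) {
  ca <- a0
  for (i in seq_len(n)) ca <- (ca + p$dCa) * exp(-p$kCa * p$t3)
  ca
}
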