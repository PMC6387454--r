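# Independent oracles and shared fixtures for the test suite.

# Brute-force fixed-point steady state of the inversion-prepared pulse
# train: literal cycle-by-cycle simulation of inversion, free relaxation,
# discrete pulses and inter-pulse recovery, iterated until the start-of-cycle
# magnetisation stops changing at machine precision. Independent of the
# closed-form geometric-series solution it checks.
brix_fixed_point <- function(s0, r1, k, seq, max_cycles = 20000L,
                             tol = 1e-14) {
  a <- k * seq$flip * pi / 180
  r <- seq$readout_index
  tau <- seq$echo_spacing
  n <- seq$train_length
  t1 <- seq$ti - (r - 1) * tau
  t2 <- seq$tr - t1 - (n - 1) * tau
  relax <- function(m, t) 1 + (m - 1) * exp(-r1 * t)
  m <- 1
  mr <- NA_real_
  for (cyc in seq_len(max_cycles)) {
    m_prev <- m
    m <- relax(-m, t1)
    for (j in seq_len(n)) {
      if (j == r) mr <- m
      m <- m * cos(a)
      if (j < n) m <- relax(m, tau)
    }
    m <- relax(m, t2)
    if (cyc > 1L && abs(m - m_prev) <= tol * max(abs(m), 1e-300)) break
  }
  s0 * sin(a) * mr
}

# Protocol fixtures (loaded once per test file)
study_protocol <- function() protocol_preset("study_3t")

hifi_seqs <- function(proto = study_protocol())
  proto[c("irsgre_long", "irsgre_short", "sgre_fa12", "sgre_fa5", "sgre_fa3")]

irse_seqs <- function(proto = study_protocol())
  proto[grep("^irse_", names(proto))]

# Forward HIFI signal vector for a parameter triple
hifi_signals <- function(s0, r1, k, seqs, model = "brix")
  vapply(seqs, function(sq)
    predict_signal(sq, s0 = s0, r1 = r1, k = k, model = model), 0)
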