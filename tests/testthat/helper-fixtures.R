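# shared fixtures, all generated in code

default_schedule <- function() build_schedule()

# simulate one hgf2 agent on the default schedule and return everything needed
# for a fit
make_agent <- function(omega = -3, zeta = 2, seed = 1, sched = default_schedule(),
                       missing_rate = 0) {
  u <- sample_outcomes(sched, seed = seed)
  sim <- simulate_agent(sched, u, "hgf2", list(omega = omega, zeta = zeta),
                        seed = seed + 5000, missing_rate = missing_rate)
  list(sched = sched, u = u, sim = sim)
}

# a long single-stream outcome sequence with probability reversals
long_outcomes <- function(n_blocks, block_len, p = 0.8, seed = 1) {
  set.seed(seed)
  unlist(lapply(seq_len(n_blocks), function(b) {
    pp <- if (b %% 2 == 1) p else 1 - p
    rbinom(block_len, 1, pp)
  }))
}
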