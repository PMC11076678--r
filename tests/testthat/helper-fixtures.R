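# short configurations shared across tests; scientific defaults (30 s,
# 20 repeats) are exercised in the acceptance suite
quick_sim <- function(duration = 6, n_repeats = 2, seed = 1, ...) {
  simulation_config(duration = duration, n_repeats = n_repeats, seed = seed,
                    ...)
}

# pure-R restatement of the right-hand side, kept independent of the
# compiled core it checks
rhs_reference <- function(state, p, drive) {
  te <- p$tau_e / 1000; ti <- p$tau_i / 1000
  S <- function(v) 2 * p$e0 / (1 + exp(-p$nu * (v - p$s0)))
  v_trn <- if (identical(p$trn_input, "trn_self"))
    p$C1 * state[5] else p$C1 * state[3]
  unname(c(state[2],
    (p$H_e / te) * drive - (2 / te) * state[2] - state[1] / te^2,
    state[4],
    (p$H_e / te) * S(p$C3 * state[1] - p$C2 * state[5]) -
      (2 / te) * state[4] - state[3] / te^2,
    state[6],
    (p$H_i / ti) * S(v_trn) - (2 / ti) * state[6] - state[5] / ti^2))
}
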