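# Shared fixtures, built in code.

# default-design trial for a given seed (optionally noise free)
make_trial <- function(seed = 1, noise_scale = 1, ...) {
  generate_trial(trial_config(seed = seed),
                 sim_truth(noise_scale = noise_scale, ...))
}

# independent re-derivation of the lipid-correction algebra, written as
# plain sequential arithmetic (oracle for the closed form)
oracle_lipid_correction <- function(delta, cn, D = 7.018, I = 0.048,
                                    a = 0.246, b = 0.775) {
  x <- a * cn - b
  L <- 93 / (1 + 1 / x)
  inner <- 287 / L
  delta + D * (I + 3.90 / (1 + inner))
}

# per-fish TDF table generated directly from arm-level parameters
# (bypasses the full trial machinery; used by the mixed-model tests)
make_deltas <- function(arm_means, arm_sds, arm_ns, tank_sd = 0,
                        diets = c("high_lipid", "low_lipid"),
                        temps = c(6, 8, 10, 12)) {
  arms <- expand.grid(diet = diets, temperature = temps,
                      stringsAsFactors = FALSE)
  arms <- arms[order(arms$diet, arms$temperature), ]
  do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    n <- arm_ns[i]
    tank <- paste0(arms$diet[i], "_T", arms$temperature[i], "_",
                   rep_len(1:2, n))
    eff <- rnorm(2, 0, tank_sd)[rep_len(1:2, n)]
    data.frame(fish_id = seq_len(n), tank = tank, diet = arms$diet[i],
               temperature = arms$temperature[i], isotope = "d15n",
               delta = arm_means[i] + eff + rnorm(n, 0, arm_sds[i]),
               stringsAsFactors = FALSE)
  }))
}
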