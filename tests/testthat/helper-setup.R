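# Shared fixtures: the canonical live-looker geometry and small builders.

geom165 <- gaze_geometry(165)

exp1_design <- function(reps = 25) {
  exponential_stimulus_design(2.5, 4, geom165, repetitions = reps)
}

# Expected "looked at" proportions for an observer on a design, as a
# proportions table with a large common trial count (noise-free input for
# fits that should recover generative parameters exactly up to binomial
# rounding of counts -- use counts that make the proportions exact).
expected_proportions <- function(obs, directions, sides, n_per = 1000) {
  p <- p_direct(directions, obs, sides = sides)
  data.frame(gaze_deg = directions, n_trials = n_per,
             n_direct = round(n_per * p))
}
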