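# Shared fixtures: corpus configurations scaled for test speed, built in
# code at test time.

# Small corpus with the default noise structure (124 tokens).
smallConfig <- function(reps_per_pair = 2L, ...) {
    corpusConfig(n_female = 1L, n_male = 1L,
                 reps_per_pair = reps_per_pair, ...)
}

# Noise-free corpus with widely separated tone targets: every stochastic
# knob off, targets far apart, and a fast time constant so the carryover
# transient dies out early and classes stay separated in contour space.
# Both recognizers should reach the 100% ceiling here.
separableConfig <- function(n_female = 2L, n_male = 2L, reps_per_pair = 3L) {
    corpusConfig(
        n_female = n_female, n_male = n_male, reps_per_pair = reps_per_pair,
        tone_targets = matrix(c(0, 20,
                                60, -10,
                                -10, -25,
                                -80, 12),
                              nrow = 4L, byrow = TRUE,
                              dimnames = list(paste0("T", 1:4), c("m", "b"))),
        tau = 0.01, noise_sd = 0, target_m_sd = 0, target_b_sd = 0,
        speaker_jitter_sd = 0, onset_jitter_sd = 0)
}

# One-point grid: fixed hyperparameters, no CV search.
fixedGrid <- function(cost = 8, gamma = 2^-3) svmGrid(cost, gamma)

# Deterministic pseudo-random contour set for fit oracles.
randomContours <- function(n, seed, sd = 3) {
    set.seed(seed)
    t(replicate(n, {
        base <- runif(1, 80, 95)
        base + cumsum(rnorm(30, 0, sd / 6)) + rnorm(30, 0, sd / 10)
    }))
}
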