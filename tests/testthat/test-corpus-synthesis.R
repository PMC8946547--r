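test_that("speaker profiles respect counts, genders and determinism", {
    p <- makeSpeakerProfiles(4, 4, seed = 42)
    expect_equal(nrow(p), 8L)
    expect_equal(sum(p$gender == "female"), 4L)
    expect_equal(sum(p$gender == "male"), 4L)
    expect_identical(p, makeSpeakerProfiles(4, 4, seed = 42))
    expect_gt(min(p$base_pitch_st[p$gender == "female"]),
              max(p$base_pitch_st[p$gender == "male"]))
    p1 <- makeSpeakerProfiles(1, 0, seed = 1)
    expect_equal(nrow(p1), 1L)
    expect_identical(p1$gender, "female")
    expect_error(makeSpeakerProfiles(0, 0), "at least one")
})

test_that("synthesized sequences transfer f0 state across the boundary", {
    cfg <- smallConfig(noise_sd = 0)
    sp <- makeSpeakerProfiles(1, 0, seed = 5, config = cfg)[1, ]
    syn <- synthesizeSequence(c(1, 4), sp, config = cfg, seed = 9)
    expect_equal(dim(syn$f0), c(30L, 2L))
    ## noise-free: syllable 2 starts exactly where syllable 1 ended
    expect_equal(syn$f0[30, 1], syn$f0[1, 2], tolerance = 1e-9)
    expect_identical(syn$tokens$tone, c(1L, 4L))
    expect_identical(syn$tokens$prev_tone, c(NA_integer_, 1L))
    expect_identical(syn$tokens$position, 1:2)
    ## determinism
    syn2 <- synthesizeSequence(c(1, 4), sp, config = cfg, seed = 9)
    expect_identical(syn$f0, syn2$f0)
})

test_that("mean synthetic shapes match the canonical tone contours", {
    corpus <- buildCorpus(smallConfig(reps_per_pair = 4L), seed = 13)
    f0 <- f0Samples(corpus)
    cd <- SummarizedExperiment::colData(corpus)
    ## second-syllable tokens have settled near their targets
    mean_shape <- function(t)
        rowMeans(f0[, cd$tone == t & cd$position == 2L, drop = FALSE])
    t2 <- mean_shape(2); t4 <- mean_shape(4)
    expect_gt(t2[30], t2[1])     # Tone 2 rises
    expect_lt(t4[30], t4[1])     # Tone 4 falls
    ## compare the settled second half (the onset region carries the
    ## previous tone's state): Tone 1 is level there, Tone 4 keeps falling
    t1 <- mean_shape(1); t3 <- mean_shape(3)
    expect_lt(abs(t1[30] - t1[15]), abs(t4[30] - t4[15]))
    expect_lt(mean(t3[20:30]), mean(t1[20:30]))          # Tone 3 low
})

test_that("corpus construction reproduces the token-count arithmetic", {
    corpus <- buildCorpus(smallConfig(), seed = 1)
    counts <- tabulate(toneLabels(corpus), 4L)
    ## 2 speakers x 2 reps x 8 (pair, position) slots = 32 per tone;
    ## Tone 3 loses the (3,3) first-syllable slot: 7/8 of 32 = 28
    expect_equal(counts, c(32L, 32L, 28L, 32L))
    no_excl <- buildCorpus(smallConfig(exclude_sandhi = FALSE), seed = 1)
    expect_equal(tabulate(toneLabels(no_excl), 4L), rep(32L, 4L))
    ## the only removed tokens are first-syllable T3 before T3
    cd <- SummarizedExperiment::colData(no_excl)
    removed <- cd$position == 1L & cd$tone == 3L &
        cd$seq_id %in% cd$seq_id[cd$position == 2L & cd$tone == 3L &
                                 cd$prev_tone == 3L]
    expect_equal(sum(removed), 4L)
    expect_setdiff <- setdiff(cd$token_id[!removed],
                              SummarizedExperiment::colData(corpus)$token_id)
    expect_length(expect_setdiff, 0L)
})

test_that("corpus generation is a pure function of (config, seed)", {
    a <- buildCorpus(smallConfig(), seed = 77)
    b <- buildCorpus(smallConfig(), seed = 77)
    expect_identical(f0Samples(a), f0Samples(b))
    expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                     as.data.frame(SummarizedExperiment::colData(b)))
    c <- buildCorpus(smallConfig(), seed = 78)
    expect_false(identical(f0Samples(a), f0Samples(c)))
    ## all semitone samples finite, Hz version positive
    expect_true(all(is.finite(f0Samples(a))))
    expect_true(all(f0Samples(convertScale(a, "hz")) > 0))
})

test_that("female tokens sit above male tokens on the Hz scale", {
    corpus <- convertScale(buildCorpus(smallConfig(), seed = 4), "hz")
    cd <- SummarizedExperiment::colData(corpus)
    f0 <- f0Samples(corpus)
    expect_gt(mean(f0[, cd$gender == "female"]),
              mean(f0[, cd$gender == "male"]))
})

test_that("splitting assigns every token once at the stated ratio", {
    corpus <- buildCorpus(smallConfig(), seed = 6)
    sp <- splitCorpus(corpus, seed = 10)
    split <- corpusSplit(sp)
    expect_false(any(is.na(split)))
    expect_equal(sum(split == "train"), round(2 / 3 * ncol(corpus)))
    ## smallest exact case and the full-size arithmetic
    tiny <- corpus[, 1:3]
    tiny_split <- corpusSplit(splitCorpus(tiny, seed = 1))
    expect_equal(sum(tiny_split == "train"), 2L)
    expect_equal(sum(tiny_split == "test"), 1L)
    expect_equal(round(5456 * 2 / 3), 3637)   # frozen split arithmetic
    ## determinism
    expect_identical(corpusSplit(splitCorpus(corpus, seed = 10)), split)
    expect_error(splitCorpus(corpus, ratio = c(0, 1)), "ratio")
    expect_error(splitCorpus(corpus[, 0]), "empty")
})

test_that("invalid configurations are rejected with the offending keys", {
    expect_error(corpusConfig(n_female = 0, n_male = 0), "n_female")
    expect_error(corpusConfig(tau = -1), "tau")
    expect_error(corpusConfig(tone_targets = matrix(0, 2, 2)),
                 "tone_targets")
})
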