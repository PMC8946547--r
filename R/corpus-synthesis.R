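## Synthetic disyllabic tone corpus: a qTA forward model per syllable,
## gender-specific speaker registers, cross-syllable f0 carryover, the
## Tone3+Tone3 sandhi-context exclusion, and a seeded 2:1 train/test split.

## Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(force(expr))
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

## Fast forward synthesis without S4 dispatch (third-order response).
.qtaForwardFast <- function(m, b, tau, onset_f0, onset_deriv, tt) {
    c0 <- onset_f0 - b
    c1 <- onset_deriv[1L] - m + c0 / tau
    c2 <- (onset_deriv[2L] + 2 * c1 / tau - c0 / tau^2) / 2
    m * tt + b + (c0 + c1 * tt + c2 * tt^2) * exp(-tt / tau)
}

#' Default configuration of the synthetic tone corpus
#'
#' The defaults emulate the structure of the study corpus the analysis
#' assumes: 4 female + 4 male speakers with distinct pitch registers, all
#' 16 ordered disyllabic tone pairs, 22 repetitions per pair per speaker
#' (so that each tone fills 8 (pair, position) slots x 8 speakers x 22 =
#' 1408 tokens before exclusion), Gaussian sample noise and per-token
#' target perturbation, and exclusion of first-syllable Tone 3 before
#' another Tone 3 (the tone-sandhi context).
#'
#' Tone targets are `(m, b)` pairs — slope in st/s and offset in st
#' relative to the speaker's mid pitch — chosen so the mean synthetic
#' shapes are level (T1), rising (T2), low (T3) and falling (T4).
#'
#' @param n_female,n_male speaker counts.
#' @param reps_per_pair repetitions of each ordered tone pair per speaker.
#' @param n_samples f0 samples per syllable (time-normalized length).
#' @param duration_s nominal syllable duration in seconds.
#' @param tone_targets 4 x 2 matrix, rows = tones, columns `m` (st/s) and
#'   `b` (st re speaker mid).
#' @param tau time constant of target approach, seconds.
#' @param noise_sd i.i.d. Gaussian noise per semitone sample, st.
#' @param target_m_sd,target_b_sd per-token Gaussian perturbation of the
#'   target slope/offset.
#' @param female_base_st,male_base_st gender mean mid pitches, st re 1 Hz
#'   (defaults: 220 Hz and 120 Hz).
#' @param speaker_jitter_sd per-speaker jitter of the mid pitch, st.
#' @param range_scale multiplier on tone-target excursions (all speakers).
#' @param onset_jitter_sd Gaussian jitter of sequence-initial onset f0, st.
#' @param exclude_sandhi drop first-syllable Tone 3 tokens followed by
#'   Tone 3.
#' @return A named list of class `corpusConfig`.
#' @export
corpusConfig <- function(n_female = 4L, n_male = 4L, reps_per_pair = 22L,
                         n_samples = 30L, duration_s = 0.25,
                         tone_targets = defaultToneTargets(), tau = 0.03,
                         noise_sd = 0.5, target_m_sd = 4, target_b_sd = 1,
                         female_base_st = 12 * log2(220),
                         male_base_st = 12 * log2(120),
                         speaker_jitter_sd = 1.5, range_scale = 1,
                         onset_jitter_sd = 1, exclude_sandhi = TRUE) {
    cfg <- list(n_female = as.integer(n_female), n_male = as.integer(n_male),
                reps_per_pair = as.integer(reps_per_pair),
                n_samples = as.integer(n_samples), duration_s = duration_s,
                tone_targets = tone_targets, tau = tau, noise_sd = noise_sd,
                target_m_sd = target_m_sd, target_b_sd = target_b_sd,
                female_base_st = female_base_st, male_base_st = male_base_st,
                speaker_jitter_sd = speaker_jitter_sd,
                range_scale = range_scale, onset_jitter_sd = onset_jitter_sd,
                exclude_sandhi = isTRUE(exclude_sandhi))
    bad <- c(
        if (cfg$n_female < 0L || cfg$n_male < 0L ||
            cfg$n_female + cfg$n_male < 1L) "n_female/n_male",
        if (cfg$reps_per_pair < 1L) "reps_per_pair",
        if (cfg$n_samples < 2L) "n_samples",
        if (cfg$duration_s <= 0) "duration_s",
        if (!is.matrix(cfg$tone_targets) ||
            !identical(dim(cfg$tone_targets), c(4L, 2L))) "tone_targets",
        if (cfg$tau <= 0) "tau",
        if (cfg$noise_sd < 0) "noise_sd",
        if (cfg$range_scale <= 0) "range_scale")
    if (length(bad))
        stop("invalid corpus configuration key(s): ", paste(bad, collapse = ", "))
    structure(cfg, class = "corpusConfig")
}

#' @rdname corpusConfig
#' @export
defaultToneTargets <- function() {
    matrix(c(0, 4,      # T1 high-level
             32, -2,    # T2 rising
             -8, -6,    # T3 low
             -48, 6),   # T4 falling
           nrow = 4L, byrow = TRUE,
           dimnames = list(paste0("T", 1:4), c("m", "b")))
}

#' Draw speaker profiles with gender-specific pitch registers
#'
#' Mid pitches are drawn around the gender means of the configuration with
#' per-speaker jitter, leaving the female registers above the male ones
#' (the individual pitch-height differences the raw Hz/semitone scales
#' retain, in the absence of any speaker normalization).
#'
#' @param n_female,n_male nonnegative speaker counts (at least one total).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param config a [corpusConfig()].
#' @return data.frame: `speaker_id`, `gender`, `base_pitch_st`,
#'   `range_scale`.
#' @export
makeSpeakerProfiles <- function(n_female = 4L, n_male = 4L, seed = NULL,
                                config = corpusConfig()) {
    if (n_female < 0L || n_male < 0L || n_female + n_male < 1L)
        stop("need at least one speaker")
    .withSeed(seed, {
        ids <- c(if (n_female) sprintf("F%d", seq_len(n_female)),
                 if (n_male) sprintf("M%d", seq_len(n_male)))
        gender <- rep(c("female", "male"), c(n_female, n_male))
        base <- ifelse(gender == "female", config$female_base_st,
                       config$male_base_st) +
            rnorm(n_female + n_male, 0, config$speaker_jitter_sd)
        data.frame(speaker_id = ids, gender = gender, base_pitch_st = base,
                   range_scale = rep(config$range_scale, n_female + n_male))
    })
}

#' Synthesize one disyllabic tone sequence for one speaker
#'
#' Syllable 1 starts at the speaker's mid pitch plus a small random
#' perturbation with zero onset derivatives; the terminal f0 state of the
#' (noise-free) syllable-1 response is transferred to syllable 2's onset,
#' modelling articulatory carryover.  Per-token Gaussian perturbations of
#' `(m, b)` and i.i.d. Gaussian sample noise (all in the semitone domain)
#' are applied per the configuration.
#'
#' @param tone_pair integer pair, tones of syllables 1 and 2.
#' @param speaker one row of [makeSpeakerProfiles()] output.
#' @param rep_index integer repetition index (used in token ids).
#' @param config a [corpusConfig()].
#' @param seed optional integer seed.
#' @return List with `f0` (`n_samples x 2` semitone matrix) and `tokens`
#'   (2-row metadata data.frame).
#' @export
synthesizeSequence <- function(tone_pair, speaker, rep_index = 1L,
                               config = corpusConfig(), seed = NULL) {
    stopifnot(length(tone_pair) == 2L, all(tone_pair %in% .TONES))
    .withSeed(seed, {
        tt <- seq(0, config$duration_s, length.out = config$n_samples)
        seq_id <- sprintf("%s_p%d%d_r%03d", speaker$speaker_id,
                          tone_pair[1L], tone_pair[2L], rep_index)
        onset <- speaker$base_pitch_st + rnorm(1L, 0, config$onset_jitter_sd)
        deriv <- c(0, 0)
        f0 <- matrix(0, config$n_samples, 2L)
        tokens <- vector("list", 2L)
        for (k in 1:2) {
            tone <- tone_pair[k]
            m <- config$tone_targets[tone, "m"] * speaker$range_scale +
                rnorm(1L, 0, config$target_m_sd)
            b <- speaker$base_pitch_st +
                config$tone_targets[tone, "b"] * speaker$range_scale +
                rnorm(1L, 0, config$target_b_sd)
            clean <- .qtaForwardFast(m, b, config$tau, onset, deriv, tt)
            f0[, k] <- clean + rnorm(config$n_samples, 0, config$noise_sd)
            tokens[[k]] <- data.frame(
                token_id = sprintf("%s_s%d", seq_id, k),
                speaker_id = speaker$speaker_id, seq_id = seq_id,
                gender = speaker$gender, tone = as.integer(tone),
                position = as.integer(k),
                prev_tone = if (k == 1L) NA_integer_
                            else as.integer(tone_pair[1L]),
                scale = "semitone", duration_s = config$duration_s,
                split = NA_character_)
            cc <- .qtaCoefs(m, b, config$tau, onset, deriv)
            term <- .qtaStateAt(m, b, config$tau, cc, config$duration_s)
            onset <- term[1L]
            deriv <- term[-1L]
        }
        list(f0 = f0, tokens = do.call(rbind, tokens))
    })
}

#' Build the full synthetic disyllabic tone corpus
#'
#' Generates all 16 ordered tone pairs x repetitions x speakers, extracts
#' both syllables of every sequence as tokens, and (by default) removes
#' first-syllable Tone 3 tokens followed by another Tone 3 — the context in
#' which tone sandhi would distort the tone's canonical shape.  Under the
#' default configuration this yields 1408 tokens each for Tones 1, 2 and 4
#' and 1232 for Tone 3.  The result is a pure function of
#' `(config, seed)`.
#'
#' @param config a [corpusConfig()].
#' @param seed integer seed for all randomness.
#' @return A [ToneCorpus-class] on the semitone scale, split unset.
#' @examples
#' small <- buildCorpus(corpusConfig(n_female = 1, n_male = 1,
#'                                   reps_per_pair = 2), seed = 1)
#' table(toneLabels(small))
#' @export
buildCorpus <- function(config = corpusConfig(), seed = 1L) {
    stopifnot(inherits(config, "corpusConfig"))
    .withSeed(seed, {
        speakers <- makeSpeakerProfiles(config$n_female, config$n_male,
                                        seed = NULL, config = config)
        pairs <- expand.grid(t1 = .TONES, t2 = .TONES,
                             KEEP.OUT.ATTRS = FALSE)
        n_seq <- nrow(speakers) * nrow(pairs) * config$reps_per_pair
        f0 <- matrix(0, config$n_samples, 2L * n_seq)
        tokens <- vector("list", n_seq)
        s <- 0L
        for (sp in seq_len(nrow(speakers))) {
            for (p in seq_len(nrow(pairs))) {
                for (r in seq_len(config$reps_per_pair)) {
                    s <- s + 1L
                    syn <- synthesizeSequence(
                        c(pairs$t1[p], pairs$t2[p]), speakers[sp, ],
                        rep_index = r, config = config, seed = NULL)
                    f0[, c(2L * s - 1L, 2L * s)] <- syn$f0
                    tokens[[s]] <- syn$tokens
                }
            }
        }
        tokens <- do.call(rbind, tokens)
        if (config$exclude_sandhi) {
            keep <- !(tokens$position == 1L & tokens$tone == 3L &
                      c(tokens$tone[-1L], NA_integer_) == 3L)
            ## position-1 rows are always directly followed by their
            ## position-2 sibling, so the lead-by-one tone is the next tone
            f0 <- f0[, keep, drop = FALSE]
            tokens <- tokens[keep, , drop = FALSE]
        }
        ToneCorpus(f0, tokens, speakers = speakers, config = config,
                   seed = as.integer(seed))
    })
}

#' Randomly assign corpus tokens to train and test splits
#'
#' Tokens are assigned at random in the given ratio (2:1 by default); with
#' `n` tokens the training split receives `round(n * r1 / (r1 + r2))`
#' tokens, so 5456 tokens at 2:1 give 3637 train and 1819 test.
#'
#' @param corpus a [ToneCorpus-class].
#' @param ratio positive numeric pair `(train_parts, test_parts)`.
#' @param seed integer seed.
#' @return The corpus with `corpusSplit()` set for every token.
#' @export
splitCorpus <- function(corpus, ratio = c(2, 1), seed = 1L) {
    stopifnot(methods::is(corpus, "ToneCorpus"))
    if (ncol(corpus) == 0L)
        stop("cannot split an empty corpus")
    if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
        stop("degenerate split ratio")
    n <- ncol(corpus)
    n_train <- round(n * ratio[1L] / sum(ratio))
    split <- rep("test", n)
    split[.withSeed(seed, sample(n, n_train))] <- "train"
    corpusSplit(corpus) <- split
    corpus
}
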