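#' @import methods
#' @importFrom stats approx optim rnorm runif sd predict
#' @importFrom utils read.csv write.csv
#' @useDynLib ToneContours, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ToneCorpus: a corpus of syllable-sized f0 contours
#'
#' A `ToneCorpus` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one token per column.  The single assay, `"f0"`, is a
#' `n_points x n_tokens` matrix of time-normalized f0 samples (30 points by
#' default), either in Hz or in semitones re 1 Hz.  Per-token metadata live
#' in `colData`:
#'
#' * `token_id`, `speaker_id`, `seq_id` — identifiers (the `seq_id` groups
#'   the two syllables of one disyllabic sequence),
#' * `gender` — `"female"` or `"male"`,
#' * `tone` — integer 1..4 (Mandarin high-level, rising, low, falling),
#' * `position` — 1 or 2 (syllable within the disyllabic sequence),
#' * `prev_tone` — tone of the preceding syllable (`NA` for position 1),
#' * `scale` — `"hz"` or `"semitone"`,
#' * `duration_s` — nominal physical duration of the syllable in seconds,
#' * `split` — `"train"`, `"test"`, or `NA` before [splitCorpus()].
#'
#' `metadata()` carries the speaker table, the generating configuration and
#' seed when the corpus is synthetic.
#'
#' @seealso [buildCorpus()], [splitCorpus()], [f0Samples()]
#' @name ToneCorpus-class
#' @aliases ToneCorpus-class
#' @exportClass ToneCorpus
setClass("ToneCorpus", contains = "SummarizedExperiment")

.TONES <- 1:4
.REQUIRED_COLDATA <- c("token_id", "speaker_id", "seq_id", "gender", "tone",
                       "position", "prev_tone", "scale", "duration_s", "split")

setValidity("ToneCorpus", function(object) {
    msg <- character()
    if (!"f0" %in% SummarizedExperiment::assayNames(object))
        return("assay 'f0' is missing")
    f0 <- SummarizedExperiment::assay(object, "f0")
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(.REQUIRED_COLDATA, colnames(cd))
    if (length(missing_cols))
        return(paste("colData misses column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (ncol(object) == 0L)
        return(TRUE)
    if (!all(is.finite(f0)))
        msg <- c(msg, "all f0 samples must be finite")
    if (anyDuplicated(cd$token_id))
        msg <- c(msg, "token_id values must be unique")
    if (!all(cd$scale %in% c("hz", "semitone")))
        msg <- c(msg, "scale must be 'hz' or 'semitone'")
    hz <- which(cd$scale == "hz")
    if (length(hz) && any(f0[, hz] <= 0))
        msg <- c(msg, "Hz-scale samples must be positive")
    if (!all(cd$tone %in% .TONES))
        msg <- c(msg, "tone must be in 1..4")
    if (!all(cd$position %in% c(1L, 2L)))
        msg <- c(msg, "position must be 1 or 2")
    p2 <- cd$position == 2L
    if (any(p2 & is.na(cd$prev_tone)))
        msg <- c(msg, "position-2 tokens must carry prev_tone")
    if (!all(is.na(cd$prev_tone) | cd$prev_tone %in% .TONES))
        msg <- c(msg, "prev_tone must be NA or in 1..4")
    if (!all(cd$duration_s > 0))
        msg <- c(msg, "duration_s must be positive")
    if (!all(is.na(cd$split) | cd$split %in% c("train", "test")))
        msg <- c(msg, "split must be NA, 'train' or 'test'")
    if (length(msg)) msg else TRUE
})

#' Construct a ToneCorpus from an f0 matrix and token metadata
#'
#' @param f0 numeric matrix, `n_points x n_tokens`, f0 samples per token.
#' @param tokens data.frame (or DataFrame) of per-token metadata with the
#'   columns documented in [ToneCorpus-class]; a missing `split` column is
#'   filled with `NA`.
#' @param speakers optional data.frame of speaker profiles (see
#'   [makeSpeakerProfiles()]); stored in `metadata()`.
#' @param config,seed optional generating configuration and seed, stored in
#'   `metadata()` for provenance.
#' @return A [ToneCorpus-class] object.
#' @export
ToneCorpus <- function(f0, tokens, speakers = NULL, config = NULL, seed = NULL) {
    f0 <- as.matrix(f0)
    tokens <- as.data.frame(tokens)
    if (!"split" %in% colnames(tokens))
        tokens$split <- NA_character_
    if (!"seq_id" %in% colnames(tokens))
        tokens$seq_id <- tokens$token_id
    if (nrow(tokens) != ncol(f0))
        stop("tokens must have one row per f0 column")
    colnames(f0) <- tokens$token_id
    if (nrow(f0) > 0)
        rownames(f0) <- sprintf("v%02d", seq_len(nrow(f0)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(f0 = f0),
        colData = S4Vectors::DataFrame(tokens, row.names = tokens$token_id),
        metadata = list(speakers = speakers, config = config, seed = seed))
    methods::new("ToneCorpus", se)
}

#' RecognitionResult: outcome of one tone-recognition experiment
#'
#' Holds the evaluated accuracy of one recognition scheme on the test split
#' of a corpus, together with the row-normalized confusion matrix, the raw
#' truth/prediction vectors (so every figure can be recomputed), and run
#' metadata.  Unlabelled predictions (a SOM test token landing on an
#' uncategorized unit, or a five-level code with no tone) are `NA` in
#' `predicted` and are counted as errors.
#'
#' @slot scheme character, one of `full_contour`, `two_level`, `five_level`,
#'   `profile`, `qta`.
#' @slot scale character, `"hz"` or `"semitone"`.
#' @slot recognizer character, `"svm"` or `"som"`.
#' @slot mode character, `"separate"`/`"together"` for level schemes else `NA`.
#' @slot cue_pair character, stylization cue pair for the profile scheme.
#' @slot include_onset logical, qTA scheme only.
#' @slot n_train,n_test integer sizes of the two splits.
#' @slot accuracy_pct overall (micro) test accuracy, percent.
#' @slot macro_accuracy_pct mean of the four per-tone accuracies, percent.
#' @slot per_tone_accuracy_pct named numeric(4), percent.
#' @slot confusion 4 x 5 matrix of row percentages (columns T1..T4 plus
#'   `none` for unlabelled predictions); each row sums to 100.
#' @slot truth,predicted integer vectors over the test tokens.
#' @slot seed integer seed used for the run.
#' @slot hyperparameters list of chosen recognizer settings.
#' @slot complexity list with the scheme's testing-phase operation-count
#'   `expression` and evaluated `value`.
#' @name RecognitionResult-class
#' @exportClass RecognitionResult
setClass("RecognitionResult",
    representation(scheme = "character", scale = "character",
                   recognizer = "character", mode = "character",
                   cue_pair = "character", include_onset = "logical",
                   n_train = "integer", n_test = "integer",
                   accuracy_pct = "numeric", macro_accuracy_pct = "numeric",
                   per_tone_accuracy_pct = "numeric", confusion = "matrix",
                   truth = "integer", predicted = "integer",
                   seed = "integer", hyperparameters = "list",
                   complexity = "list"))

setValidity("RecognitionResult", function(object) {
    msg <- character()
    if (length(object@truth) != length(object@predicted))
        msg <- c(msg, "truth and predicted lengths differ")
    if (object@accuracy_pct < 0 || object@accuracy_pct > 100)
        msg <- c(msg, "accuracy_pct out of [0, 100]")
    rs <- rowSums(object@confusion)
    occupied <- tabulate(object@truth, 4L) > 0
    if (any(abs(rs[occupied] - 100) > 1e-6))
        msg <- c(msg, "confusion rows must sum to 100")
    if (length(msg)) msg else TRUE
})

#' QtaTarget: an underlying pitch target with its initial state
#'
#' The quantitative target-approximation (qTA) model drives syllable f0
#' toward a linear pitch target `x(t) = m t + b` through a critically damped
#' third-order (by default) dynamic response: `f0(t) = (m t + b) +
#' (c0 + c1 t + ... + c_{N-1} t^{N-1}) exp(-t / tau)`.  The transient
#' coefficients are never stored: they are fully determined by the target
#' and the f0 state (value and `N - 1` derivatives) at syllable onset.
#'
#' @slot m numeric, target slope in st/s.
#' @slot b numeric, target offset in st (relative to the ambient reference;
#'   the speaker's mid pitch during synthesis, 0 for utterance-mean
#'   normalized contours during fitting).
#' @slot tau positive numeric, time constant of target approach in seconds.
#' @slot response_order integer `N >= 1`, number of transient coefficients.
#' @slot onset_f0 numeric, f0 in st at syllable start.
#' @slot onset_deriv numeric of length `N - 1`: f0 derivatives at syllable
#'   start (st/s, st/s^2, ...).
#' @seealso [qtaForward()], [fitQta()]
#' @name QtaTarget-class
#' @exportClass QtaTarget
setClass("QtaTarget",
    representation(m = "numeric", b = "numeric", tau = "numeric",
                   response_order = "integer", onset_f0 = "numeric",
                   onset_deriv = "numeric"))

setValidity("QtaTarget", function(object) {
    msg <- character()
    if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0)
        msg <- c(msg, "tau must be a single positive number")
    if (object@response_order < 1L)
        msg <- c(msg, "response_order must be >= 1")
    if (length(object@onset_deriv) != object@response_order - 1L)
        msg <- c(msg, "onset_deriv must have length response_order - 1")
    if (!all(is.finite(c(object@m, object@b, object@onset_f0,
                         object@onset_deriv))))
        msg <- c(msg, "all target fields must be finite")
    if (length(msg)) msg else TRUE
})

#' @param m,b,tau,onset_f0 target slope (st/s), offset (st), time constant
#'   (s) and onset f0 (st).
#' @param onset_deriv onset f0 derivatives, length `response_order - 1`.
#' @param response_order order `N` of the transient polynomial.
#' @rdname QtaTarget-class
#' @export
QtaTarget <- function(m, b, tau, onset_f0 = b, onset_deriv = c(0, 0),
                      response_order = length(onset_deriv) + 1L) {
    methods::new("QtaTarget", m = as.numeric(m), b = as.numeric(b),
                 tau = as.numeric(tau),
                 response_order = as.integer(response_order),
                 onset_f0 = as.numeric(onset_f0),
                 onset_deriv = as.numeric(onset_deriv))
}

#' ParabolaFit: least-squares parabola stylization of a contour
#'
#' Coefficients of the mean-centered quadratic basis
#' `{1, (t - 1/2), (t - 1/2)^2 - 1/12}` over unit-normalized time.  `c1` is
#' the slope cue and `c2` the curve cue of the profile representation.
#'
#' @slot c0,c1,c2 numeric basis coefficients (st, st per unit time, st per
#'   unit time squared).
#' @slot rss nonnegative numeric, residual sum of squares.
#' @seealso [fitParabola()]
#' @name ParabolaFit-class
#' @exportClass ParabolaFit
setClass("ParabolaFit",
    representation(c0 = "numeric", c1 = "numeric", c2 = "numeric",
                   rss = "numeric"))

setValidity("ParabolaFit", function(object) {
    if (object@rss < -1e-12) "rss must be nonnegative" else TRUE
})

#' BrokenLineFit: two-piece linear stylization with a free breakpoint
#'
#' Independent least-squares lines on `t < d` and `t >= d`, with the
#' breakpoint `d` (unit-normalized time) chosen on the interior sample grid
#' to minimize the total residual sum of squares.
#'
#' @slot a1,b1 numeric, intercept/slope of the left piece.
#' @slot a2,b2 numeric, intercept/slope of the right piece.
#' @slot d numeric in (0, 1), breakpoint position.
#' @slot rss nonnegative numeric, total residual sum of squares.
#' @seealso [fitBrokenLine()]
#' @name BrokenLineFit-class
#' @exportClass BrokenLineFit
setClass("BrokenLineFit",
    representation(a1 = "numeric", b1 = "numeric", a2 = "numeric",
                   b2 = "numeric", d = "numeric", rss = "numeric"))

setValidity("BrokenLineFit", function(object) {
    msg <- character()
    if (object@d <= 0 || object@d >= 1)
        msg <- c(msg, "d must lie strictly inside (0, 1)")
    if (object@rss < -1e-12)
        msg <- c(msg, "rss must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' ProfileCues: the five f0 profile cues of the stylization fits
#'
#' Slope and curve come from the parabola fit; onglide, offglide and
#' overall are f0 differences (later minus earlier, so a rise is positive)
#' between contour onset, breakpoint and offset of the broken-line fit,
#' with the breakpoint value taken from the left piece.
#'
#' @slot slope,curve,onglide,offglide,overall numeric cues (st-based).
#' @seealso [deriveProfileCues()], [makePairFeatures()]
#' @name ProfileCues-class
#' @exportClass ProfileCues
setClass("ProfileCues",
    representation(slope = "numeric", curve = "numeric", onglide = "numeric",
                   offglide = "numeric", overall = "numeric"))
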