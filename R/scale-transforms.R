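## Frequency-scale and time-axis transforms applied to f0 contours.

#' Convert f0 from Hz to semitones
#'
#' Semitones re a fixed reference (1 Hz by default, so absolute pitch
#' height — and in particular the female/male register gap — is kept):
#' `st = 12 * log2(f0 / ref)`.
#'
#' @param f0_hz positive numeric vector of f0 values in Hz.
#' @param ref_hz positive scalar, reference frequency (default 1 Hz).
#' @return Numeric vector of semitone values, same order.
#' @examples
#' hzToSemitone(c(1, 2, 220))
#' @export
hzToSemitone <- function(f0_hz, ref_hz = 1) {
    stopifnot(is.numeric(f0_hz), length(ref_hz) == 1L, ref_hz > 0)
    bad <- which(!is.finite(f0_hz) | f0_hz <= 0)
    if (length(bad))
        stop("f0 values must be positive and finite; offending index ",
             bad[1L], " (value ", f0_hz[bad[1L]], ")")
    12 * log2(f0_hz / ref_hz)
}

#' Convert semitones back to Hz
#'
#' Inverse of [hzToSemitone()]: `f0 = ref * 2^(st / 12)`.
#'
#' @param st finite numeric vector of semitone values.
#' @param ref_hz positive scalar reference frequency (default 1 Hz).
#' @return Numeric vector of Hz values, all positive.
#' @export
semitoneToHz <- function(st, ref_hz = 1) {
    stopifnot(is.numeric(st), length(ref_hz) == 1L, ref_hz > 0)
    bad <- which(!is.finite(st))
    if (length(bad))
        stop("semitone values must be finite; offending index ", bad[1L])
    ref_hz * 2^(st / 12)
}

#' Resample a contour to a fixed number of equidistant points
#'
#' Linear interpolation of the input at `n_out` equidistant positions on the
#' full input support, endpoints included (positions `i/(n_out - 1)` on a
#' unit support).  Applied to dense pitch tracks this yields the
#' time-normalized fixed-length vectors the recognizers consume.
#'
#' @param samples numeric vector of length >= 2.
#' @param n_out positive integer, output length (default 30).
#' @return Numeric vector of length `n_out`; endpoints preserved.
#' @export
timeNormalize <- function(samples, n_out = 30L) {
    stopifnot(is.numeric(samples), n_out >= 1L)
    if (length(samples) < 2L)
        stop("need at least 2 samples to time-normalize")
    if (any(!is.finite(samples)))
        stop("samples must be finite")
    approx(x = seq(0, 1, length.out = length(samples)), y = samples,
           xout = seq(0, 1, length.out = n_out))$y
}

#' Remove the utterance mean from the contours of one sequence
#'
#' For each disyllabic sequence (grouped by `seq_id`) the pooled mean of all
#' its f0 samples is subtracted from every sample, so that within-sequence
#' shape differences are untouched but the sequence as a whole is centered
#' at 0 st.  This is the preprocessing the qTA analysis-by-synthesis stage
#' applies before fitting pitch targets.  Contours must be on the semitone
#' scale.
#'
#' @param x a [ToneCorpus-class] on the semitone scale.
#' @param ... unused.
#' @return The corpus with centered samples (scale unchanged).
#' @export
#' @rdname utteranceMeanNormalize
setMethod("utteranceMeanNormalize", "ToneCorpus", function(x, ...) {
    if (ncol(x) == 0L)
        stop("empty corpus")
    if (!all(SummarizedExperiment::colData(x)$scale == "semitone"))
        stop("utterance-mean normalization requires the semitone scale")
    f0 <- SummarizedExperiment::assay(x, "f0")
    seq_id <- SummarizedExperiment::colData(x)$seq_id
    grp_mean <- vapply(split(seq_len(ncol(f0)), seq_id),
                       function(j) mean(f0[, j, drop = FALSE]), numeric(1))
    SummarizedExperiment::assay(x, "f0") <-
        sweep(f0, 2L, grp_mean[as.character(seq_id)], `-`)
    x
})

#' Convert a corpus between the Hz and semitone scales
#'
#' @param x a [ToneCorpus-class].
#' @param to `"hz"` or `"semitone"`.
#' @return The corpus with converted samples and updated `scale` labels.
#' @export
#' @rdname convertScale
setMethod("convertScale", "ToneCorpus", function(x, to = c("semitone", "hz")) {
    to <- match.arg(to)
    from <- corpusScale(x)
    if (length(from) == 0L || identical(from, to))
        return(x)
    f0 <- SummarizedExperiment::assay(x, "f0")
    SummarizedExperiment::assay(x, "f0") <-
        if (to == "semitone") matrix(hzToSemitone(f0), nrow = nrow(f0),
                                     dimnames = dimnames(f0))
        else matrix(semitoneToHz(f0), nrow = nrow(f0), dimnames = dimnames(f0))
    SummarizedExperiment::colData(x)$scale <- to
    x
})
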