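#' @rdname f0Samples
#' @export
setGeneric("f0Samples", function(x) standardGeneric("f0Samples"))

#' @rdname accessors
#' @export
setGeneric("toneLabels", function(x) standardGeneric("toneLabels"))

#' @rdname accessors
#' @export
setGeneric("speakerInfo", function(x) standardGeneric("speakerInfo"))

#' @rdname accessors
#' @export
setGeneric("corpusScale", function(x) standardGeneric("corpusScale"))

#' @rdname accessors
#' @export
setGeneric("corpusSplit", function(x) standardGeneric("corpusSplit"))

#' @rdname accessors
#' @export
setGeneric("corpusSplit<-", function(x, value) standardGeneric("corpusSplit<-"))

#' @rdname convertScale
#' @export
setGeneric("convertScale", function(x, to) standardGeneric("convertScale"))

#' @rdname utteranceMeanNormalize
#' @export
setGeneric("utteranceMeanNormalize",
           function(x, ...) standardGeneric("utteranceMeanNormalize"))

#' @rdname toneAccuracy
#' @export
setGeneric("toneAccuracy", function(x, ...) standardGeneric("toneAccuracy"))

#' @rdname toneAccuracy
#' @export
setGeneric("toneConfusion", function(x, ...) standardGeneric("toneConfusion"))

## ---- ToneCorpus accessors ----------------------------------------------

#' Extract the f0 sample matrix of a corpus
#'
#' @param x a [ToneCorpus-class].
#' @return Numeric matrix, `n_points x n_tokens`.
#' @export
#' @rdname f0Samples
setMethod("f0Samples", "ToneCorpus", function(x)
    SummarizedExperiment::assay(x, "f0"))

#' ToneCorpus accessors
#'
#' `toneLabels()` returns the integer tone (1..4) of each token;
#' `speakerInfo()` the speaker profile table; `corpusScale()` the common
#' frequency scale of the tokens; `corpusSplit()` the train/test assignment
#' (settable).
#'
#' @param x a [ToneCorpus-class].
#' @param value for `corpusSplit<-`, a character vector over tokens with
#'   values `"train"`/`"test"` (or `NA`).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("toneLabels", "ToneCorpus", function(x)
    as.integer(SummarizedExperiment::colData(x)$tone))

#' @rdname accessors
setMethod("speakerInfo", "ToneCorpus", function(x)
    S4Vectors::metadata(x)$speakers)

#' @rdname accessors
setMethod("corpusScale", "ToneCorpus", function(x) {
    sc <- unique(SummarizedExperiment::colData(x)$scale)
    if (length(sc) > 1L)
        stop("corpus mixes frequency scales: ", paste(sc, collapse = ", "))
    sc
})

#' @rdname accessors
setMethod("corpusSplit", "ToneCorpus", function(x)
    SummarizedExperiment::colData(x)$split)

#' @rdname accessors
setMethod("corpusSplit<-", "ToneCorpus", function(x, value) {
    SummarizedExperiment::colData(x)$split <- value
    methods::validObject(x)
    x
})

setMethod("show", "ToneCorpus", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("ToneCorpus with", ncol(object), "tokens x", nrow(object),
        "f0 samples\n")
    if (ncol(object)) {
        cat("  scale:", paste(unique(cd$scale), collapse = "/"),
            " speakers:", length(unique(cd$speaker_id)), "\n")
        cat("  tone counts:",
            paste(sprintf("T%d=%d", .TONES, tabulate(cd$tone, 4L)),
                  collapse = " "), "\n")
        if (all(is.na(cd$split))) {
            cat("  split: unset\n")
        } else {
            cat("  split:", sum(cd$split == "train", na.rm = TRUE), "train /",
                sum(cd$split == "test", na.rm = TRUE), "test\n")
        }
    }
    invisible(object)
})

setMethod("show", "QtaTarget", function(object) {
    cat(sprintf("QtaTarget: m = %.3g st/s, b = %.3g st, tau = %.3g s (order %d)\n",
                object@m, object@b, object@tau, object@response_order))
    cat(sprintf("  onset f0 = %.3g st; onset derivs: %s\n", object@onset_f0,
                paste(signif(object@onset_deriv, 3), collapse = ", ")))
    invisible(object)
})

setMethod("show", "ParabolaFit", function(object) {
    cat(sprintf("ParabolaFit: c0 = %.4g, c1 = %.4g, c2 = %.4g (rss %.3g)\n",
                object@c0, object@c1, object@c2, object@rss))
    invisible(object)
})

setMethod("show", "BrokenLineFit", function(object) {
    cat(sprintf("BrokenLineFit: left %.4g + %.4g t | right %.4g + %.4g t, break d = %.3g (rss %.3g)\n",
                object@a1, object@b1, object@a2, object@b2, object@d,
                object@rss))
    invisible(object)
})

setMethod("show", "ProfileCues", function(object) {
    cat(sprintf("ProfileCues: slope %.4g, curve %.4g, onglide %.4g, offglide %.4g, overall %.4g\n",
                object@slope, object@curve, object@onglide, object@offglide,
                object@overall))
    invisible(object)
})

setMethod("show", "RecognitionResult", function(object) {
    extra <- c(if (!is.na(object@mode)) paste0("mode=", object@mode),
               if (!is.na(object@cue_pair)) paste0("cues=", object@cue_pair),
               if (isTRUE(object@include_onset)) "with onset f0")
    cat(sprintf("RecognitionResult: %s (%s, %s%s)\n", object@scheme,
                object@scale, object@recognizer,
                if (length(extra)) paste0(", ", paste(extra, collapse = ", "))
                else ""))
    cat(sprintf("  accuracy: %.2f%% (macro %.2f%%) on %d test tokens (%d train)\n",
                object@accuracy_pct, object@macro_accuracy_pct,
                object@n_test, object@n_train))
    cat("  per tone:",
        paste(sprintf("T%d=%.1f%%", .TONES, object@per_tone_accuracy_pct),
              collapse = " "), "\n")
    invisible(object)
})

## ---- RecognitionResult accessors ---------------------------------------

#' Accuracy and confusion of a recognition result
#'
#' `toneAccuracy()` returns the overall test accuracy in percent (set
#' `per_tone = TRUE` for the four per-tone rates); `toneConfusion()` returns
#' the 4 x 5 row-percentage confusion matrix (columns T1..T4 plus `none`
#' for unlabelled predictions).
#'
#' @param x a [RecognitionResult-class].
#' @param per_tone logical; return per-tone rates instead.
#' @param ... unused.
#' @name toneAccuracy
#' @rdname toneAccuracy
NULL

#' @rdname toneAccuracy
setMethod("toneAccuracy", "RecognitionResult", function(x, per_tone = FALSE, ...)
    if (per_tone) x@per_tone_accuracy_pct else x@accuracy_pct)

#' @rdname toneAccuracy
setMethod("toneConfusion", "RecognitionResult", function(x, ...) x@confusion)
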