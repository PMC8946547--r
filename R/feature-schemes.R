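## Feature representations of a syllable f0 contour: the raw 30-point
## vector, two-position pitch-level codes (binary or five-level),
## parabola/broken-line profile cues, and qTA parameters.

.LEVEL_CODES <- list(
    two_level  = matrix(c(1, 1,  0, 1,  0, 0,  1, 0), nrow = 4L,
                        byrow = TRUE,
                        dimnames = list(paste0("T", 1:4),
                                        c("first", "second"))),
    five_level = matrix(c(5, 5,  3, 5,  2, 1,  5, 3), nrow = 4L,
                        byrow = TRUE,
                        dimnames = list(paste0("T", 1:4),
                                        c("first", "second"))))

.CUE_PAIRS <- list(
    "slope+curve"      = c("slope", "curve"),
    "curve+overall"    = c("curve", "overall"),
    "slope+onglide"    = c("slope", "onglide"),
    "onglide+offglide" = c("onglide", "offglide"),
    "offglide+overall" = c("offglide", "overall"))

#' Split a 30-point contour into its two 15-point halves
#'
#' @param samples numeric vector of length 30 (or a `30 x n` matrix, split
#'   row-wise).
#' @return List with `first` and `second` halves; their concatenation
#'   reproduces the input.
#' @export
splitHalves <- function(samples) {
    n <- if (is.matrix(samples)) nrow(samples) else length(samples)
    if (n != 30L)
        stop("expected a 30-sample contour, got ", n)
    if (is.matrix(samples))
        list(first = samples[1:15, , drop = FALSE],
             second = samples[16:30, , drop = FALSE])
    else
        list(first = samples[1:15], second = samples[16:30])
}

#' Map a tone to its two-position pitch-level code
#'
#' Two-level (distinctive-feature style) coding: 11 = T1, 01 = T2,
#' 00 = T3, 10 = T4 ('1' high, '0' low).  Five-level coding: 55 = T1,
#' 35 = T2, 21 = T3, 53 = T4 (a larger number is a higher pitch).
#'
#' @param tone integer vector of tones in 1..4.
#' @param scheme `"two_level"` or `"five_level"`.
#' @return Integer matrix with columns `first` and `second`, one row per
#'   tone.
#' @export
toneToCode <- function(tone, scheme = c("two_level", "five_level")) {
    scheme <- match.arg(scheme)
    if (!all(tone %in% .TONES))
        stop("tone must be in 1..4")
    .LEVEL_CODES[[scheme]][tone, , drop = FALSE]
}

#' Map a two-position level code back to a tone
#'
#' Inverse of [toneToCode()].  All four two-level codes are valid; a
#' five-level code outside the four defined pairs has no tone and yields
#' `NA` (scored as a misclassification downstream).
#'
#' @param first,second integer level vectors (one entry per token).
#' @param scheme `"two_level"` or `"five_level"`.
#' @return Integer tone vector with `NA` for unmatched codes.
#' @export
codeToTone <- function(first, second, scheme = c("two_level", "five_level")) {
    scheme <- match.arg(scheme)
    codes <- .LEVEL_CODES[[scheme]]
    key <- paste(first, second)
    tone <- match(key, paste(codes[, "first"], codes[, "second"]))
    as.integer(tone)
}

#' Least-squares parabola fit of a contour
#'
#' Fits the mean-centered quadratic basis
#' `f(t) ~ c0 + c1 (t - 1/2) + c2 [(t - 1/2)^2 - 1/12]` over
#' unit-normalized time `t_i = i/(n-1)` by ordinary least squares (via the
#' normal equations of the fixed 3-column design).  `c1` and `c2` are the
#' slope and curve cues of the profile representation.
#'
#' @param samples numeric contour (30 points by default; any length >= 3
#'   is accepted).
#' @return A [ParabolaFit-class].
#' @export
fitParabola <- function(samples) {
    if (!is.numeric(samples) || any(!is.finite(samples)))
        stop("samples must be finite numeric values")
    n <- length(samples)
    if (n < 3L)
        stop("need at least 3 samples")
    tc <- seq(0, 1, length.out = n) - 0.5
    X <- cbind(1, tc, tc^2 - 1 / 12)
    beta <- unname(drop(solve(crossprod(X), crossprod(X, samples))))
    r <- samples - drop(X %*% beta)
    methods::new("ParabolaFit", c0 = beta[1L], c1 = beta[2L], c2 = beta[3L],
                 rss = sum(r^2))
}

## Per-candidate projection matrices for the broken-line scan, cached per
## contour length.  Candidate j (0-based sample index) puts samples
## 1..j in the left piece (t < d) and j+1..n in the right (t >= d).
.blDesign <- local({
    cache <- list()
    function(n) {
        key <- as.character(n)
        if (!is.null(cache[[key]]))
            return(cache[[key]])
        tt <- seq(0, 1, length.out = n)
        cand <- 3:(n - 3L)          # 0-based breakpoint sample positions
        des <- lapply(cand, function(j) {
            li <- seq_len(j)
            ri <- (j + 1L):n
            XL <- cbind(1, tt[li]); XR <- cbind(1, tt[ri])
            list(li = li, ri = ri, d = tt[j + 1L],
                 PL = solve(crossprod(XL), t(XL)),
                 PR = solve(crossprod(XR), t(XR)),
                 XL = XL, XR = XR)
        })
        out <- list(cand = cand, des = des)
        cache[[key]] <<- out
        out
    }
})

#' Broken-line (two-piece linear) fit with a free breakpoint
#'
#' For every candidate breakpoint on the interior sample grid (each piece
#' keeps at least 3 samples) the two pieces are fitted by independent
#' ordinary least squares; the candidate minimizing the total residual sum
#' of squares wins, with ties broken in favour of the smallest breakpoint
#' position.  With `continuous = TRUE` the two pieces are instead
#' constrained to meet at the breakpoint (basis `{1, t, (t - d)+}`).
#'
#' @param samples numeric contour of length >= 7.
#' @param continuous logical; enforce continuity at the breakpoint.
#' @return A [BrokenLineFit-class].
#' @export
fitBrokenLine <- function(samples, continuous = FALSE) {
    if (!is.numeric(samples) || any(!is.finite(samples)))
        stop("samples must be finite numeric values")
    n <- length(samples)
    if (n < 7L)
        stop("need at least 7 samples for a two-piece fit")
    dd <- .blDesign(n)
    best <- NULL
    for (de in dd$des) {
        if (continuous) {
            tt <- seq(0, 1, length.out = n)
            X <- cbind(1, tt, pmax(tt - de$d, 0))
            beta <- unname(drop(solve(crossprod(X), crossprod(X, samples))))
            rss <- sum((samples - drop(X %*% beta))^2)
            cf <- list(a1 = beta[1L], b1 = beta[2L],
                       a2 = beta[1L] - beta[3L] * de$d,
                       b2 = beta[2L] + beta[3L])
        } else {
            bl <- drop(de$PL %*% samples[de$li])
            br <- drop(de$PR %*% samples[de$ri])
            rss <- sum((samples[de$li] - drop(de$XL %*% bl))^2) +
                   sum((samples[de$ri] - drop(de$XR %*% br))^2)
            cf <- list(a1 = bl[1L], b1 = bl[2L], a2 = br[1L], b2 = br[2L])
        }
        ## strict improvement beyond float noise, so that near-ties keep
        ## the smaller breakpoint position
        if (is.null(best) ||
            rss < best$rss - max(1e-12, 1e-9 * best$rss))
            best <- c(cf, list(d = de$d, rss = rss))
    }
    methods::new("BrokenLineFit", a1 = best$a1, b1 = best$b1, a2 = best$a2,
                 b2 = best$b2, d = best$d, rss = max(best$rss, 0))
}

#' Derive the five profile cues from the two stylization fits
#'
#' Slope and curve are `c1` and `c2` of the parabola fit.  The glide cues
#' are f0 differences of the broken-line fit, later value minus earlier
#' (so a rise is positive): onglide from contour onset to breakpoint,
#' offglide from breakpoint to contour offset, overall from onset to
#' offset.  The breakpoint value is taken from the left piece at `t = d`,
#' which makes `overall = onglide + offglide` an identity.
#'
#' @param pf a [ParabolaFit-class] of the contour.
#' @param bl a [BrokenLineFit-class] of the same contour.
#' @return A [ProfileCues-class].
#' @export
deriveProfileCues <- function(pf, bl) {
    stopifnot(methods::is(pf, "ParabolaFit"), methods::is(bl, "BrokenLineFit"))
    onset <- bl@a1
    at_break <- bl@a1 + bl@b1 * bl@d
    offset <- bl@a2 + bl@b2
    methods::new("ProfileCues", slope = pf@c1, curve = pf@c2,
                 onglide = at_break - onset, offglide = offset - at_break,
                 overall = offset - onset)
}

#' Assemble a two-dimensional cue-pair feature vector
#'
#' The five cue pairs carried forward to classification are
#' `slope+curve`, `curve+overall`, `slope+onglide`, `onglide+offglide` and
#' `offglide+overall`.
#'
#' @param cues a [ProfileCues-class].
#' @param pair one of the five pair names above.
#' @return Named numeric vector of length 2, in the listed order.
#' @export
makePairFeatures <- function(cues, pair) {
    stopifnot(methods::is(cues, "ProfileCues"))
    if (!pair %in% names(.CUE_PAIRS))
        stop("unknown cue pair '", pair, "'; valid pairs: ",
             paste(names(.CUE_PAIRS), collapse = ", "))
    sel <- .CUE_PAIRS[[pair]]
    vals <- c(slope = cues@slope, curve = cues@curve, onglide = cues@onglide,
              offglide = cues@offglide, overall = cues@overall)
    vals[sel]
}

#' @rdname makePairFeatures
#' @export
cuePairNames <- function() names(.CUE_PAIRS)

#' qTA parameter feature vector
#'
#' `(m, b, tau)` — optionally extended with the syllable-onset f0 as a
#' fourth dimension, the contextual cue carried over from the preceding
#' syllable.
#'
#' @param target a fitted [QtaTarget-class].
#' @param include_onset logical; append `onset_f0`.
#' @return Named numeric vector of dimension 3 or 4.
#' @export
qtaFeatureVector <- function(target, include_onset = FALSE) {
    stopifnot(methods::is(target, "QtaTarget"))
    v <- c(m = target@m, b = target@b, tau = target@tau)
    if (include_onset)
        v <- c(v, onset_f0 = target@onset_f0)
    v
}

## ---- corpus-level feature extraction -----------------------------------

## Vectorized profile cues for all columns of a 30 x n f0 matrix.
.profileCueMatrix <- function(f0, continuous = FALSE) {
    n <- nrow(f0)
    tc <- seq(0, 1, length.out = n) - 0.5
    X <- cbind(1, tc, tc^2 - 1 / 12)
    beta <- solve(crossprod(X), crossprod(X, f0))   # 3 x ntok
    dd <- .blDesign(n)
    ntok <- ncol(f0)
    best_rss <- rep(Inf, ntok)
    a1 <- b1 <- a2 <- b2 <- dpos <- numeric(ntok)
    for (de in dd$des) {
        bl <- de$PL %*% f0[de$li, , drop = FALSE]
        br <- de$PR %*% f0[de$ri, , drop = FALSE]
        rss <- colSums((f0[de$li, , drop = FALSE] - de$XL %*% bl)^2) +
               colSums((f0[de$ri, , drop = FALSE] - de$XR %*% br)^2)
        thr <- ifelse(is.finite(best_rss),
                      best_rss - pmax(1e-12, 1e-9 * best_rss), Inf)
        upd <- rss < thr               # near-ties keep the smaller d
        if (any(upd)) {
            best_rss[upd] <- rss[upd]
            a1[upd] <- bl[1L, upd]; b1[upd] <- bl[2L, upd]
            a2[upd] <- br[1L, upd]; b2[upd] <- br[2L, upd]
            dpos[upd] <- de$d
        }
    }
    at_break <- a1 + b1 * dpos
    offset <- a2 + b2
    data.frame(slope = beta[2L, ], curve = beta[3L, ],
               onglide = at_break - a1, offglide = offset - at_break,
               overall = offset - a1, d = dpos, bl_rss = best_rss,
               pb_rss = colSums((f0 - X %*% beta)^2))
}

#' Extract the feature matrix of a corpus under a recognition scheme
#'
#' Returns the per-token classifier input for one representation:
#' `full_contour` (the raw 30-point vectors, transposed to one row per
#' token), `profile` (a two-dimensional cue pair from the parabola and
#' broken-line stylizations), or `qta` (analysis-by-synthesis qTA
#' parameters, optionally with onset f0; always computed on utterance-mean
#' normalized semitone contours).  Level-code schemes operate on contour
#' halves and are driven directly by [runScheme()].
#'
#' @param corpus a [ToneCorpus-class].
#' @param scheme `"full_contour"`, `"profile"` or `"qta"`.
#' @param scale `"semitone"` or `"hz"`; the corpus is converted as needed
#'   (`qta` is defined on the semitone scale only).
#' @param cue_pair cue pair for the profile scheme (see [cuePairNames()]).
#' @param include_onset logical, qTA scheme only.
#' @param ... extra arguments for [fitQtaCorpus()].
#' @return Numeric matrix, one row per token (rownames = token ids).
#' @export
featureMatrix <- function(corpus, scheme = c("full_contour", "profile", "qta"),
                          scale = c("semitone", "hz"),
                          cue_pair = "slope+curve", include_onset = FALSE,
                          ...) {
    scheme <- match.arg(scheme)
    scale <- match.arg(scale)
    if (scheme == "qta" && scale != "semitone")
        stop("the qTA representation is defined on the semitone scale only")
    corpus <- convertScale(corpus, scale)
    f0 <- f0Samples(corpus)
    out <- switch(scheme,
        full_contour = t(f0),
        profile = {
            if (!cue_pair %in% names(.CUE_PAIRS))
                stop("unknown cue pair '", cue_pair, "'")
            cues <- .profileCueMatrix(f0)
            as.matrix(cues[, .CUE_PAIRS[[cue_pair]]])
        },
        qta = {
            fits <- fitQtaCorpus(corpus, ...)
            stopifnot(identical(fits$token_id,
                                SummarizedExperiment::colData(corpus)$token_id))
            cols <- c("m", "b", "tau", if (include_onset) "onset_f0")
            as.matrix(fits[, cols])
        })
    rownames(out) <- SummarizedExperiment::colData(corpus)$token_id
    out
}
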