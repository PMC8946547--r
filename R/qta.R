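## Quantitative target approximation (qTA): forward synthesis and
## analysis-by-synthesis parameter recovery.
##
## Surface f0 approaches a linear pitch target x(t) = m t + b through
##   f0(t) = (m t + b) + (c0 + c1 t + ... + c_{N-1} t^{N-1}) exp(-t / tau),
## the response of a critically damped N-th order system.  The transient
## coefficients c_i are pinned down by the f0 value and first N-1
## derivatives at syllable onset, which is how articulatory inertia carries
## f0 state across syllable boundaries.

## Solve c_0..c_{N-1} from the onset state.  Derivatives of
## p(t) exp(-t/tau) at 0 give a triangular system solved sequentially:
##   k! c_k = (y_k - x_k(0)) - sum_{i<k} C(k,i) i! c_i (-1/tau)^(k-i)
## with x_0(0) = b, x_1(0) = m, higher derivatives of the target zero.
.qtaCoefs <- function(m, b, tau, onset_f0, onset_deriv) {
    n <- length(onset_deriv) + 1L
    y <- c(onset_f0, onset_deriv)
    xk <- c(b, if (n > 1L) m, rep(0, max(0L, n - 2L)))
    cc <- numeric(n)
    for (k in seq_len(n) - 1L) {
        acc <- 0
        for (i in seq_len(k) - 1L)
            acc <- acc + choose(k, i) * factorial(i) * cc[i + 1L] *
                (-1 / tau)^(k - i)
        cc[k + 1L] <- (y[k + 1L] - xk[k + 1L] - acc) / factorial(k)
    }
    cc
}

## f0 and its first (order-1) derivatives at time t (scalar t).
.qtaStateAt <- function(m, b, tau, cc, t) {
    n <- length(cc)
    pj <- function(j) {       # j-th derivative of the transient polynomial
        i <- j:(n - 1L)
        if (j > n - 1L) return(0)
        sum(cc[i + 1L] * factorial(i) / factorial(i - j) * t^(i - j))
    }
    et <- exp(-t / tau)
    vapply(seq_len(n) - 1L, function(k) {
        xk <- if (k == 0L) m * t + b else if (k == 1L) m else 0
        g <- sum(vapply(0:k, function(j)
            choose(k, j) * pj(j) * (-1 / tau)^(k - j), numeric(1)))
        xk + et * g
    }, numeric(1))
}

#' Synthesize a syllable f0 contour from a qTA target
#'
#' Samples the qTA response at `n_samples` equidistant times on
#' `[0, duration_s]`.  The transient coefficients are solved so that the
#' output and its first `N - 1` derivatives at `t = 0` equal the target's
#' onset state; in particular the first sample equals `onset_f0` exactly.
#'
#' @param target a [QtaTarget-class].
#' @param duration_s positive duration in seconds.
#' @param n_samples integer >= 2, number of equidistant samples.
#' @return Numeric vector of `n_samples` f0 values in st.
#' @examples
#' qtaForward(QtaTarget(m = 0, b = 96, tau = 0.02, onset_f0 = 90), 0.25, 30)
#' @export
qtaForward <- function(target, duration_s, n_samples = 30L) {
    stopifnot(methods::is(target, "QtaTarget"), duration_s > 0,
              n_samples >= 2L)
    methods::validObject(target)
    tt <- seq(0, duration_s, length.out = n_samples)
    cc <- .qtaCoefs(target@m, target@b, target@tau, target@onset_f0,
                    target@onset_deriv)
    poly <- rep(0, n_samples)
    for (i in seq_along(cc))
        poly <- poly + cc[i] * tt^(i - 1L)
    target@m * tt + target@b + poly * exp(-tt / target@tau)
}

#' Terminal f0 state of a qTA target at the end of a syllable
#'
#' Evaluates f0 and its first `N - 1` derivatives at `t = duration_s`; this
#' is the state transferred to the next syllable's onset to model
#' articulatory carryover.
#'
#' @inheritParams qtaForward
#' @return Numeric vector `(f0, f0', ..., f0^{(N-1)})` at `duration_s`.
#' @export
qtaTerminalState <- function(target, duration_s) {
    stopifnot(methods::is(target, "QtaTarget"), duration_s > 0)
    cc <- .qtaCoefs(target@m, target@b, target@tau, target@onset_f0,
                    target@onset_deriv)
    .qtaStateAt(target@m, target@b, target@tau, cc, duration_s)
}

## For fixed tau the third-order response is linear in (m, b):
##   f0(t) = m f_m(t) + b f_b(t) + g(t),
## with basis f_b = 1 - E (1 + t/tau + t^2/(2 tau^2)),
## f_m = t - E (t + t^2/tau), E = exp(-t/tau), and g collecting the onset
## terms.  Solving the 2x2 least squares exactly lets the refinement
## search tau alone, which avoids the flat, correlated (m, b, tau)
## surface that defeats a joint local search.
.qtaProfiled <- function(tau, y, tt, onset_f0, onset_deriv) {
    E <- exp(-tt / tau)
    fb <- 1 - E * (1 + tt / tau + tt^2 / (2 * tau^2))
    fm <- tt - E * (tt + tt^2 / tau)
    g <- E * (onset_f0 + (onset_deriv[1L] + onset_f0 / tau) * tt +
              (onset_deriv[2L] / 2 + onset_deriv[1L] / tau +
               onset_f0 / (2 * tau^2)) * tt^2)
    X <- cbind(fm, fb)
    r <- y - g
    xtx <- crossprod(X)
    if (abs(det(xtx)) < 1e-20)       # degenerate: tau >> duration
        return(list(m = 0, b = mean(r), rss = sum((r - mean(r))^2)))
    beta <- drop(solve(xtx, crossprod(X, r)))
    list(m = beta[1L], b = beta[2L], rss = sum((r - drop(X %*% beta))^2))
}

## Vectorized residual sum of squares of candidate (m, b, tau) triples
## against one observed contour (third-order response).
.qtaGridRss <- function(m, b, tau, y, tt, onset_f0, onset_deriv) {
    c0 <- onset_f0 - b
    c1 <- onset_deriv[1L] - m + c0 / tau
    c2 <- (onset_deriv[2L] + 2 * c1 / tau - c0 / tau^2) / 2
    E <- exp(outer(-1 / tau, tt))
    P <- c0 + outer(c1, tt) + outer(c2, tt^2)
    M <- outer(m, tt) + b + P * E
    rowSums((M - matrix(y, nrow = length(m), ncol = length(tt),
                        byrow = TRUE))^2)
}

#' Recover qTA parameters from a contour by analysis-by-synthesis
#'
#' Searches for the pitch target `(m, b, tau)` whose forward-synthesized
#' contour best matches `samples` in the least-squares sense, holding the
#' onset state fixed.  A coarse grid scan (by default 21 slope points over
#' `m_range`, 21 offset points over `mean(samples) + b_range`, 15
#' log-spaced time constants over `tau_range`) is followed by
#' derivative-free local refinement: for fixed `tau` the response is linear
#' in `(m, b)`, so those are profiled out by exact least squares and only
#' `tau` is polished by golden-section search inside a fine profiled grid
#' bracket (the profiled rss over `tau` can be multimodal).  The refined
#' fit never has larger rss than the best grid candidate; `m_range` and
#' `b_range` bound the coarse scan, while the local refinement may settle
#' just outside them.
#'
#' @param samples numeric contour in st (typically utterance-mean
#'   normalized, see [utteranceMeanNormalize()]).
#' @param duration_s positive physical duration in seconds.
#' @param onset_f0 f0 state at syllable start (default: first sample).
#' @param onset_deriv onset derivatives, length 2 for the default
#'   third-order response.
#' @param m_range,b_range,tau_range search bounds; `b_range` is relative to
#'   the contour mean.
#' @param grid_n integer triple: grid resolution for `(m, b, tau)`.
#' @param refine logical; run local refinement after the grid scan.
#' @return List with `target` (a [QtaTarget-class]), `rss`, and `grid_rss`
#'   (rss of the best grid candidate before refinement).
#' @export
fitQta <- function(samples, duration_s, onset_f0 = samples[1L],
                   onset_deriv = c(0, 0), m_range = c(-100, 100),
                   b_range = c(-15, 15), tau_range = c(0.01, 0.1),
                   grid_n = c(21L, 21L, 15L), refine = TRUE) {
    stopifnot(is.numeric(samples), all(is.finite(samples)), duration_s > 0,
              length(onset_deriv) == 2L)
    if (m_range[1L] > m_range[2L] || b_range[1L] > b_range[2L] ||
        tau_range[1L] > tau_range[2L] || tau_range[1L] <= 0)
        stop("search bounds exclude all candidates")
    tt <- seq(0, duration_s, length.out = length(samples))
    m_grid <- seq(m_range[1L], m_range[2L], length.out = grid_n[1L])
    b_grid <- mean(samples) + seq(b_range[1L], b_range[2L],
                                  length.out = grid_n[2L])
    tau_grid <- exp(seq(log(tau_range[1L]), log(tau_range[2L]),
                        length.out = grid_n[3L]))
    cand <- expand.grid(m = m_grid, b = b_grid, tau = tau_grid,
                        KEEP.OUT.ATTRS = FALSE)
    rss <- .qtaGridRss(cand$m, cand$b, cand$tau, samples, tt, onset_f0,
                       onset_deriv)
    best <- which.min(rss)
    grid_rss <- rss[best]
    out <- list(m = cand$m[best], b = cand$b[best], tau = cand$tau[best],
                rss = grid_rss)
    if (refine) {
        ## profile (m, b) out in closed form and refine tau alone; the
        ## profiled rss(tau) can be multimodal, so scan a fine log grid
        ## before the local golden-section polish
        tau_fine <- exp(seq(log(tau_range[1L]), log(tau_range[2L]),
                            length.out = max(80L, 4L * grid_n[3L])))
        prof_rss <- vapply(tau_fine, function(tau)
            .qtaProfiled(tau, samples, tt, onset_f0, onset_deriv)$rss,
            numeric(1))
        k <- which.min(prof_rss)
        lo <- tau_fine[max(1L, k - 1L)]
        hi <- tau_fine[min(length(tau_fine), k + 1L)]
        tau_hat <- if (lo < hi)
            optimize(function(tau)
                .qtaProfiled(tau, samples, tt, onset_f0, onset_deriv)$rss,
                interval = c(lo, hi), tol = 1e-12)$minimum
        else tau_fine[k]
        ref <- .qtaProfiled(tau_hat, samples, tt, onset_f0, onset_deriv)
        if (ref$rss <= grid_rss)
            out <- list(m = ref$m, b = ref$b, tau = tau_hat, rss = ref$rss)
    }
    list(target = QtaTarget(m = out$m, b = out$b, tau = out$tau,
                            onset_f0 = onset_f0, onset_deriv = onset_deriv),
         rss = out$rss, grid_rss = grid_rss)
}

#' Fit qTA targets to every token of a corpus
#'
#' Applies the qTA preprocessing and fitting pipeline: contours are taken
#' on the semitone scale, utterance-mean normalized per disyllabic
#' sequence, then fitted sequence by sequence.  Syllable-1 tokens use their
#' first sample as onset f0 with zero onset derivatives; syllable-2 tokens
#' inherit the terminal state of the preceding syllable's *fitted* model,
#' mirroring the carryover rule of the forward model.
#'
#' @param corpus a [ToneCorpus-class] (Hz corpora are converted).
#' @param normalize logical; apply [utteranceMeanNormalize()] first.
#' @param ... passed on to [fitQta()] (search bounds, grid resolution).
#' @return data.frame with one row per token: `token_id`, `m`, `b`, `tau`,
#'   `onset_f0`, `rss`.
#' @export
fitQtaCorpus <- function(corpus, normalize = TRUE, ...) {
    stopifnot(methods::is(corpus, "ToneCorpus"))
    corpus <- convertScale(corpus, "semitone")
    if (normalize)
        corpus <- utteranceMeanNormalize(corpus)
    f0 <- f0Samples(corpus)
    cd <- SummarizedExperiment::colData(corpus)
    res <- vector("list", ncol(corpus))
    for (j in split(seq_len(ncol(corpus)), as.character(cd$seq_id))) {
        j <- j[order(cd$position[j])]
        state <- NULL
        for (idx in j) {
            y <- f0[, idx]
            if (is.null(state))
                state <- list(onset = y[1L], deriv = c(0, 0))
            fit <- fitQta(y, duration_s = cd$duration_s[idx],
                          onset_f0 = state$onset,
                          onset_deriv = state$deriv, ...)
            res[[idx]] <- data.frame(
                token_id = cd$token_id[idx], m = fit$target@m,
                b = fit$target@b, tau = fit$target@tau,
                onset_f0 = state$onset, rss = fit$rss)
            term <- qtaTerminalState(fit$target, cd$duration_s[idx])
            state <- list(onset = term[1L], deriv = term[-1L])
        }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
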