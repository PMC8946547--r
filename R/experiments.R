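## Experiment driver: run one recognition scheme end to end on a split
## corpus, assemble confusion matrices, the testing-phase time-complexity
## ledger, and the cross-scheme summary.

.SCHEMES <- c("full_contour", "two_level", "five_level", "profile", "qta")

#' Row-percentage tone confusion matrix
#'
#' Rows are true tones, columns predicted tones plus a final `none` column
#' collecting unlabelled predictions (`NA`: a SOM token on an
#' uncategorized unit, or a level code with no tone).  Each row with at
#' least one test token sums to 100.
#'
#' @param truth integer tones 1..4.
#' @param predicted integer tones with `NA` for unlabelled predictions.
#' @return 4 x 5 numeric matrix of row percentages.
#' @export
toneConfusionMatrix <- function(truth, predicted) {
    if (length(truth) != length(predicted))
        stop("truth and predicted must have equal length")
    stopifnot(all(truth %in% .TONES))
    out <- matrix(0, 4L, 5L,
                  dimnames = list(paste0("T", .TONES),
                                  c(paste0("T", .TONES), "none")))
    pred5 <- ifelse(is.na(predicted), 5L, as.integer(predicted))
    for (t in .TONES) {
        i <- truth == t
        if (any(i))
            out[t, ] <- 100 * tabulate(pred5[i], 5L) / sum(i)
    }
    out
}

#' Testing-phase time-complexity ledger of the recognition schemes
#'
#' Operation-count accounting per scheme at the testing phase: a
#' `d`-dimensional input classified into `m` categories by the SVM costs
#' on the order of `d x m`; the level schemes run one 15-point classifier
#' per half (2 or 5 level classes) plus, for the binary code, one matching
#' step; the stylization and qTA schemes pay an order-`30^3` fitting term
#' before classifying their 2- or 3-dimensional features.  Values are
#' invariant to corpus content.
#'
#' @param schemes character vector of scheme ids (default: all five).
#' @return data.frame: `scheme`, `method`, `input_size`, `n_steps`,
#'   `n_dims`, `n_classes`, `expression`, `value`.
#' @export
complexityReport <- function(schemes = .SCHEMES) {
    rows <- list(
        full_contour = list(method = "SVM", input_size = "30 points",
                            n_steps = 1L, n_dims = 30L, n_classes = 4L,
                            expression = "O(30 x 4)", value = 30L * 4L),
        two_level = list(method = "SVM x 2 + matching",
                         input_size = "15 points", n_steps = 3L,
                         n_dims = 15L, n_classes = 2L,
                         expression = "O(15 x 2) x 2 + 1",
                         value = (15L * 2L) * 2L + 1L),
        five_level = list(method = "SVM x 2 + matching",
                          input_size = "15 points", n_steps = 3L,
                          n_dims = 15L, n_classes = 5L,
                          expression = "O(15 x 5) x 2",
                          value = (15L * 5L) * 2L),
        profile = list(method = "parabola/broken-line + SVM",
                       input_size = "30 points", n_steps = 2L,
                       n_dims = 2L, n_classes = 4L,
                       expression = "O(30^3) + O(2 x 4)",
                       value = as.integer(30^3 + 2 * 4)),
        qta = list(method = "qTA extraction + SVM",
                   input_size = "30 points", n_steps = 2L,
                   n_dims = 3L, n_classes = 4L,
                   expression = "O(30^3) + O(3 x 4)",
                   value = as.integer(30^3 + 3 * 4)))
    bad <- setdiff(schemes, names(rows))
    if (length(bad))
        stop("unknown scheme(s): ", paste(bad, collapse = ", "))
    out <- do.call(rbind, lapply(schemes, function(s)
        data.frame(scheme = s, rows[[s]], stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
}

## Integer tone predictions from a factor/character prediction vector.
.asTone <- function(p) {
    out <- suppressWarnings(as.integer(as.character(p)))
    out[!out %in% .TONES] <- NA_integer_
    out
}

.trainPredict <- function(recognizer, x_train, y_train, x_test, seed,
                          svm_grid, folds, tune_max_n, som, scale_features) {
    if (recognizer == "svm") {
        fit <- svmTrain(x_train, y_train, grid = svm_grid, folds = folds,
                        seed = seed, scale = scale_features,
                        tune_max_n = tune_max_n)
        list(pred = as.character(svmPredict(fit, x_test)),
             hyper = list(cost = fit$cost, gamma = fit$gamma,
                          cv_accuracy = fit$cv_accuracy))
    } else {
        spec <- som
        spec$seed <- as.integer(seed)
        map <- somTrain(x_train, spec)
        lab <- somLabelUnits(map, x_train, y_train)
        list(pred = somPredict(map, lab, x_test),
             hyper = list(units = spec$rows * spec$cols,
                          epochs = spec$epochs,
                          label_threshold = spec$label_threshold,
                          labelled_units = sum(!is.na(lab$labels)),
                          qe = unname(map$qe)))
    }
}

#' Run one tone-recognition scheme on a split corpus
#'
#' Drives a complete experiment: extract the scheme's representation from
#' the training and test splits, train the recognizer, predict the test
#' tokens, and score.  The level schemes classify the two 15-point contour
#' halves into pitch levels — either with one model per half
#' (`mode = "separate"`) or one model pooling both halves
#' (`mode = "together"`) — and then map the combined two-position code
#' back to a tone; codes matching no tone count as errors.  The SOM
#' recognizer is available for the contour-based schemes (full contour and
#' level codes) only.
#'
#' @param corpus a [ToneCorpus-class] with the split set ([splitCorpus()]).
#' @param scheme one of `full_contour`, `two_level`, `five_level`,
#'   `profile`, `qta`.
#' @param scale `"semitone"` or `"hz"` (`qta` is semitone-only).
#' @param recognizer `"svm"` or `"som"`.
#' @param mode `"separate"` or `"together"` (level schemes only).
#' @param cue_pair stylization cue pair (profile scheme only), see
#'   [cuePairNames()].
#' @param include_onset append onset f0 to the qTA parameters (qta only).
#' @param seed integer seed for all run randomness.
#' @param svm_grid,folds,tune_max_n SVM tuning controls, see [svmTrain()].
#' @param som a [somSpec()]; its seed is overridden by `seed`.
#' @param scale_features standardize features inside the SVM (off by
#'   default: raw pitch height is informative).
#' @param qta_args list of extra arguments for [fitQtaCorpus()].
#' @param features optional precomputed feature matrix over all tokens
#'   (rows = tokens in corpus order), bypassing extraction.
#' @return A [RecognitionResult-class].
#' @export
runScheme <- function(corpus, scheme = .SCHEMES, scale = c("semitone", "hz"),
                      recognizer = c("svm", "som"),
                      mode = c("separate", "together"),
                      cue_pair = "slope+curve", include_onset = FALSE,
                      seed = 1L, svm_grid = svmGrid(), folds = 5L,
                      tune_max_n = Inf, som = somSpec(),
                      scale_features = FALSE, qta_args = list(),
                      features = NULL) {
    scheme <- match.arg(scheme)
    scale <- match.arg(scale)
    recognizer <- match.arg(recognizer)
    level_scheme <- scheme %in% c("two_level", "five_level")
    mode <- if (level_scheme) match.arg(mode) else NA_character_
    if (recognizer == "som" && !scheme %in%
        c("full_contour", "two_level", "five_level"))
        stop("the SOM recognizer applies to contour-based schemes only")
    if (include_onset && scheme != "qta")
        stop("include_onset is a qTA-scheme option")
    if (scheme == "qta" && scale == "hz")
        stop("the qTA representation is defined on the semitone scale only")
    split <- corpusSplit(corpus)
    if (any(is.na(split)))
        stop("corpus split is not set; call splitCorpus() first")
    tr <- which(split == "train")
    te <- which(split == "test")
    tone <- toneLabels(corpus)
    truth <- tone[te]
    seed <- as.integer(seed)

    if (level_scheme) {
        X <- if (is.null(features))
            featureMatrix(corpus, "full_contour", scale = scale)
        else as.matrix(features)
        H <- splitHalves(t(X))            # halves as 15 x n; transpose back
        H1 <- t(H$first); H2 <- t(H$second)
        codes <- toneToCode(tone, scheme)
        if (mode == "separate") {
            r1 <- .trainPredict(recognizer, H1[tr, , drop = FALSE],
                                codes[tr, "first"], H1[te, , drop = FALSE],
                                seed, svm_grid, folds, tune_max_n, som,
                                scale_features)
            r2 <- .trainPredict(recognizer, H2[tr, , drop = FALSE],
                                codes[tr, "second"], H2[te, , drop = FALSE],
                                seed + 1L, svm_grid, folds, tune_max_n, som,
                                scale_features)
            hyper <- list(first_half = r1$hyper, second_half = r2$hyper)
            p1 <- r1$pred; p2 <- r2$pred
        } else {
            r <- .trainPredict(recognizer,
                               rbind(H1[tr, , drop = FALSE],
                                     H2[tr, , drop = FALSE]),
                               c(codes[tr, "first"], codes[tr, "second"]),
                               rbind(H1[te, , drop = FALSE],
                                     H2[te, , drop = FALSE]),
                               seed, svm_grid, folds, tune_max_n, som,
                               scale_features)
            hyper <- list(pooled = r$hyper)
            p1 <- r$pred[seq_along(te)]
            p2 <- r$pred[seq_along(te) + length(te)]
        }
        predicted <- codeToTone(p1, p2, scheme)
    } else {
        X <- if (is.null(features))
            do.call(featureMatrix,
                    c(list(corpus, scheme, scale = scale,
                           cue_pair = cue_pair,
                           include_onset = include_onset), qta_args))
        else as.matrix(features)
        r <- .trainPredict(recognizer, X[tr, , drop = FALSE], tone[tr],
                           X[te, , drop = FALSE], seed, svm_grid, folds,
                           tune_max_n, som, scale_features)
        hyper <- r$hyper
        predicted <- .asTone(r$pred)
    }

    correct <- !is.na(predicted) & predicted == truth
    per_tone <- vapply(.TONES, function(t) {
        i <- truth == t
        if (any(i)) 100 * sum(correct[i]) / sum(i) else NA_real_
    }, numeric(1))
    names(per_tone) <- paste0("T", .TONES)
    methods::new("RecognitionResult", scheme = scheme, scale = scale,
                 recognizer = recognizer, mode = mode,
                 cue_pair = if (scheme == "profile") cue_pair
                            else NA_character_,
                 include_onset = if (scheme == "qta") include_onset else NA,
                 n_train = length(tr), n_test = length(te),
                 accuracy_pct = 100 * sum(correct) / length(te),
                 macro_accuracy_pct = mean(per_tone, na.rm = TRUE),
                 per_tone_accuracy_pct = per_tone,
                 confusion = toneConfusionMatrix(truth, predicted),
                 truth = as.integer(truth),
                 predicted = as.integer(predicted), seed = seed,
                 hyperparameters = hyper,
                 complexity = as.list(
                     complexityReport(scheme)[, c("expression", "value")]))
}

#' Run the full scheme roster and summarize
#'
#' Runs the six SVM/semitone conditions of the summary comparison — full
#' contour, two-level and five-level codes (separate mode), the best
#' profile cue pair (slope+curve), and qTA with and without onset f0 —
#' plus, optionally, the Hz full-contour and SOM full-contour conditions.
#' The summary ranks schemes by test accuracy (descending), breaking ties
#' by the lower testing-phase complexity value.
#'
#' @param corpus a split [ToneCorpus-class].
#' @param seed integer master seed (per-run seeds are derived from it).
#' @param include_hz also run the Hz-scale full-contour condition.
#' @param include_som also run the SOM full-contour condition.
#' @param ... passed to [runScheme()] (tuning grid, SOM spec, ...).
#' @return List with `results` (named [RecognitionResult-class] list),
#'   `summary` (ranked data.frame) and `complexity` (the full ledger).
#' @export
runAll <- function(corpus, seed = 1L, include_hz = FALSE,
                   include_som = FALSE, ...) {
    seed <- as.integer(seed)
    qta_features <- featureMatrix(corpus, "qta", include_onset = TRUE)
    roster <- list(
        full_contour = list(scheme = "full_contour"),
        two_level = list(scheme = "two_level", mode = "separate"),
        five_level = list(scheme = "five_level", mode = "separate"),
        profile_slope_curve = list(scheme = "profile",
                                   cue_pair = "slope+curve"),
        qta = list(scheme = "qta",
                   features = qta_features[, c("m", "b", "tau")]),
        qta_onset = list(scheme = "qta", include_onset = TRUE,
                         features = qta_features))
    if (include_hz)
        roster$full_contour_hz <- list(scheme = "full_contour", scale = "hz")
    if (include_som)
        roster$full_contour_som <- list(scheme = "full_contour",
                                        recognizer = "som")
    results <- vector("list", length(roster))
    names(results) <- names(roster)
    extra <- list(...)
    for (i in seq_along(roster))
        results[[i]] <- do.call(runScheme,
                                c(list(corpus), roster[[i]],
                                  list(seed = seed + i - 1L), extra))
    summary <- data.frame(
        condition = names(results),
        scheme = vapply(results, function(r) r@scheme, character(1)),
        scale = vapply(results, function(r) r@scale, character(1)),
        recognizer = vapply(results, function(r) r@recognizer, character(1)),
        accuracy_pct = vapply(results, toneAccuracy, numeric(1)),
        complexity_value = vapply(results,
                                  function(r) as.numeric(r@complexity$value),
                                  numeric(1)))
    summary <- summary[order(-summary$accuracy_pct,
                             summary$complexity_value), ]
    rownames(summary) <- NULL
    list(results = results, summary = summary,
         complexity = complexityReport())
}
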