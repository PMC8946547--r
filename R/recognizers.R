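## The two trainable recognizers: a supervised maximum-margin classifier
## (RBF-kernel SVM, one-vs-one with majority voting, as in libsvm) and an
## unsupervised self-organizing map with firing-frequency tone labelling.

#' Candidate (cost, gamma) grid for SVM tuning
#'
#' Powers of two: by default cost over 2^-1..2^7 and gamma over 2^-7..2^1
#' in steps of two octaves (a 5 x 5 grid).
#'
#' @param cost,gamma positive numeric candidate vectors.
#' @return data.frame of all (cost, gamma) combinations.
#' @export
svmGrid <- function(cost = 2^seq(-1, 7, by = 2), gamma = 2^seq(-7, 1, by = 2)) {
    stopifnot(all(cost > 0), all(gamma > 0))
    expand.grid(cost = sort(cost), gamma = sort(gamma),
                KEEP.OUT.ATTRS = FALSE)
}

#' Train an RBF-kernel SVM with cross-validated hyperparameter selection
#'
#' Multiclass problems are decomposed one-vs-one into `n(n-1)/2` binary
#' tasks combined by majority voting (libsvm's native strategy).  The
#' `(cost, gamma)` pair maximizing mean `folds`-fold cross-validation
#' accuracy on the training set is selected (ties go to the smaller cost,
#' then the smaller gamma) and the final model is refit on all training
#' data.  Deterministic given `seed`.
#'
#' Features are fed unscaled by default: on raw Hz or semitone contours
#' the absolute pitch height is informative and standardization would
#' discard it.  Set `scale = TRUE` to standardize.
#'
#' @param x numeric feature matrix, one row per token.
#' @param y class labels (coerced to factor; at least 2 classes).
#' @param grid data.frame of `(cost, gamma)` candidates, see [svmGrid()].
#' @param folds integer >= 2, cross-validation folds.
#' @param seed optional integer seed for fold assignment / tuning subsample.
#' @param scale logical, standardize features inside the SVM.
#' @param tune_max_n cap on the number of training rows used during grid
#'   search (the final refit always uses all rows); `Inf` to disable.
#' @return Object of class `svmToneModel`: the fitted e1071/libsvm model
#'   plus `cost`, `gamma` and the achieved `cv_accuracy`.
#' @export
svmTrain <- function(x, y, grid = svmGrid(), folds = 5L, seed = NULL,
                     scale = FALSE, tune_max_n = Inf) {
    x <- as.matrix(x)
    y <- factor(y)
    if (nlevels(y) < 2L)
        stop("need at least 2 classes to train a classifier")
    if (nrow(x) != length(y))
        stop("feature/label length mismatch")
    stopifnot(folds >= 2L, nrow(grid) >= 1L)
    grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
    cv_acc <- NA_real_
    if (nrow(grid) == 1L) {
        best <- grid[1L, ]
    } else {
        sel <- .withSeed(seed, {
            idx <- seq_len(nrow(x))
            if (is.finite(tune_max_n) && nrow(x) > tune_max_n)
                idx <- sort(sample(idx, tune_max_n))
            fold <- sample(rep_len(seq_len(folds), length(idx)))
            list(idx = idx, fold = fold)
        })
        xt <- x[sel$idx, , drop = FALSE]
        yt <- droplevels(y[sel$idx])
        best <- grid[1L, ]
        best_acc <- -Inf
        for (g in seq_len(nrow(grid))) {
            acc <- vapply(seq_len(folds), function(k) {
                tr <- sel$fold != k
                if (nlevels(droplevels(yt[tr])) < 2L)
                    return(NA_real_)
                m <- e1071::svm(xt[tr, , drop = FALSE], yt[tr],
                                kernel = "radial", cost = grid$cost[g],
                                gamma = grid$gamma[g], scale = scale)
                mean(predict(m, xt[!tr, , drop = FALSE]) == yt[!tr])
            }, numeric(1))
            acc <- mean(acc, na.rm = TRUE)
            if (acc > best_acc + 1e-12) {      # strict: ties keep smaller
                best_acc <- acc                # cost, then smaller gamma
                best <- grid[g, ]
            }
        }
        cv_acc <- best_acc
    }
    model <- e1071::svm(x, y, kernel = "radial", cost = best$cost,
                        gamma = best$gamma, scale = scale)
    structure(list(model = model, cost = best$cost, gamma = best$gamma,
                   cv_accuracy = cv_acc, levels = levels(y),
                   n_features = ncol(x)),
              class = "svmToneModel")
}

#' Predict classes with a trained SVM
#'
#' One-vs-one majority voting over the binary machines; stateless, one
#' label per input row.
#'
#' @param fit an `svmToneModel` from [svmTrain()].
#' @param x numeric feature matrix with the training dimensionality.
#' @return Factor of predicted class labels.
#' @export
svmPredict <- function(fit, x) {
    stopifnot(inherits(fit, "svmToneModel"))
    x <- as.matrix(x)
    if (ncol(x) != fit$n_features)
        stop("feature dimension mismatch: model expects ", fit$n_features,
             ", got ", ncol(x))
    predict(fit$model, x)
}

#' Self-organizing map specification
#'
#' Defaults follow common SOM practice for a 10 x 10 rectangular map of
#' 100 prototype units: Gaussian neighborhood, 100 epochs of online
#' training with the learning rate decaying linearly 0.5 -> 0.01 and the
#' neighborhood radius 5 -> 1, prototypes initialized from random training
#' rows.  A unit is labelled with a tone when at least `label_threshold`
#' (68%) of the training tokens firing it carry that tone.
#'
#' @param rows,cols map dimensions.
#' @param epochs passes over the training data.
#' @param lr learning-rate schedule `(start, end)`.
#' @param radius neighborhood-radius schedule `(start, end)`, grid units.
#' @param seed integer seed for initialization and presentation order.
#' @param label_threshold firing-share threshold in (0, 1].
#' @return A list of class `somSpec`.
#' @export
somSpec <- function(rows = 10L, cols = 10L, epochs = 100L, lr = c(0.5, 0.01),
                    radius = c(5, 1), seed = 42L, label_threshold = 0.68) {
    stopifnot(rows >= 1L, cols >= 1L, epochs >= 1L, length(lr) == 2L,
              all(lr > 0), length(radius) == 2L, all(radius > 0),
              label_threshold > 0, label_threshold <= 1)
    structure(list(rows = as.integer(rows), cols = as.integer(cols),
                   epochs = as.integer(epochs), lr = as.numeric(lr),
                   radius = as.numeric(radius), seed = as.integer(seed),
                   label_threshold = label_threshold),
              class = "somSpec")
}

## Row index of the best-matching unit for each row of x (ties -> lowest
## unit index, row-major order).
.somBmu <- function(proto, x) {
    d2 <- outer(rowSums(x^2), rowSums(proto^2), `+`) -
        2 * x %*% t(proto)
    max.col(-d2, ties.method = "first")
}

#' Train a self-organizing map on feature vectors
#'
#' Online Kohonen training: at each step the best-matching unit (smallest
#' Euclidean distance, ties to the lowest unit index) and its Gaussian
#' neighborhood move toward the presented vector.  Learning rate and
#' radius decay linearly over all presentation steps.  Deterministic given
#' `spec$seed`.
#'
#' @param x numeric feature matrix, one row per token (>= 1 row).
#' @param spec a [somSpec()].
#' @return Object of class `somToneMap`: `prototypes`
#'   (`rows*cols x n_features`, row-major unit order), the grid layout and
#'   the quantization error after the first and last epoch.
#' @export
somTrain <- function(x, spec = somSpec()) {
    x <- as.matrix(x)
    if (nrow(x) < 1L)
        stop("need at least one feature vector")
    stopifnot(inherits(spec, "somSpec"))
    n_units <- spec$rows * spec$cols
    gridpos <- cbind(row = rep(seq_len(spec$rows), each = spec$cols),
                     col = rep(seq_len(spec$cols), times = spec$rows))
    st <- .withSeed(spec$seed, {
        init <- x[sample(nrow(x), n_units, replace = nrow(x) < n_units), ,
                  drop = FALSE]
        ord <- unlist(lapply(seq_len(spec$epochs),
                             function(e) sample(nrow(x))))
        list(init = init, ord = ord)
    })
    total <- length(st$ord)
    frac <- (seq_len(total) - 1) / max(total - 1, 1)
    lr_t <- spec$lr[1L] + (spec$lr[2L] - spec$lr[1L]) * frac
    rad_t <- spec$radius[1L] + (spec$radius[2L] - spec$radius[1L]) * frac
    per_epoch <- nrow(x)
    first <- seq_len(per_epoch)
    proto <- som_train_cpp(x, st$init, st$ord[first], lr_t[first],
                           rad_t[first], gridpos)
    qe1 <- mean(sqrt(rowSums((x - proto[.somBmu(proto, x), ,
                                        drop = FALSE])^2)))
    if (spec$epochs > 1L) {
        rest <- (per_epoch + 1L):total
        proto <- som_train_cpp(x, proto, st$ord[rest], lr_t[rest],
                               rad_t[rest], gridpos)
    }
    qe_final <- mean(sqrt(rowSums((x - proto[.somBmu(proto, x), ,
                                             drop = FALSE])^2)))
    structure(list(prototypes = proto, rows = spec$rows, cols = spec$cols,
                   gridpos = gridpos, spec = spec,
                   qe = c(first_epoch = qe1, final_epoch = qe_final)),
              class = "somToneMap")
}

#' Label SOM units by firing frequency
#'
#' Every training vector fires its best-matching unit; a unit whose firing
#' distribution gives one class a share of at least `threshold` is
#' labelled with that class, otherwise (including units never fired) it
#' stays unlabelled.
#'
#' @param map a `somToneMap` from [somTrain()].
#' @param x training feature matrix.
#' @param y training class labels.
#' @param threshold firing share required to label a unit (default: the
#'   spec's `label_threshold`).
#' @return Object of class `somLabelling` with the per-unit firing
#'   `counts`, `shares` and the unit `labels` (`NA` = unlabelled).
#' @export
somLabelUnits <- function(map, x, y, threshold = map$spec$label_threshold) {
    stopifnot(inherits(map, "somToneMap"), threshold > 0, threshold <= 1)
    x <- as.matrix(x)
    y <- factor(y)
    bmu <- .somBmu(map$prototypes, x)
    n_units <- nrow(map$prototypes)
    counts <- matrix(0L, n_units, nlevels(y),
                     dimnames = list(NULL, levels(y)))
    tab <- table(factor(bmu, levels = seq_len(n_units)), y)
    counts[] <- as.integer(tab)
    tot <- rowSums(counts)
    shares <- counts / ifelse(tot > 0, tot, 1)
    labels <- rep(NA_character_, n_units)
    for (u in which(tot > 0)) {
        best <- which.max(shares[u, ])
        if (shares[u, best] >= threshold)
            labels[u] <- levels(y)[best]
    }
    structure(list(counts = counts, shares = shares, labels = labels,
                   threshold = threshold, class_levels = levels(y)),
              class = "somLabelling")
}

#' Classify feature vectors with a labelled SOM
#'
#' Each vector maps to its best-matching unit and receives that unit's
#' label; vectors landing on unlabelled units get `NA` (counted as errors
#' in downstream accuracies).
#'
#' @param map a `somToneMap`.
#' @param labelling a `somLabelling` from [somLabelUnits()].
#' @param x feature matrix with the training dimensionality.
#' @return Character vector of labels with `NA` for unlabelled outcomes.
#' @export
somPredict <- function(map, labelling, x) {
    stopifnot(inherits(map, "somToneMap"), inherits(labelling, "somLabelling"))
    x <- as.matrix(x)
    if (ncol(x) != ncol(map$prototypes))
        stop("feature dimension mismatch: map expects ",
             ncol(map$prototypes), ", got ", ncol(x))
    labelling$labels[.somBmu(map$prototypes, x)]
}
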