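# Small deterministic 4-class point clouds for classifier contracts.
makeBlobs <- function(n_per = 20, centers = rbind(c(0, 0), c(10, 0),
                                                  c(0, 10), c(10, 10)),
                      sd = 0.3, seed = 1) {
    set.seed(seed)
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
        cbind(rnorm(n_per, centers[k, 1], sd),
              rnorm(n_per, centers[k, 2], sd))))
    list(x = x, y = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("one-vs-one decomposition yields n(n-1)/2 binary machines", {
    for (n_cls in 2:5) {
        centers <- cbind(seq_len(n_cls) * 10, 0)
        blobs <- makeBlobs(10, centers)
        fit <- svmTrain(blobs$x, blobs$y, grid = fixedGrid())
        expect_equal(length(fit$model$rho), n_cls * (n_cls - 1) / 2)
    }
})

test_that("the SVM separates well-separated classes perfectly", {
    blobs <- makeBlobs()
    fit <- svmTrain(blobs$x, blobs$y, grid = svmGrid(c(1, 8), c(0.125, 0.5)),
                    seed = 3)
    expect_equal(fit$cv_accuracy, 1)
    pred <- svmPredict(fit, blobs$x)
    expect_equal(as.integer(as.character(pred)), blobs$y)
    ## single vector in, single label out; permutation equivariance
    expect_length(svmPredict(fit, blobs$x[1, , drop = FALSE]), 1L)
    perm <- sample(nrow(blobs$x))
    expect_equal(svmPredict(fit, blobs$x[perm, ]),
                 svmPredict(fit, blobs$x)[perm], ignore_attr = TRUE)
})

test_that("grid selection is deterministic with documented tie-breaks", {
    blobs <- makeBlobs(sd = 3, seed = 7)     # overlapping: imperfect CV
    f1 <- svmTrain(blobs$x, blobs$y, seed = 11)
    f2 <- svmTrain(blobs$x, blobs$y, seed = 11)
    expect_identical(c(f1$cost, f1$gamma), c(f2$cost, f2$gamma))
    expect_identical(f1$cv_accuracy, f2$cv_accuracy)
    ## a perfectly separable problem ties everywhere near the top:
    ## the smallest (cost, gamma) candidate must win
    sep <- makeBlobs(10, sd = 0.1, seed = 2)
    fs <- svmTrain(sep$x, sep$y, grid = svmGrid(c(2, 8), c(0.25, 1)),
                   seed = 1)
    expect_equal(fs$cv_accuracy, 1)
    expect_equal(fs$cost, 2)
    expect_equal(fs$gamma, 0.25)
    expect_error(svmTrain(blobs$x, rep(1, nrow(blobs$x))), "2 classes")
    expect_error(svmPredict(f1, blobs$x[, 1, drop = FALSE]), "dimension")
})

test_that("SOM training produces the specified prototype sheet", {
    blobs <- makeBlobs(30, seed = 5)
    map <- somTrain(blobs$x, somSpec(epochs = 30, seed = 9))
    expect_equal(dim(map$prototypes), c(100L, 2L))
    ## deterministic given the seed
    map2 <- somTrain(blobs$x, somSpec(epochs = 30, seed = 9))
    expect_identical(map$prototypes, map2$prototypes)
    expect_false(identical(
        map$prototypes,
        somTrain(blobs$x, somSpec(epochs = 30, seed = 10))$prototypes))
    ## quantization error does not increase after the first epoch
    expect_lte(map$qe["final_epoch"], map$qe["first_epoch"] + 1e-9)
    ## degenerate data: every prototype converges to the single point
    same <- matrix(rep(c(3, 4), each = 120), ncol = 2)
    dmap <- somTrain(same, somSpec(epochs = 20, seed = 1))
    expect_lt(dmap$qe["final_epoch"], 1e-3)
    expect_true(all(abs(sweep(dmap$prototypes, 2, c(3, 4))) < 0.5))
    expect_error(somTrain(blobs$x[0, , drop = FALSE]), "at least one")
})

test_that("firing-frequency labelling applies the threshold rule", {
    ## two prototype units, hand-placed; firing shares known by design
    map <- structure(list(prototypes = rbind(c(0, 0), c(10, 10)),
                          rows = 1L, cols = 2L,
                          gridpos = cbind(c(1, 1), c(1, 2)),
                          spec = somSpec(rows = 1, cols = 2)),
                     class = "somToneMap")
    x <- rbind(matrix(0, 7, 2), matrix(0.1, 3, 2), matrix(10, 4, 2))
    y <- c(rep(1, 7), rep(2, 3), rep(2, 2), rep(3, 2))
    lab <- somLabelUnits(map, x, y, threshold = 0.68)
    ## unit 1: shares (0.7, 0.3) -> labelled class 1
    expect_identical(lab$labels[1], "1")
    ## unit 2: shares (0.5, 0.5) -> below threshold, unlabelled
    expect_true(is.na(lab$labels[2]))
    ## firing shares of fired units sum to 1
    fired <- rowSums(lab$counts) > 0
    expect_equal(unname(rowSums(lab$shares[fired, , drop = FALSE])),
                 rep(1, sum(fired)), tolerance = 1e-12)
    ## never-fired units stay unlabelled
    x1 <- matrix(0, 5, 2); y1 <- rep(1, 5)
    lab1 <- somLabelUnits(map, x1, y1)
    expect_true(is.na(lab1$labels[2]))
    ## raising the threshold never labels more units
    blobs <- makeBlobs(30, sd = 2, seed = 12)
    bmap <- somTrain(blobs$x, somSpec(epochs = 20, seed = 3))
    n_lab <- vapply(c(0.5, 0.68, 0.9, 1),
                    function(th) sum(!is.na(
                        somLabelUnits(bmap, blobs$x, blobs$y, th)$labels)),
                    numeric(1))
    expect_true(all(diff(n_lab) <= 0))
})

test_that("SOM prediction maps vectors to their unit's label", {
    map <- structure(list(prototypes = rbind(c(0, 0), c(10, 10), c(20, 20)),
                          rows = 1L, cols = 3L,
                          gridpos = cbind(rep(1, 3), 1:3),
                          spec = somSpec(rows = 1, cols = 3)),
                     class = "somToneMap")
    lab <- structure(list(labels = c("4", NA, "2"), threshold = 0.68,
                          class_levels = c("2", "4")),
                     class = "somLabelling")
    ## exact prototype match -> that unit's tone
    expect_identical(somPredict(map, lab, rbind(c(0, 0))), "4")
    ## nearest an unlabelled unit -> NA
    expect_true(is.na(somPredict(map, lab, rbind(c(10.2, 9.9)))))
    ## equidistant between units 1 and 2 -> lowest unit index wins
    expect_identical(somPredict(map, lab, rbind(c(5, 5))), c("4"))
    expect_error(somPredict(map, lab, matrix(0, 1, 3)), "dimension")
})
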