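# One split separable corpus shared across the driver tests.
separableCorpus <- local({
    corpus <- NULL
    function() {
        if (is.null(corpus))
            corpus <<- splitCorpus(buildCorpus(separableConfig(), seed = 8),
                                   seed = 8)
        corpus
    }
})

test_that("confusion matrices count by hand and normalize by row", {
    cm <- toneConfusionMatrix(c(1, 1, 2), c(1, 2, 2))
    expect_equal(unname(cm["T1", ]), c(50, 50, 0, 0, 0))
    expect_equal(unname(cm["T2", ]), c(0, 100, 0, 0, 0))
    expect_equal(unname(cm["T3", ]), rep(0, 5))
    ## all correct: 100% diagonal
    cm2 <- toneConfusionMatrix(1:4, 1:4)
    expect_equal(unname(diag(cm2[, 1:4])), rep(100, 4))
    ## unlabelled predictions land in the 'none' column; rows still sum 100
    cm3 <- toneConfusionMatrix(c(1, 1, 1, 4), c(1, NA, NA, 4))
    expect_equal(unname(cm3["T1", ]), c(100 / 3, 0, 0, 0, 200 / 3))
    expect_equal(unname(rowSums(cm3[c(1, 4), ])), c(100, 100),
                 tolerance = 1e-6)
    expect_error(toneConfusionMatrix(1:3, 1:2), "equal length")
})

test_that("the complexity ledger reproduces the scheme accounting", {
    cr <- complexityReport()
    expect_identical(cr$scheme, c("full_contour", "two_level", "five_level",
                                  "profile", "qta"))
    expect_equal(cr$value[cr$scheme == "full_contour"], 30L * 4L)
    expect_equal(cr$value[cr$scheme == "two_level"], 61L)
    expect_equal(cr$value[cr$scheme == "five_level"], 150L)
    expect_equal(cr$value[cr$scheme == "profile"], 27008L)
    expect_equal(cr$value[cr$scheme == "qta"], 27012L)
    expect_identical(cr$expression[1], "O(30 x 4)")
    expect_identical(cr$expression[2], "O(15 x 2) x 2 + 1")
    ## two-level is the only scheme cheaper than the full contour
    full <- cr$value[cr$scheme == "full_contour"]
    expect_identical(cr$scheme[cr$value < full], "two_level")
    expect_true(cr$value[cr$scheme == "two_level"] < full)
    expect_true(full < cr$value[cr$scheme == "qta"])
    expect_error(complexityReport("mfcc"), "unknown scheme")
})

test_that("the full-contour scheme hits the ceiling on separable data", {
    corpus <- separableCorpus()
    r <- runScheme(corpus, "full_contour", seed = 1, svm_grid = fixedGrid())
    expect_equal(toneAccuracy(r), 100)
    expect_equal(unname(diag(toneConfusion(r)[, 1:4])), rep(100, 4))
    expect_equal(r@n_test, sum(corpusSplit(corpus) == "test"))
    ## accuracy recomputes from the stored predictions
    expect_equal(toneAccuracy(r),
                 100 * mean(!is.na(r@predicted) & r@predicted == r@truth))
    ## result serializes to a complete list
    lst <- resultToList(r)
    expect_equal(lst$accuracy_pct, 100)
    expect_equal(lst$complexity$value, 120L)
})

test_that("level schemes combine half-codes and score no-match as error", {
    corpus <- separableCorpus()
    r_sep <- runScheme(corpus, "five_level", mode = "separate", seed = 2,
                       svm_grid = fixedGrid())
    r_tog <- runScheme(corpus, "five_level", mode = "together", seed = 2,
                       svm_grid = fixedGrid())
    expect_equal(r_sep@n_test, r_tog@n_test)
    expect_gt(toneAccuracy(r_sep), 95)
    ## hand-check the code intersection on the stored predictions: any
    ## non-NA prediction must be one of the four defined tones
    expect_true(all(is.na(r_sep@predicted) | r_sep@predicted %in% 1:4))
    ## the no-match share is exactly the 'none' confusion mass
    none_share <- sum(is.na(r_sep@predicted)) / r_sep@n_test
    tone_n <- tabulate(r_sep@truth, 4)
    none_from_cm <- sum(toneConfusion(r_sep)[, "none"] / 100 * tone_n) /
        sum(tone_n)
    expect_equal(none_share, none_from_cm, tolerance = 1e-9)
})

test_that("scheme/recognizer combinations are validated", {
    corpus <- separableCorpus()
    expect_error(runScheme(corpus, "qta", scale = "hz"), "semitone")
    expect_error(runScheme(corpus, "profile", recognizer = "som"),
                 "contour-based")
    expect_error(runScheme(corpus, "full_contour", include_onset = TRUE),
                 "qTA")
    expect_error(runScheme(corpus, "profile", cue_pair = "slope+overall",
                           svm_grid = fixedGrid()), "cue pair")
    unsplit <- buildCorpus(smallConfig(), seed = 1)
    expect_error(runScheme(unsplit, "full_contour"), "split")
})

test_that("identical seeds reproduce a run exactly", {
    corpus <- separableCorpus()
    r1 <- runScheme(corpus, "profile", seed = 5, svm_grid = fixedGrid())
    r2 <- runScheme(corpus, "profile", seed = 5, svm_grid = fixedGrid())
    expect_identical(resultToList(r1), resultToList(r2))
})

test_that("the roster run ranks schemes and carries the ledger", {
    corpus <- separableCorpus()
    all <- runAll(corpus, seed = 3, svm_grid = fixedGrid(),
                  qta_args = list(grid_n = c(11L, 11L, 8L)))
    expect_length(all$results, 6L)
    expect_setequal(all$summary$condition,
                    c("full_contour", "two_level", "five_level",
                      "profile_slope_curve", "qta", "qta_onset"))
    ## ranked by accuracy descending, ties by lower complexity
    acc <- all$summary$accuracy_pct
    expect_true(all(diff(acc) <= 0))
    ties <- which(diff(acc) == 0)
    expect_true(all(diff(all$summary$complexity_value)[ties] >= 0))
    expect_identical(all$complexity, complexityReport())
    ## qta with onset sees the carryover cue; both qta rows present
    expect_true(all(c("qta", "qta_onset") %in% all$summary$condition))
})
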