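test_that("halving a contour conserves and orders the samples", {
    h <- splitHalves(1:30)
    expect_identical(h$first, 1:15)
    expect_identical(h$second, 16:30)
    expect_identical(c(h$first, h$second), 1:30)
    expect_error(splitHalves(1:29), "30")
    m <- matrix(1:60, nrow = 30)
    hm <- splitHalves(m)
    expect_identical(rbind(hm$first, hm$second), m)
})

test_that("tone/level code mappings are mutually inverse", {
    ## the four defined codes of each alphabet
    expect_equal(unname(toneToCode(2, "two_level")[1, ]), c(0, 1))
    expect_equal(unname(toneToCode(3, "two_level")[1, ]), c(0, 0))
    expect_equal(unname(toneToCode(1, "five_level")[1, ]), c(5, 5))
    expect_equal(unname(toneToCode(4, "five_level")[1, ]), c(5, 3))
    for (scheme in c("two_level", "five_level")) {
        codes <- toneToCode(1:4, scheme)
        expect_identical(codeToTone(codes[, "first"], codes[, "second"],
                                    scheme), 1:4)
    }
    ## five-level codes outside the alphabet have no tone
    expect_true(is.na(codeToTone(5, 4, "five_level")))
    expect_identical(codeToTone(2, 1, "five_level"), 3L)
    ## all four binary codes are covered
    grid <- expand.grid(f = 0:1, s = 0:1)
    expect_false(any(is.na(codeToTone(grid$f, grid$s, "two_level"))))
    expect_error(toneToCode(5, "two_level"), "tone")
})

test_that("parabola fitting recovers its own basis exactly", {
    pf <- fitParabola(rep(90, 30))
    expect_equal(pf@c0, 90, tolerance = 1e-9)
    expect_lt(abs(pf@c1), 1e-9)
    expect_lt(abs(pf@c2), 1e-9)
    expect_lt(pf@rss, 1e-15)
    ## generate-then-fit with known coefficients
    tc <- seq(0, 1, length.out = 30) - 0.5
    y <- 88 + 6 * tc + (-12) * (tc^2 - 1 / 12)
    pf2 <- fitParabola(y)
    expect_equal(c(pf2@c0, pf2@c1, pf2@c2), c(88, 6, -12), tolerance = 1e-9)
    expect_lt(pf2@rss, 1e-15)
    ## exact line of slope k: c1 = k
    pf3 <- fitParabola(80 + 7 * seq(0, 1, length.out = 30))
    expect_equal(pf3@c1, 7, tolerance = 1e-9)
    expect_error(fitParabola(c(rep(1, 29), NA)), "finite")
})

test_that("parabola fit agrees with the lm() least-squares oracle", {
    contours <- randomContours(25, seed = 31)
    tc <- seq(0, 1, length.out = 30) - 0.5
    for (i in seq_len(nrow(contours))) {
        y <- contours[i, ]
        pf <- fitParabola(y)
        ol <- lm(y ~ I(tc) + I(tc^2 - 1 / 12))
        expect_equal(c(pf@c0, pf@c1, pf@c2), unname(coef(ol)),
                     tolerance = 1e-8)
        expect_equal(pf@rss, sum(resid(ol)^2), tolerance = 1e-8)
    }
})

test_that("broken-line fitting recovers exact two-piece generators", {
    tt <- seq(0, 1, length.out = 30)
    ## slopes +10 / -10 with the break at sample 15 (0-based, t = 15/29)
    d_true <- tt[16]
    y <- ifelse(tt < d_true, 80 + 10 * tt,
                80 + 10 * d_true + 10 * d_true - 10 * tt)
    ## rewrite right piece as a2 + b2 t continuous at d
    y <- ifelse(tt < d_true, 80 + 10 * tt, (80 + 20 * d_true) - 10 * tt)
    bl <- fitBrokenLine(y)
    expect_equal(bl@b1, 10, tolerance = 1e-9)
    expect_equal(bl@b2, -10, tolerance = 1e-9)
    expect_equal(bl@d, d_true, tolerance = 1e-9)
    expect_lt(bl@rss, 1e-15)
    ## an exact single line fits every breakpoint: smallest d wins
    line <- 70 + 5 * tt
    bl2 <- fitBrokenLine(line)
    expect_equal(bl2@b1, 5, tolerance = 1e-9)
    expect_equal(bl2@b2, 5, tolerance = 1e-9)
    expect_equal(bl2@d, tt[4], tolerance = 1e-9)   # candidate j = 3
    ## a line is a special case: broken-line rss never exceeds line rss
    contours <- randomContours(20, seed = 37)
    for (i in seq_len(nrow(contours))) {
        y <- contours[i, ]
        lf <- lm(y ~ tt)
        expect_lte(fitBrokenLine(y)@rss, sum(resid(lf)^2) + 1e-10)
    }
})

test_that("broken-line scan matches an independent exhaustive oracle", {
    ## brute-force re-implementation with lm() per candidate breakpoint
    oracle <- function(y) {
        tt <- seq(0, 1, length.out = length(y))
        best <- NULL
        for (j in 3:(length(y) - 3L)) {
            li <- seq_len(j); ri <- (j + 1L):length(y)
            fl <- lm(y[li] ~ tt[li]); fr <- lm(y[ri] ~ tt[ri])
            rss <- sum(resid(fl)^2) + sum(resid(fr)^2)
            if (is.null(best) || rss < best$rss)
                best <- list(d = tt[j + 1L], rss = rss,
                             b1 = unname(coef(fl)[2]),
                             b2 = unname(coef(fr)[2]))
        }
        best
    }
    contours <- randomContours(40, seed = 41)
    for (i in seq_len(nrow(contours))) {
        y <- contours[i, ]
        bl <- fitBrokenLine(y)
        ex <- oracle(y)
        expect_equal(bl@d, ex$d)
        expect_equal(bl@rss, ex$rss, tolerance = 1e-8)
        expect_equal(bl@b1, ex$b1, tolerance = 1e-6)
        expect_equal(bl@b2, ex$b2, tolerance = 1e-6)
    }
})

test_that("profile cues derive from the fits with the stated sign rules", {
    tt <- seq(0, 1, length.out = 30)
    ## symmetric V: fall -k then rise +k, break at 1/2
    k <- 8
    y <- ifelse(tt < 0.5, 90 - k * tt, 90 - k + k * tt)
    cues <- deriveProfileCues(fitParabola(y), fitBrokenLine(y))
    expect_equal(cues@onglide, -k / 2, tolerance = 0.3)
    expect_equal(cues@offglide, k / 2, tolerance = 0.3)
    expect_equal(cues@overall, 0, tolerance = 1e-6)
    ## straight line: onglide + offglide = overall = slope
    y2 <- 85 + 6 * tt
    cues2 <- deriveProfileCues(fitParabola(y2), fitBrokenLine(y2))
    expect_equal(cues2@overall, 6, tolerance = 1e-6)
    expect_equal(cues2@onglide + cues2@offglide, cues2@overall,
                 tolerance = 1e-9)
    expect_equal(cues2@slope, 6, tolerance = 1e-9)
    ## additivity holds for arbitrary contours under the left-piece rule
    contours <- randomContours(10, seed = 43)
    for (i in seq_len(nrow(contours))) {
        y <- contours[i, ]
        cu <- deriveProfileCues(fitParabola(y), fitBrokenLine(y))
        expect_equal(cu@onglide + cu@offglide, cu@overall, tolerance = 1e-9)
    }
})

test_that("cue pairs project in the documented order and reject unknowns", {
    cues <- methods::new("ProfileCues", slope = 6, curve = -12, onglide = 2,
                         offglide = 3, overall = 5)
    expect_equal(unname(makePairFeatures(cues, "slope+curve")), c(6, -12))
    expect_equal(unname(makePairFeatures(cues, "onglide+offglide")), c(2, 3))
    expect_equal(unname(makePairFeatures(cues, "offglide+overall")), c(3, 5))
    expect_error(makePairFeatures(cues, "slope+overall"), "unknown cue pair")
    expect_length(cuePairNames(), 5L)
})

test_that("qTA feature vectors expose (m, b, tau[, onset]) in order", {
    tgt <- QtaTarget(m = -48, b = 6, tau = 0.03, onset_f0 = 1.5)
    expect_equal(unname(qtaFeatureVector(tgt)), c(-48, 6, 0.03))
    expect_length(qtaFeatureVector(tgt), 3L)
    v4 <- qtaFeatureVector(tgt, include_onset = TRUE)
    expect_length(v4, 4L)
    expect_equal(unname(v4), c(-48, 6, 0.03, 1.5))
    expect_identical(names(v4), c("m", "b", "tau", "onset_f0"))
})

test_that("corpus-level feature extraction matches the per-contour API", {
    corpus <- buildCorpus(smallConfig(), seed = 17)
    X <- featureMatrix(corpus, "profile", cue_pair = "curve+overall")
    expect_equal(dim(X), c(ncol(corpus), 2L))
    f0 <- f0Samples(corpus)
    for (i in c(1L, 50L, ncol(corpus))) {
        cu <- deriveProfileCues(fitParabola(f0[, i]), fitBrokenLine(f0[, i]))
        expect_equal(unname(X[i, ]),
                     unname(makePairFeatures(cu, "curve+overall")),
                     tolerance = 1e-9)
    }
    full <- featureMatrix(corpus, "full_contour")
    expect_identical(dim(full), c(ncol(corpus), 30L))
    expect_equal(unname(full[3, ]), unname(f0[, 3]))
    expect_error(featureMatrix(corpus, "qta", scale = "hz"), "semitone")
})
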