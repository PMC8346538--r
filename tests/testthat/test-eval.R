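test_that("AUC follows the Mann-Whitney pair convention", {
    expect_equal(aucScore(c(3, 4, 1, 2), c("case", "case", "control",
                                           "control")), 1)
    expect_equal(aucScore(rep(1, 6), rep(c("case", "control"), 3)), 0.5)
    expect_equal(aucScore(c(0.9, 0.4, 0.5, 0.1),
                          c("case", "case", "control", "control")), 3 / 4)
    expect_error(aucScore(1:3, rep("case", 3)), "both classes")
})

test_that("AUC equals brute-force pair enumeration, with ties at half", {
    set.seed(15)
    for (i in 1:5) {
        s <- sample(1:8, 30, replace = TRUE)   # many ties
        y <- sample(c("case", "control"), 30, replace = TRUE,
                    prob = c(0.4, 0.6))
        if (length(unique(y)) < 2) next
        cs <- s[y == "case"]; ct <- s[y == "control"]
        pairs <- outer(cs, ct, function(a, b)
            (a > b) + 0.5 * (a == b))
        expect_equal(aucScore(s, y), mean(pairs))
    }
})

test_that("AUC is invariant under strictly increasing transforms", {
    set.seed(16)
    s <- rnorm(40)
    y <- rep(c("case", "control"), 20)
    a <- aucScore(s, y)
    expect_equal(aucScore(exp(s), y), a)
    expect_equal(aucScore(3 * s + 7, y), a)
})

test_that("AUC agrees with an independent ROC implementation", {
    set.seed(17)
    s <- rnorm(200) + rep(c(0.8, 0), c(80, 120))
    y <- rep(c("case", "control"), c(80, 120))
    ref <- suppressMessages(pROC::auc(pROC::roc(
        response = y, predictor = s, levels = c("control", "case"),
        direction = "<")))
    expect_equal(aucScore(s, y), as.numeric(ref), tolerance = 1e-12)
})

test_that("MCC matches its formula and conventions", {
    expect_equal(mccScore(10, 0, 10, 0), 1)
    expect_equal(mccScore(10, 10, 0, 0), 0)   # degenerate denominator -> 0
    # counts implied by the published first-cohort stratification
    expect_equal(mccScore(2492, 839, 5330, 805), 0.618371,
                 tolerance = 1e-6)
    # swapping predicted labels negates; swapping both preserves
    set.seed(18)
    for (i in 1:8) {
        cm <- sample(1:40, 4)
        m <- mccScore(cm[1], cm[2], cm[3], cm[4])
        expect_true(abs(m) <= 1)
        expect_equal(mccScore(cm[3], cm[4], cm[1], cm[2]), m)   # both
        expect_equal(mccScore(cm[4], cm[3], cm[2], cm[1]), -m)  # predicted
    }
})

test_that("the MCC-optimal cutoff is found at a separating midpoint", {
    rep_ <- bestMccCutoff(c(0.9, 0.8, 0.1, 0.2),
                          c("case", "case", "control", "control"))
    expect_equal(rep_@mcc, 1)
    expect_equal(rep_@cutoff, 0.5)           # midpoint of 0.2 and 0.8
    expect_equal(rep_@auc, 1)
    expect_equal(unname(rep_@confusion), c(2L, 0L, 2L, 0L))
})

test_that("the cutoff search equals exhaustive candidate evaluation", {
    set.seed(19)
    s <- c(1, 1, 2, 3, 3, 4, 5, 5, 6, 7, 8, 8) + 0.0
    y <- c("control", "case", "control", "case", "control", "case",
           "control", "case", "case", "control", "case", "case")
    rep_ <- bestMccCutoff(s, y)
    u <- sort(unique(s))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    mccs <- vapply(cand, function(cc) {
        pred <- s > cc
        mccScore(sum(pred & y == "case"), sum(pred & y == "control"),
                 sum(!pred & y == "control"), sum(!pred & y == "case"))
    }, numeric(1))
    expect_equal(rep_@mcc, max(mccs))
    expect_equal(rep_@cutoff, cand[which.max(mccs)])
    # the reported mcc equals mcc() recomputed from the reported confusion
    expect_identical(rep_@mcc, mccScore(rep_@confusion))
})

test_that("uninformative scores give near-zero best MCC", {
    for (seed in 1:3) {
        set.seed(seed)
        s <- rnorm(2000)
        y <- sample(rep(c("case", "control"), 1000))
        expect_lt(bestMccCutoff(s, y)@mcc, 0.1)
    }
})

test_that("stratification uses the inclusive low-risk rule", {
    # published first-cohort case stratification: 805 low of 3297
    s <- c(rep(0.0005, 805), rep(0.002, 2492))
    y <- rep("case", 3297)
    s <- c(s, rep(0.0005, 5330), rep(0.002, 839))
    y <- c(y, rep("control", 6169))
    st <- stratifyByScore(s, y, cutoff = 1.11e-3)
    expect_equal(st$pct_low_cases, 24.4)
    expect_equal(st$pct_low_controls, 86.4)
    expect_equal(unname(st$confusion), c(2492L, 839L, 5330L, 805L))

    # switched-cohort controls: 5567 low of 6181
    st2 <- stratifyByScore(c(rep(0, 5567), rep(1, 614)),
                           rep("control", 6181), cutoff = 0)
    expect_equal(st2$pct_low_controls, 90.1)

    # scores exactly at the cutoff are low (inclusive)
    st3 <- stratifyByScore(c(1, 2), c("case", "case"), cutoff = 1)
    expect_equal(length(st3$low), 1L)

    # cutoff below the minimum: nobody is low
    st4 <- stratifyByScore(c(1, 2), c("case", "control"), cutoff = 0.5)
    expect_equal(st4$pct_low_cases, 0)
    expect_equal(st4$pct_low_controls, 0)
})

test_that("rank AUC equals trapezoidal ROC integration on tie-free data", {
    set.seed(20)
    s <- rnorm(150)
    y <- rep(c("case", "control"), c(60, 90))
    # empirical ROC by threshold sweep, trapezoid rule
    thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(t) mean(s[y == "case"] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(s[y == "control"] >= t), numeric(1))
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(aucScore(s, y), trap, tolerance = 1e-12)
})
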