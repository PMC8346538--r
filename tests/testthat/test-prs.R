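test_that("clumping keeps the best proxy and respects chromosomes", {
    g <- rbinom(100, 2, 0.3)
    d <- rbind(g, g)                       # perfect proxies, 10 kb apart
    ge <- makeGe(d, pos = c(1e6, 1e6 + 1e4), ids = c("a", "b"))
    res <- fakeTrainResults(p = c(1e-9, 1e-10), pos = c(1e6, 1e6 + 1e4),
                            ids = c("a", "b"))
    expect_equal(clumpVariants(res, ge, 0.1, 250), "b")  # smaller P wins

    # same dosages but on different chromosomes: both retained
    ge2 <- makeGe(d, chrom = c("1", "2"), pos = c(1e6, 1e6 + 1e4),
                  ids = c("a", "b"))
    res2 <- fakeTrainResults(p = c(1e-9, 1e-10), chrom = c("1", "2"),
                             pos = c(1e6, 1e6 + 1e4), ids = c("a", "b"))
    expect_setequal(clumpVariants(res2, ge2, 0.1, 250), c("a", "b"))
})

test_that("greedy clumping equals an exhaustive re-scanning oracle", {
    set.seed(77)
    n <- 300
    base <- matrix(rbinom(5 * n, 2, 0.4), nrow = 5)
    d <- base[rep(1:5, each = 4), ]
    flip <- matrix(runif(20 * n) < 0.12, nrow = 20)   # decorrelate members
    d[flip] <- sample(0:2, sum(flip), replace = TRUE)
    ge <- makeGe(d, pos = seq(1e6, by = 4e4, length.out = 20))
    res <- fakeTrainResults(p = runif(20, 1e-12, 1e-3),
                            pos = seq(1e6, by = 4e4, length.out = 20))

    got <- clumpVariants(res, ge, r2_threshold = 0.1, window_kb = 250)

    # oracle: naive greedy that re-scans the whole list every round
    r2 <- cor(t(d))^2
    ord <- order(res$p, res$pos)
    alive <- rep(TRUE, 20)
    keep <- character(0)
    repeat {
        cand <- ord[alive[ord]]
        if (!length(cand)) break
        i <- cand[1]
        keep <- c(keep, res$id[i])
        alive[i] <- FALSE
        for (j in which(alive))
            if (res$chrom[j] == res$chrom[i] &&
                abs(res$pos[j] - res$pos[i]) <= 250e3 &&
                r2[i, j] > 0.1) alive[j] <- FALSE
    }
    expect_equal(got, keep)
})

test_that("models are nested over the threshold grid", {
    set.seed(5)
    p <- 10^runif(30, -12, 0)
    res <- fakeTrainResults(p = p, beta = rnorm(30, 0, 0.3),
                            pos = seq(1e6, by = 1e6, length.out = 30))
    ids <- res$id
    m_small <- buildPrsModel(res, ids, 1e-10)
    m_all <- buildPrsModel(res, ids, 1)
    expect_true(all(m_small@entries$id %in% m_all@entries$id))
    grid <- defaultPGrid()
    expect_length(grid, 14L)
    sizes <- vapply(grid, function(th)
        tryCatch(nrow(buildPrsModel(res, ids, th)@entries),
                 error = function(e) 0L), integer(1))
    expect_true(all(diff(sizes) >= 0))     # 14 nested models

    # beta is the training ln OR
    res2 <- fakeTrainResults(p = 1e-9, beta = log(2))
    m <- buildPrsModel(res2, res2$id, 1e-8)
    expect_equal(m@entries$beta, log(2))
    expect_error(buildPrsModel(res2, res2$id, 1e-20), "threshold")
})

test_that("scoring averages beta per non-missing allele", {
    d <- matrix(2, 1, 3)
    ge <- makeGe(d, ids = "v001")
    m <- buildPrsModel(fakeTrainResults(p = 1e-9, beta = 0.5, ids = "v001"),
                       "v001", 1e-8)
    sc <- scorePrs(m, ge)
    expect_equal(sc$prs, rep(0.5 * 2 / (2 * 1), 3))

    # all dosages zero: score 0
    ge0 <- makeGe(matrix(0, 1, 3), ids = "v001")
    expect_equal(scorePrs(m, ge0)$prs, rep(0, 3))

    # 5 variants, one missing dosage for sample 1: divide by 2*4
    set.seed(3)
    d5 <- matrix(sample(0:2, 15, replace = TRUE), 5, 3)
    d5[2, 1] <- NA
    betas <- c(0.5, -0.2, 0.1, 0.3, -0.4)
    ge5 <- makeGe(d5)
    res5 <- fakeTrainResults(p = rep(1e-9, 5), beta = betas)
    m5 <- buildPrsModel(res5, res5$id, 1e-8)
    sc5 <- scorePrs(m5, ge5)
    hand1 <- sum(betas[-2] * d5[-2, 1]) / (2 * 4)
    hand2 <- sum(betas * d5[, 2]) / (2 * 5)
    expect_equal(sc5$prs, c(hand1, hand2, sum(betas * d5[, 3]) / (2 * 5)))
    expect_equal(sc5$m_used, c(4, 5, 5))
})

test_that("scoring is linear in beta and flip-covariant", {
    set.seed(4)
    d <- matrix(sample(0:2, 12, replace = TRUE), 4, 3)
    ge <- makeGe(d)
    res <- fakeTrainResults(p = rep(1e-9, 4), beta = c(0.5, -0.2, 0.1, 0.3))
    m <- buildPrsModel(res, res$id, 1e-8)
    sc <- scorePrs(m, ge)
    m2 <- m; m2@entries$beta <- 2 * m2@entries$beta
    expect_equal(scorePrs(m2, ge)$prs, 2 * sc$prs)

    # representing variant 1 as (-beta, other allele): dosage flips to 2-G,
    # so each score changes by exactly -beta_1 / M_j
    mf <- m
    mf@entries$beta[1] <- -mf@entries$beta[1]
    mf@entries$effect_allele[1] <- "G"
    scf <- scorePrs(mf, ge)
    expect_equal(scf$prs, sc$prs - 0.5 / sc$m_used, tolerance = 1e-12)
})

test_that("model variants absent from the genotypes are counted, not fatal", {
    d <- matrix(sample(0:2, 6, replace = TRUE), 2, 3)
    ge <- makeGe(d)
    res <- fakeTrainResults(p = rep(1e-9, 3), beta = c(0.5, 0.2, 0.9),
                            ids = c("v001", "v002", "zzz"))
    m <- buildPrsModel(res, res$id, 1e-8)
    sc <- scorePrs(m, ge)
    expect_equal(attr(sc, "n_absent"), 1L)
    expect_equal(sc$m_used, rep(2, 3))
    m_gone <- buildPrsModel(res[3, ], "zzz", 1e-8)
    expect_error(scorePrs(m_gone, ge), "no model variant")
})

test_that("threshold selection maximizes test-cohort AUC", {
    # one strong causal common variant
    cfg <- simulationConfig(400, 800, n_null_variants = 300,
                            common_panel = data.frame(maf = 0.3, or_ = 4),
                            rare_panel = data.frame(maf = 0.02, or_ = 1.1),
                            subtype_fraction = 0.05, seed = 17)
    sim <- simulateCohort(cfg)
    ge <- splitCohorts(sim$ge, seed = 17)
    train <- ge[, sampleInfo(ge)$cohort == "A"]
    test <- ge[, sampleInfo(ge)$cohort == "B"]
    train_res <- runAssoc(train, makeCovariates(sampleInfo(train)))
    sel <- selectPThreshold(train_res, train, test)
    n1 <- sum(sampleInfo(test)$phenotype == "case")
    n0 <- sum(sampleInfo(test)$phenotype == "control")
    se_auc <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
    expect_gt(max(sel$grid$auc, na.rm = TRUE), 0.5 + 5 * se_auc)
    expect_equal(nrow(sel$grid), 14L)

    # a grid of one returns it
    sel1 <- selectPThreshold(train_res, train, test, grid = 0.05)
    expect_equal(sel1$best_threshold, 0.05)

    # shuffled labels: every AUC near 0.5
    test_shuf <- test
    cd <- SummarizedExperiment::colData(test_shuf)
    set.seed(1)
    cd$phenotype <- sample(cd$phenotype)
    SummarizedExperiment::colData(test_shuf) <- cd
    sel0 <- selectPThreshold(train_res, train, test_shuf)
    expect_true(all(abs(sel0$grid$auc - 0.5) < 3 * se_auc, na.rm = TRUE))
})
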