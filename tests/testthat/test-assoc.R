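test_that("a binary predictor recovers the 2x2 cross-product odds ratio", {
    # carriers: 30 cases / 10 controls; non-carriers: 170 cases / 190 controls
    g <- c(rep(1, 40), rep(0, 360))
    y <- c(rep(1, 30), rep(0, 10), rep(1, 170), rep(0, 190))
    fit <- logisticAssoc(g, y)
    expect_equal(fit$or_, (30 * 190) / (10 * 170), tolerance = 1e-6)

    # property: random nonzero 2x2 tables
    set.seed(8)
    for (i in 1:10) {
        tab <- matrix(sample(5:50, 4), 2)
        g <- rep(c(1, 1, 0, 0), tab)
        y <- rep(c(1, 0, 1, 0), tab)
        fit <- logisticAssoc(g, y)
        or_tab <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
        expect_equal(fit$or_, or_tab, tolerance = 1e-6)
    }
})

test_that("the IRLS engine matches glm with covariates on dosage data", {
    set.seed(12)
    n <- 400
    g <- rbinom(n, 2, 0.3) + runif(n, 0, 0.1)
    sex <- rbinom(n, 1, 0.5)
    pc <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * g + 0.3 * sex - 0.2 * pc))
    fit <- logisticAssoc(g, y, cbind(sex = sex, pc = pc))
    ref <- glm(y ~ g + sex + pc, family = binomial)
    expect_equal(fit$beta, unname(coef(ref)["g"]), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(ref)["g", "g"])),
                 tolerance = 1e-4)
    expect_equal(fit$test, "wald")
    # Wald CI identity: ln l95 + ln u95 = 2 beta, exactly
    expect_equal(log(fit$l95) + log(fit$u95), 2 * fit$beta,
                 tolerance = 1e-12)
})

test_that("separation triggers a finite Firth estimate", {
    # zero case-carriers: ordinary ML diverges
    g <- c(rep(1, 15), rep(0, 185))
    y <- c(rep(0, 15), rep(1, 90), rep(0, 95))
    fit <- logisticAssoc(g, y)
    expect_equal(fit$test, "firth")
    expect_true(is.finite(fit$beta) && is.finite(fit$se))
    expect_lt(fit$beta, 0)
})

test_that("null variants rarely show |beta| above 3 standard errors", {
    set.seed(33)
    n <- 2000
    d <- matrix(rbinom(n * 200, 2, 0.3), nrow = 200)
    ge <- makeGe(d, phenotype = rep(c("case", "control"), each = n / 2))
    res <- runAssoc(ge)
    expect_gte(mean(abs(res$beta) < 3 * res$se), 0.98)
})

test_that("constant variants are skipped, single-class phenotypes refused", {
    d <- rbind(rep(1, 6), c(0, 1, 2, 0, 1, 2))
    ge <- makeGe(d)
    res <- runAssoc(ge)
    expect_equal(res$test, c("skipped_constant", "wald"))
    expect_true(is.na(res$p[1]))
    ge2 <- makeGe(d, phenotype = rep("case", 6))
    expect_error(runAssoc(ge2), "case and one control")
    expect_error(logisticAssoc(rep(1, 6), rep(1, 6)), "constant|control")
})

test_that("principal components are orthonormal and expose structure", {
    cfg <- simulationConfig(
        300, 300, n_null_variants = 800,
        common_panel = data.frame(maf = 0.25, or_ = 1),
        rare_panel = data.frame(maf = 0.01, or_ = 1),
        structure_fst = 0.5, seed = 3)
    sim <- simulateCohort(cfg)
    pcs <- computePCs(sim$ge, k = 4)
    U <- as.matrix(pcs[, -1])
    expect_lt(max(abs(crossprod(U) - diag(4))), 1e-8)
    # strong divergence: the subpopulations separate cleanly on PC1
    pop <- sim$truth$samples$subpop
    side <- pcs$PC1 > median(pcs$PC1)
    frac1 <- mean(side[pop == 1])
    expect_true(frac1 < 0.005 || frac1 > 0.995)
})

test_that("rank-deficient PC requests and constant variants are handled", {
    d <- matrix(rbinom(40 * 10, 2, 0.4), nrow = 40)
    d[1, ] <- 1                     # constant variant: skipped, no error
    ge <- makeGe(d, maf = rep(0.4, 40))
    expect_error(computePCs(ge, k = 10), "rank")
    pcs <- computePCs(ge, k = 3)
    expect_equal(ncol(pcs), 4L)
})

test_that("genome-wide filtering keeps P equal to alpha (inclusive)", {
    res <- fakeTrainResults(p = c(4e-8, 5e-8, 6e-8))
    hits <- genomeWideHits(res, 5e-8)
    expect_equal(hits$p, c(4e-8, 5e-8))
    expect_equal(nrow(genomeWideHits(res, 1)), 3L)
    expect_equal(nrow(genomeWideHits(res[0, ], 5e-8)), 0L)
    # sorted by chromosome then position
    res2 <- fakeTrainResults(p = rep(1e-9, 4), chrom = c("2", "1", "1", "10"),
                             pos = c(5, 9, 2, 1))
    expect_equal(genomeWideHits(res2)$pos, c(2, 9, 5, 1))
})

test_that("odds-ratio heterogeneity reproduces the published lead-SNP tests", {
    row <- function(or, l, u, id = "v", a1 = "A")
        list(id = id, effect_allele = a1, beta = NA, se = NA,
             or_ = or, l95 = l, u95 = u)
    # HLA-class-II lead: low-PRS stratum vs overall
    h <- orHeterogeneity(row(4.073, 3.616, 4.587), row(6.018, 5.572, 6.5))
    expect_equal(h$p_het, 6.67e-8, tolerance = 0.005)
    # PTPN22 lead
    h <- orHeterogeneity(row(1.87, 1.594, 2.194), row(2.244, 2.048, 2.458))
    expect_equal(h$p_het, 0.052, tolerance = 0.01)
    # INS lead (protective)
    h <- orHeterogeneity(row(0.391, 0.3354, 0.4559),
                         row(0.4442, 0.4098, 0.4815))
    expect_equal(h$p_het, 0.149, tolerance = 0.005)
    # switched-cohort HLA lead
    h <- orHeterogeneity(row(3.809, 3.416, 4.247), row(5.937, 5.503, 6.404))
    expect_equal(h$p_het, 5.49e-11, tolerance = 0.005)
})

test_that("heterogeneity is antisymmetric in z and refuses allele flips", {
    r1 <- list(id = "v", effect_allele = "A", beta = 0.3, se = 0.1)
    r2 <- list(id = "v", effect_allele = "A", beta = 0.8, se = 0.2)
    h12 <- orHeterogeneity(r1, r2)
    h21 <- orHeterogeneity(r2, r1)
    expect_equal(h12$z, -h21$z)
    expect_equal(h12$p_het, h21$p_het)
    # identical records: z = 0, p = 1
    h <- orHeterogeneity(r1, r1)
    expect_equal(h$z, 0)
    expect_equal(h$p_het, 1)
    r3 <- list(id = "v", effect_allele = "G", beta = 0.8, se = 0.2)
    expect_error(orHeterogeneity(r1, r3), "effect allele")
    r4 <- list(id = "w", effect_allele = "A", beta = 0.8, se = 0.2)
    expect_error(orHeterogeneity(r1, r4), "same variant")
})

test_that("genomic inflation equals 1 for flat P and matches brute force", {
    expect_equal(genomicInflation(rep(0.5, 200)), 1)
    set.seed(2)
    p_unif <- runif(10000)
    expect_lt(abs(genomicInflation(p_unif) - 1), 0.05)
    # non-central mixture: compare against a direct median computation
    chi <- c(rchisq(5000, 1), rchisq(5000, 1, ncp = 3))
    p_mix <- pchisq(chi, 1, lower.tail = FALSE)
    expect_equal(genomicInflation(p_mix),
                 median(chi) / qchisq(0.5, 1), tolerance = 1e-10)
    expect_error(genomicInflation(runif(50)), "100")
})

test_that("PC correction removes structure-driven inflation", {
    cfg <- simulationConfig(
        800, 800, n_null_variants = 3000,
        common_panel = data.frame(maf = 0.25, or_ = 1),
        rare_panel = data.frame(maf = 0.01, or_ = 1),
        structure_fst = 0.1, case_pop2_fraction = 0.7,
        control_pop2_fraction = 0.3, seed = 42)
    sim <- simulateCohort(cfg)
    naive <- runAssoc(sim$ge)
    pcs <- computePCs(sim$ge, k = 10)
    corrected <- runAssoc(sim$ge, makeCovariates(sampleInfo(sim$ge), pcs))
    expect_gt(genomicInflation(naive), 1.05)
    expect_gt(genomicInflation(corrected), 0.93)
    expect_lt(genomicInflation(corrected), 1.07)
})
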