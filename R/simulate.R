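#' Build a simulation configuration
#'
#' Defaults emulate a pediatric autoimmune-diabetes-like cohort: a majority
#' subtype driven by a common-variant panel (an HLA-like risk locus with
#' OR 6 at MAF 0.25, a PTPN22-like locus with OR 2.2 at MAF 0.10, and an
#' INS-like protective locus with OR 0.44 at MAF 0.25) and a minority
#' subtype (default 8 percent of cases, inside the 5-10 percent range
#' quoted for antibody-negative presentations) driven by a rare-variant
#' panel spanning MAF 0.002-0.035 and OR 2-9.
#'
#' @param n_cases,n_controls target sample counts.
#' @param n_null_variants effect-free variants, default 1000.
#' @param common_panel,rare_panel data.frames with columns \code{maf},
#'   \code{or_}.
#' @param subtype_fraction minority-subtype share of cases, default 0.08.
#' @param baseline_prevalence marginal case probability of each subtype
#'   model, default 0.005.
#' @param structure_fst Balding-Nichols divergence between two
#'   subpopulations; 0 (default) disables structure.
#' @param case_pop2_fraction,control_pop2_fraction probability that a case
#'   (control) is drawn from subpopulation 2; unequal values confound
#'   ancestry with status.
#' @param seed integer seed, default 1.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n_cases, n_controls,
                             n_null_variants = 1000L,
                             common_panel = data.frame(
                                 maf = c(0.25, 0.10, 0.25),
                                 or_ = c(6.0, 2.2, 0.44)),
                             rare_panel = data.frame(
                                 maf = c(0.002, 0.0035, 0.006, 0.01,
                                         0.02, 0.035),
                                 or_ = c(9, 8, 6, 5, 3, 2)),
                             subtype_fraction = 0.08,
                             baseline_prevalence = 0.005,
                             structure_fst = 0,
                             case_pop2_fraction = 0.5,
                             control_pop2_fraction = 0.5,
                             seed = 1L) {
    cfg <- new("SimulationConfig",
               n_cases = as.integer(n_cases),
               n_controls = as.integer(n_controls),
               n_null_variants = as.integer(n_null_variants),
               common_panel = as.data.frame(common_panel),
               rare_panel = as.data.frame(rare_panel),
               subtype_fraction = subtype_fraction,
               baseline_prevalence = baseline_prevalence,
               structure_fst = structure_fst,
               case_pop2_fraction = case_pop2_fraction,
               control_pop2_fraction = control_pop2_fraction,
               seed = as.integer(seed))
    validObject(cfg)
    cfg
}

# distribution of the liability sum over a panel: data.frame(value, prob),
# genotypes independent binomial(2, maf) (Hardy-Weinberg)
.liabilityDist <- function(panel) {
    val <- 0
    prob <- 1
    for (i in seq_len(nrow(panel))) {
        p <- panel$maf[i]
        b <- log(panel$or_[i])
        hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
        val <- as.vector(outer(val, b * 0:2, `+`))
        prob <- as.vector(outer(prob, hw, `*`))
        if (length(val) > 4096) {
            # bin the liability grid at 1e-3 resolution; the induced
            # prevalence error (< ~2.5e-4 relative) is negligible next to
            # sampling noise for large panels
            key <- round(val, 3)
            agg <- rowsum(prob, key)
            val <- as.numeric(rownames(agg))
            prob <- as.vector(agg)
        }
    }
    list(value = val, prob = prob)
}

#' Solve the subtype intercept for a target marginal prevalence
#'
#' Finds the logistic intercept a such that
#' E[plogis(a + sum ln(OR_i) G_i)] = \code{prevalence} under independent
#' Hardy-Weinberg genotypes, by bisection to a tolerance of 1e-8 on the
#' marginal prevalence.
#'
#' @param panel data.frame with columns \code{maf}, \code{or_}.
#' @param prevalence target marginal case probability.
#' @return the intercept (numeric scalar).
#' @export
solveIntercept <- function(panel, prevalence) {
    d <- .liabilityDist(panel)
    f <- function(a) sum(d$prob * stats::plogis(a + d$value)) - prevalence
    lo <- -60; hi <- 10
    stopifnot(f(lo) < 0, f(hi) > 0)
    repeat {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (abs(fm) < 1e-8) return(mid)
        if (fm < 0) lo <- mid else hi <- mid
        if (hi - lo < 1e-14) return(mid)
    }
}

#' Expected effect-allele frequency among cases
#'
#' Analytic three-term oracle for a single variant under the logistic
#' disease model: frequency among cases =
#' sum_g (g/2) HW(g) Pr(case|g) / sum_g HW(g) Pr(case|g) over g in 0..2,
#' with Pr(case|g) = plogis(intercept + ln(or_) g).
#'
#' @param maf population allele frequency in (0, 0.5).
#' @param or_ per-allele odds ratio.
#' @param intercept logistic intercept (see \code{\link{solveIntercept}}).
#' @return expected case allele frequency.
#' @export
expectedCaseFrequency <- function(maf, or_, intercept) {
    stopifnot(maf > 0, maf < 0.5)
    g <- 0:2
    hw <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    pc <- stats::plogis(intercept + log(or_) * g)
    sum((g / 2) * hw * pc) / sum(hw * pc)
}

#' Simulate a two-subtype case-control cohort
#'
#' Cases are accumulated by rejection sampling under the per-subtype
#' logistic liability model until the target counts are reached, with the
#' minority subtype filling \code{subtype_fraction} of cases; controls are
#' sampled non-cases from the subtype mixture. Genotypes are drawn
#' per-variant binomial(2, maf) (Hardy-Weinberg), within each subpopulation
#' when structure is enabled (Balding-Nichols allele-frequency divergence).
#' Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{ge} (a
#'   \linkS4class{GenotypeExperiment}), and \code{truth} (list of
#'   \code{variants}: id/causal/panel/true_beta, and \code{samples}:
#'   sample_id/subtype/subpop).
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
    cp <- config@common_panel
    rp <- config@rare_panel
    prev <- config@baseline_prevalence
    a_common <- solveIntercept(cp, prev)
    a_rare <- solveIntercept(rp, prev)

    n_minor <- max(1L, round(config@subtype_fraction * config@n_cases))
    n_major <- config@n_cases - n_minor

    fst <- config@structure_fst
    # per-variant, per-subpopulation allele frequencies
    panelFreqs <- function(maf) {
        if (fst <= 0) return(cbind(maf, maf))
        ab <- maf * (1 - fst) / fst
        bb <- (1 - maf) * (1 - fst) / fst
        f1 <- stats::rbeta(length(maf), ab, bb)
        f2 <- stats::rbeta(length(maf), ab, bb)
        cbind(pmin(pmax(f1, 1e-4), 1 - 1e-4),
              pmin(pmax(f2, 1e-4), 1 - 1e-4))
    }
    cpF <- panelFreqs(cp$maf)
    rpF <- panelFreqs(rp$maf)

    drawPanel <- function(freqs, pop, n) {
        # n individuals x nrow(freqs) variants
        m <- nrow(freqs)
        g <- matrix(stats::rbinom(n * m, 2L,
                                  rep(freqs[cbind(rep(seq_len(m),
                                                      each = n),
                                                  rep(pop, m))], 1)),
                    nrow = n)
        g
    }

    sampleClass <- function(n_target, panel, freqs, intercept, pop2frac,
                            want_case) {
        beta <- log(panel$or_)
        if (n_target == 0L)
            return(list(g = matrix(0, 0, nrow(panel)), pop = integer(0)))
        got_g <- NULL; got_pop <- integer(0)
        draws <- 0L
        p_acc <- if (want_case) prev else 1 - prev
        max_draws <- min(ceiling(50 * n_target / p_acc) + 10000, 2e7)
        while (length(got_pop) < n_target) {
            need <- n_target - length(got_pop)
            B <- min(max(2000L, ceiling(1.4 * need / p_acc)), 500000L)
            pop <- 1L + stats::rbinom(B, 1L, pop2frac)
            g <- drawPanel(freqs, pop, B)
            eta <- intercept + as.vector(g %*% beta)
            pcase <- stats::plogis(eta)
            u <- stats::runif(B)
            acc <- if (want_case) u < pcase else u >= pcase
            draws <- draws + B
            if (any(acc)) {
                got_g <- rbind(got_g, g[acc, , drop = FALSE])
                got_pop <- c(got_pop, pop[acc])
            }
            if (draws > max_draws)
                stop("rejection sampling budget exhausted; the requested ",
                     "subtype mix is unattainable at this prevalence",
                     call. = FALSE)
        }
        list(g = got_g[seq_len(n_target), , drop = FALSE],
             pop = got_pop[seq_len(n_target)])
    }

    maj <- sampleClass(n_major, cp, cpF, a_common,
                       config@case_pop2_fraction, TRUE)
    mino <- sampleClass(n_minor, rp, rpF, a_rare,
                        config@case_pop2_fraction, TRUE)

    # controls: non-cases from the subtype mixture
    nctrl <- config@n_controls
    cls <- stats::rbinom(nctrl, 1L, config@subtype_fraction)  # 1 = minority
    n_ctrl_min <- sum(cls == 1L)
    ctl_maj <- sampleClass(nctrl - n_ctrl_min, cp, cpF, a_common,
                           config@control_pop2_fraction, FALSE)
    ctl_min <- sampleClass(n_ctrl_min, rp, rpF, a_rare,
                           config@control_pop2_fraction, FALSE)

    subtype <- c(rep("major", n_major), rep("minor", n_minor),
                 rep("major", nctrl - n_ctrl_min), rep("minor", n_ctrl_min))
    phenotype <- c(rep("case", config@n_cases),
                   rep("control", nctrl))
    pop <- c(maj$pop, mino$pop, ctl_maj$pop, ctl_min$pop)
    n_all <- length(pop)

    # fill the panel genotypes that did not drive the individual's liability
    fillPanel <- function(freqs, pop, n) drawPanel(freqs, pop, n)
    g_common <- matrix(NA_real_, n_all, nrow(cp))
    g_rare <- matrix(NA_real_, n_all, nrow(rp))
    is_maj <- subtype == "major"
    g_common[is_maj, ] <- rbind(maj$g, ctl_maj$g)
    g_rare[is_maj, ] <- fillPanel(rpF, pop[is_maj], sum(is_maj))
    g_common[!is_maj, ] <- fillPanel(cpF, pop[!is_maj], sum(!is_maj))
    g_rare[!is_maj, ] <- rbind(mino$g, ctl_min$g)

    m_null <- config@n_null_variants
    null_maf <- stats::runif(m_null, 0.05, 0.5)
    nullF <- panelFreqs(null_maf)
    g_null <- drawPanel(nullF, pop, n_all)

    G <- cbind(g_common, g_rare, g_null)  # samples x variants
    m_all <- ncol(G)
    base_maf <- c(cp$maf, rp$maf, null_maf)
    panel_lab <- c(rep("common", nrow(cp)), rep("rare", nrow(rp)),
                   rep("none", m_null))
    true_beta <- c(log(cp$or_), log(rp$or_), rep(0, m_null))

    # lay variants out over 22 autosomes in contiguous blocks, 200 kb apart
    per_chr <- ceiling(m_all / 22)
    chrom <- as.character(rep(seq_len(22), each = per_chr)[seq_len(m_all)])
    idx_in_chr <- sequence(rle(chrom)$lengths)
    pos <- 1000000L + (idx_in_chr - 1L) * 200000L
    ids <- sprintf("sim%05d", seq_len(m_all))

    variants <- data.frame(
        chrom = chrom, pos = pos, id = ids,
        effect_allele = "A", other_allele = "G",
        maf = base_maf,
        quality_r2 = ifelse(panel_lab == "rare", 0.95, 1.0),
        genotyped = ifelse(panel_lab == "rare", "Imputed", "Genotyped"),
        stringsAsFactors = FALSE)

    sex <- sample(c("male", "female", "unknown"), n_all, replace = TRUE,
                  prob = c(0.495, 0.5, 0.005))
    samples <- data.frame(
        sample_id = sprintf("S%06d", seq_len(n_all)),
        sex = sex, phenotype = phenotype, cohort = "unassigned",
        stringsAsFactors = FALSE)

    ge <- GenotypeExperiment(t(G), variants, samples,
                             genome_build = "simulated")
    truth <- list(
        variants = data.frame(id = ids, causal = panel_lab != "none",
                              panel = panel_lab, true_beta = true_beta,
                              stringsAsFactors = FALSE),
        samples = data.frame(sample_id = samples$sample_id,
                             subtype = subtype, subpop = pop,
                             stringsAsFactors = FALSE),
        intercepts = c(common = a_common, rare = a_rare))
    list(ge = ge, truth = truth)
}
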