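#' @useDynLib PRSstrat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' LD-prune variants in a sliding window
#'
#' PLINK-style pruning on dosage correlation: windows of
#' \code{window} consecutive variants (ordered by chromosome and position),
#' shifted by \code{step}; within a window, when a pair has squared dosage
#' correlation above \code{r2}, the later variant is removed.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param window window size in variant count, default 50.
#' @param step shift in variants, default 5.
#' @param r2 removal threshold on squared correlation, default 0.2.
#' @return character vector of retained variant ids.
#' @export
ldPrune <- function(ge, window = 50L, step = 5L, r2 = 0.2) {
    v <- variantInfo(ge)
    d <- dosages(ge)
    keep <- rep(TRUE, nrow(v))
    ord <- order(.chromNum(v$chrom), v$pos)
    for (chr in unique(v$chrom)) {
        idx <- ord[v$chrom[ord] == chr]
        if (length(idx) < 2) next
        start <- 1L
        repeat {
            win <- idx[seq(start, min(start + window - 1L, length(idx)))]
            win <- win[keep[win]]
            if (length(win) >= 2) {
                cc <- suppressWarnings(
                    stats::cor(t(d[win, , drop = FALSE]),
                               use = "pairwise.complete.obs"))
                cc[is.na(cc)] <- 0
                for (a in seq_along(win)) {
                    if (!keep[win[a]]) next
                    hit <- which(cc[a, ]^2 > r2)
                    hit <- hit[hit > a & keep[win[hit]]]
                    keep[win[hit]] <- FALSE
                }
            }
            if (start + window - 1L >= length(idx)) break
            start <- start + step
        }
    }
    v$id[keep]
}

.chromNum <- function(chrom) {
    x <- sub("^chr", "", as.character(chrom))
    n <- suppressWarnings(as.numeric(x))
    n[is.na(n)] <- 1000 + as.numeric(factor(x[is.na(n)]))
    n
}

#' Principal components of standardized genotypes
#'
#' Computes the top \code{k} sample principal components of the standardized
#' dosage matrix (mean-centered, scaled by sqrt(2 p (1-p)) with p the
#' observed allele frequency). Missing dosages are mean-imputed before
#' standardization; constant variants are skipped. Input variants are
#' restricted to \code{maf >= maf_min} and LD-pruned (see
#' \code{\link{ldPrune}}). Sign convention: the largest-magnitude variant
#' loading of each PC is positive.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param k number of PCs (default 10).
#' @param maf_min minimum minor allele frequency, default 0.05.
#' @param prune_window,prune_step,prune_r2 pruning parameters (defaults
#'   50 / 5 / 0.2).
#' @return data.frame with sample_id and PC1..PCk columns.
#' @export
computePCs <- function(ge, k = 10L, maf_min = 0.05,
                       prune_window = 50L, prune_step = 5L,
                       prune_r2 = 0.2) {
    v <- variantInfo(ge)
    sub <- ge[v$maf >= maf_min, ]
    kept <- ldPrune(sub, prune_window, prune_step, prune_r2)
    sub <- sub[kept, ]
    X <- t(dosages(sub))                     # samples x variants
    for (j in seq_len(ncol(X))) {
        nas <- is.na(X[, j])
        if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
    p <- colMeans(X) / 2
    sdv <- sqrt(2 * p * (1 - p))
    ok <- sdv > 0 & apply(X, 2, stats::sd) > 0
    X <- sweep(X[, ok, drop = FALSE], 2, 2 * p[ok], "-")
    X <- sweep(X, 2, sdv[ok], "/")
    n <- nrow(X); m <- ncol(X)
    if (k > min(n - 1, m))
        stop("k = ", k, " exceeds the rank of the standardized genotype ",
             "matrix", call. = FALSE)
    if (m <= n) {
        ee <- eigen(crossprod(X), symmetric = TRUE)
        lam <- ee$values[seq_len(k)]
        V <- ee$vectors[, seq_len(k), drop = FALSE]   # variant loadings
        U <- X %*% V
        U <- sweep(U, 2, sqrt(pmax(lam, 1e-12)), "/")
    } else {
        ee <- eigen(tcrossprod(X), symmetric = TRUE)
        lam <- ee$values[seq_len(k)]
        U <- ee$vectors[, seq_len(k), drop = FALSE]
        V <- crossprod(X, U)
        V <- sweep(V, 2, sqrt(pmax(lam, 1e-12)), "/")
    }
    if (any(lam <= 1e-8))
        stop("k = ", k, " exceeds the rank of the standardized genotype ",
             "matrix", call. = FALSE)
    for (j in seq_len(k)) {           # sign: top-|loading| entry positive
        top <- which.max(abs(V[, j]))
        if (V[top, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
    }
    out <- data.frame(sample_id = sampleInfo(sub)$sample_id, U,
                      stringsAsFactors = FALSE)
    colnames(out)[-1] <- paste0("PC", seq_len(k))
    out
}

#' Build the covariate matrix used by the association scan
#'
#' Sex is coded 0 (female) / 1 (male); unknown sex is mean-imputed so
#' sex-undetermined samples stay in the analysis. PC columns are joined by
#' sample id.
#'
#' @param samples sample data.frame with sample_id and sex.
#' @param pcs data.frame from \code{\link{computePCs}}, or NULL.
#' @return numeric matrix with rownames = sample ids.
#' @export
makeCovariates <- function(samples, pcs = NULL) {
    sex <- ifelse(samples$sex == "male", 1,
                  ifelse(samples$sex == "female", 0, NA))
    sex[is.na(sex)] <- mean(sex, na.rm = TRUE)
    out <- cbind(sex = sex)
    if (!is.null(pcs)) {
        idx <- match(samples$sample_id, pcs$sample_id)
        if (anyNA(idx))
            stop("PC table lacks some samples", call. = FALSE)
        out <- cbind(out, as.matrix(pcs[idx, -1, drop = FALSE]))
    }
    rownames(out) <- samples$sample_id
    out
}

#' Per-variant logistic association scan
#'
#' Fits an additive-dosage logistic regression
#' logit Pr(case) = b0 + b G + gamma' covariates for every variant, by IRLS
#' (tolerance 1e-8, up to 25 iterations), and reports the Wald test of the
#' dosage coefficient: beta, its standard error from the observed
#' information, OR = exp(beta), the 95 percent CI exp(beta -/+ 1.96 se) and
#' a two-sided normal P. On detected separation (a fitted probability
#' within 1e-8 of 0 or 1) or non-convergence the variant is refit with a
#' Firth penalty and flagged \code{test = "firth"}; rare variants in
#' moderate samples make quasi-separation common. Missing dosages are
#' mean-imputed per variant; constant variants are skipped with
#' \code{test = "skipped_constant"} and NA statistics.
#'
#' @param ge a \linkS4class{GenotypeExperiment} whose samples carry
#'   case/control phenotypes.
#' @param covariates numeric matrix from \code{\link{makeCovariates}}
#'   (rows aligned to samples), or NULL for no covariates.
#' @return association data.frame with one row per variant: chrom, id, pos,
#'   effect_allele, other_allele, maf, quality_r2, genotyped, n, beta, se,
#'   or_, l95, u95, p, test.
#' @export
runAssoc <- function(ge, covariates = NULL) {
    s <- sampleInfo(ge)
    y <- as.numeric(s$phenotype == "case")
    if (length(unique(y[!is.na(y)])) < 2)
        stop("need at least one case and one control", call. = FALSE)
    G <- t(dosages(ge))                      # samples x variants
    for (j in seq_len(ncol(G))) {
        nas <- is.na(G[, j])
        if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
    }
    C <- cbind(intercept = rep(1, nrow(G)))
    if (!is.null(covariates)) C <- cbind(C, covariates)
    const <- apply(G, 2, function(x) stats::sd(x) == 0 || anyNA(x))
    fit <- matrix(NA_real_, ncol(G), 4)
    if (any(!const))
        fit[!const, ] <- cpp_logistic_scan(C, G[, !const, drop = FALSE],
                                           y, 1e-8, 25L, 100L)
    v <- variantInfo(ge)
    beta <- fit[, 1]; se <- fit[, 2]
    test <- ifelse(const, "skipped_constant",
                   ifelse(is.na(fit[, 3]), "failed",
                          ifelse(fit[, 3] == 1, "firth",
                                 ifelse(fit[, 3] == 2, "failed", "wald"))))
    beta[test %in% c("failed", "skipped_constant")] <- NA
    se[test %in% c("failed", "skipped_constant")] <- NA
    z <- beta / se
    data.frame(
        chrom = v$chrom, id = v$id, pos = v$pos,
        effect_allele = v$effect_allele, other_allele = v$other_allele,
        maf = v$maf, quality_r2 = v$quality_r2, genotyped = v$genotyped,
        n = length(y),
        beta = beta, se = se,
        or_ = exp(beta),
        l95 = exp(beta - 1.96 * se), u95 = exp(beta + 1.96 * se),
        p = 2 * stats::pnorm(-abs(z)),
        test = test, stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-variant logistic association
#'
#' Convenience wrapper around the scan engine for one dosage vector.
#'
#' @param g numeric dosage vector in [0, 2].
#' @param y 0/1 or case/control phenotype vector.
#' @param covariates optional numeric covariate matrix.
#' @return one-row data.frame with beta, se, or_, l95, u95, p, test, n.
#' @export
logisticAssoc <- function(g, y, covariates = NULL) {
    if (is.character(y) || is.factor(y))
        y <- as.numeric(as.character(y) == "case")
    y <- as.numeric(y)
    if (length(unique(y)) < 2)
        stop("need at least one case and one control", call. = FALSE)
    if (stats::sd(g, na.rm = TRUE) == 0)
        stop("constant variant", call. = FALSE)
    nas <- is.na(g)
    if (any(nas)) g[nas] <- mean(g, na.rm = TRUE)
    C <- cbind(intercept = rep(1, length(y)))
    if (!is.null(covariates)) C <- cbind(C, covariates)
    fit <- cpp_logistic_scan(C, matrix(g, ncol = 1), y, 1e-8, 25L, 100L)
    beta <- fit[1, 1]; se <- fit[1, 2]
    data.frame(beta = beta, se = se, or_ = exp(beta),
               l95 = exp(beta - 1.96 * se), u95 = exp(beta + 1.96 * se),
               p = 2 * stats::pnorm(-abs(beta / se)),
               test = if (fit[1, 3] == 1) "firth" else "wald",
               n = length(y), stringsAsFactors = FALSE)
}

#' Genome-wide significant hits
#'
#' Retains records with \code{p <= alpha} (inclusive, default the
#' genome-wide 5.0e-8), sorted by chromosome and position.
#'
#' @param results association data.frame.
#' @param alpha significance cutoff in (0, 1).
#' @return the filtered, sorted data.frame.
#' @export
genomeWideHits <- function(results, alpha = 5e-8) {
    stopifnot(alpha > 0, alpha <= 1)
    keep <- !is.na(results$p) & results$p <= alpha
    out <- results[keep, , drop = FALSE]
    out[order(.chromNum(out$chrom), out$pos), , drop = FALSE]
}

#' Odds-ratio heterogeneity z-test between two analyses
#'
#' Tests whether the same variant's log odds ratio differs between two
#' association analyses (e.g. low-PRS stratum versus overall):
#' z = (beta2 - beta1) / sqrt(se1^2 + se2^2), two-sided normal P.
#' When a standard error is absent it is recovered from the 95 percent CI
#' as ln(U95/L95) / (2 * 1.96). The two records must agree on variant id
#' and effect allele; mismatched effect alleles are an error (no silent
#' flipping).
#'
#' @param r1,r2 one-row association records (data.frame or list) with at
#'   least \code{id}, \code{effect_allele}, and either \code{beta}/\code{se}
#'   or \code{or_}/\code{l95}/\code{u95}.
#' @return one-row data.frame: id, beta1, se1, beta2, se2, z, p_het.
#' @export
orHeterogeneity <- function(r1, r2) {
    if (!is.null(r1$id) && !is.null(r2$id) && !identical(
        as.character(r1$id), as.character(r2$id)))
        stop("heterogeneity test requires the same variant", call. = FALSE)
    if (!is.null(r1$effect_allele) && !is.null(r2$effect_allele) &&
        !identical(as.character(r1$effect_allele),
                   as.character(r2$effect_allele)))
        stop("mismatched effect alleles; flip explicitly before testing",
             call. = FALSE)
    grab <- function(r) {
        b <- r$beta; s <- r$se
        if (is.null(b) || is.na(b)) b <- log(r$or_)
        if (is.null(s) || is.na(s)) s <- log(r$u95 / r$l95) / (2 * 1.96)
        c(b, s)
    }
    b1 <- grab(r1); b2 <- grab(r2)
    z <- (b2[1] - b1[1]) / sqrt(b1[2]^2 + b2[2]^2)
    data.frame(id = if (is.null(r1$id)) NA_character_ else
                   as.character(r1$id),
               beta1 = b1[1], se1 = b1[2], beta2 = b2[1], se2 = b2[2],
               z = z, p_het = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' lambda = median of the chi-square(1) deviates implied by the P-values,
#' divided by the chi-square(1) median (0.4549...).
#'
#' @param p vector of P-values (or an association data.frame with a
#'   \code{p} column); at least 100 values.
#' @return lambda (numeric scalar).
#' @export
genomicInflation <- function(p) {
    if (is.data.frame(p)) p <- p$p
    p <- p[!is.na(p)]
    if (length(p) < 100)
        stop("need at least 100 P-values for a stable lambda",
             call. = FALSE)
    chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
    stats::median(chi) / stats::qchisq(0.5, df = 1)
}
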