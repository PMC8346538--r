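#' The SNP-inclusion P-value threshold grid
#'
#' Fourteen cutoffs from 1e-10 to 1 (including 0.5), the grid over which
#' \code{\link{selectPThreshold}} picks the best-AUC model.
#'
#' @return numeric vector of length 14.
#' @export
defaultPGrid <- function() {
    c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4,
      0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed variant with smallest training P as an
#' index variant and removes every unclaimed variant within
#' \code{window_kb} on the same chromosome whose squared dosage correlation
#' with it (computed on \code{ge_ref}) exceeds \code{r2_threshold}.
#' Deterministic, with P then position as the tie-break. Variants absent
#' from the reference genotypes are excluded (a warning reports the count).
#'
#' @param train_results association data.frame of the training GWAS.
#' @param ge_ref \linkS4class{GenotypeExperiment} used as LD reference
#'   (conventionally the training cohort itself).
#' @param r2_threshold squared-correlation threshold, default 0.1.
#' @param window_kb window in kb, default 250.
#' @return character vector of retained (index) variant ids.
#' @export
clumpVariants <- function(train_results, ge_ref, r2_threshold = 0.1,
                          window_kb = 250) {
    res <- train_results[!is.na(train_results$p), , drop = FALSE]
    ref_ids <- variantInfo(ge_ref)$id
    absent <- !(res$id %in% ref_ids)
    if (any(absent)) {
        warning(sum(absent), " variant(s) absent from the LD reference ",
                "were excluded from clumping", call. = FALSE)
        res <- res[!absent, , drop = FALSE]
    }
    res <- res[order(res$p, .chromNum(res$chrom), res$pos), , drop = FALSE]
    d <- dosages(ge_ref)
    claimed <- rep(FALSE, nrow(res))
    keep <- character(0)
    win <- window_kb * 1000
    for (i in seq_len(nrow(res))) {
        if (claimed[i]) next
        claimed[i] <- TRUE
        keep <- c(keep, res$id[i])
        near <- which(!claimed & res$chrom == res$chrom[i] &
                      abs(res$pos - res$pos[i]) <= win)
        if (!length(near)) next
        gi <- d[res$id[i], ]
        r <- suppressWarnings(stats::cor(
            gi, t(d[res$id[near], , drop = FALSE]),
            use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0
        claimed[near[r[1, ]^2 > r2_threshold]] <- TRUE
    }
    keep
}

#' Build a PRS model at a P-threshold
#'
#' Entries are the clumped variants whose training P is at or below the
#' threshold, with beta = ln(OR) from the training GWAS.
#'
#' @param train_results training association data.frame.
#' @param clumped_ids ids surviving \code{\link{clumpVariants}}.
#' @param p_threshold inclusion cutoff.
#' @param clump_r2,clump_window_kb recorded clumping parameters.
#' @return a \linkS4class{PRSModel}.
#' @export
buildPrsModel <- function(train_results, clumped_ids, p_threshold,
                          clump_r2 = 0.1, clump_window_kb = 250) {
    sub <- train_results[train_results$id %in% clumped_ids &
                         !is.na(train_results$p) &
                         train_results$p <= p_threshold, , drop = FALSE]
    if (!nrow(sub))
        stop("no variant passes the P threshold ", format(p_threshold),
             call. = FALSE)
    entries <- data.frame(id = sub$id,
                          effect_allele = sub$effect_allele,
                          beta = sub$beta,
                          train_p = sub$p, stringsAsFactors = FALSE)
    new("PRSModel", entries = entries, p_threshold = p_threshold,
        clump_r2 = clump_r2, clump_window_kb = clump_window_kb)
}

#' Score samples with a PRS model
#'
#' Average per non-missing allele: S_j = sum_i beta_i G_ij / (2 M_j), where
#' M_j counts the model variants with a non-missing dosage for sample j.
#' When a model entry's effect allele is the container's other allele the
#' dosage is flipped to 2 - G. Model variants absent from the genotypes are
#' excluded from numerator and denominator and counted in the
#' \code{n_absent} attribute.
#'
#' @param model a \linkS4class{PRSModel}.
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @return data.frame (sample_id, prs, m_used), with attribute
#'   \code{n_absent}.
#' @export
scorePrs <- function(model, ge) {
    e <- model@entries
    if (!nrow(e)) stop("empty PRS model", call. = FALSE)
    v <- variantInfo(ge)
    idx <- match(e$id, v$id)
    absent <- is.na(idx)
    if (all(absent))
        stop("no model variant present in the genotypes", call. = FALSE)
    e <- e[!absent, , drop = FALSE]
    idx <- idx[!absent]
    d <- dosages(ge)[idx, , drop = FALSE]
    flip <- e$effect_allele == v$other_allele[idx]
    match_ok <- flip | e$effect_allele == v$effect_allele[idx]
    if (!all(match_ok))
        stop("model effect allele matches neither allele for variant(s) ",
             paste(utils::head(e$id[!match_ok], 3), collapse = ", "),
             call. = FALSE)
    d[flip, ] <- 2 - d[flip, , drop = FALSE]
    miss <- is.na(d)
    d[miss] <- 0
    num <- as.vector(crossprod(d, e$beta))
    m_used <- nrow(d) - colSums(miss)
    if (any(m_used == 0))
        stop("sample(s) with no scored variant", call. = FALSE)
    out <- data.frame(sample_id = sampleInfo(ge)$sample_id,
                      prs = num / (2 * m_used), m_used = m_used,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "n_absent") <- sum(absent)
    out
}

#' Select the SNP-inclusion P threshold by test-cohort AUC
#'
#' Clumps the training GWAS once, then for each grid threshold builds the
#' model, scores the test cohort and computes the AUC of the scores against
#' the test phenotypes. Returns the threshold with the largest AUC (ties
#' resolved toward the smaller threshold) plus the full grid table. A
#' threshold yielding an empty model is recorded with NA AUC, not an abort.
#'
#' @param train_results training association data.frame.
#' @param ge_ref LD-reference genotypes for clumping (training cohort).
#' @param ge_test test-cohort genotypes with phenotypes attached.
#' @param grid thresholds, default \code{\link{defaultPGrid}()}.
#' @param clump_r2,clump_window_kb clumping parameters.
#' @return list: \code{best_threshold}, \code{grid} (data.frame threshold,
#'   n_snps, auc), \code{clumped_ids}.
#' @export
selectPThreshold <- function(train_results, ge_ref, ge_test,
                             grid = defaultPGrid(),
                             clump_r2 = 0.1, clump_window_kb = 250) {
    stopifnot(length(grid) >= 1)
    clumped <- clumpVariants(train_results, ge_ref, clump_r2,
                             clump_window_kb)
    labels <- sampleInfo(ge_test)$phenotype
    grid <- sort(grid)
    auc <- n_snps <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
        model <- tryCatch(
            buildPrsModel(train_results, clumped, grid[i],
                          clump_r2, clump_window_kb),
            error = function(e) NULL)
        if (is.null(model)) next
        sc <- scorePrs(model, ge_test)
        n_snps[i] <- nrow(model@entries)
        auc[i] <- aucScore(sc$prs, labels)
    }
    if (all(is.na(auc)))
        stop("every grid threshold yielded an empty model", call. = FALSE)
    best <- grid[which.max(auc)]   # ties -> first, i.e. smaller threshold
    list(best_threshold = best,
         grid = data.frame(threshold = grid, n_snps = n_snps, auc = auc),
         clumped_ids = clumped)
}
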