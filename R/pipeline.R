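#' Pipeline configuration
#'
#' Collects every tunable of the stratified-GWAS flow with its default:
#' TOPMed-style variant quality filter (R2 >= 0.3), 10 PCs on MAF >= 0.05
#' LD-pruned variants, PRSice-style clumping (r2 0.1, 250 kb), the 14-value
#' threshold grid, genome-wide alpha 5e-8 (inclusive), 500 kb locus merging
#' and 300 kb novelty flanks.
#'
#' @param min_quality_r2 variant quality filter, default 0.3.
#' @param maf_range inclusive MAF bounds, default c(0, 0.5).
#' @param n_pcs principal components used as covariates, default 10.
#' @param pc_maf_min,prune_window,prune_step,prune_r2 PCA variant
#'   selection/pruning, defaults 0.05 / 50 / 5 / 0.2.
#' @param clump_r2,clump_window_kb clumping, defaults 0.1 / 250.
#' @param grid P-threshold grid, default \code{\link{defaultPGrid}()}.
#' @param alpha genome-wide significance, default 5e-8.
#' @param loci_merge_kb,loci_flank_kb locus calling, defaults 500 / 300.
#' @param recompute_pcs_low recompute PCs on the low-PRS subset (default
#'   TRUE) instead of reusing the test-cohort PCs.
#' @param split_seed seed for \code{\link{splitCohorts}} when the input is
#'   unassigned.
#' @return a named list of settings.
#' @export
pipelineConfig <- function(min_quality_r2 = 0.3, maf_range = c(0, 0.5),
                           n_pcs = 10L, pc_maf_min = 0.05,
                           prune_window = 50L, prune_step = 5L,
                           prune_r2 = 0.2,
                           clump_r2 = 0.1, clump_window_kb = 250,
                           grid = defaultPGrid(), alpha = 5e-8,
                           loci_merge_kb = 500, loci_flank_kb = 300,
                           recompute_pcs_low = TRUE, split_seed = 1L) {
    as.list(environment())
}

.cohortSubset <- function(ge, cohort) {
    keep <- sampleInfo(ge)$cohort == cohort
    if (!any(keep)) stop("no samples in cohort ", cohort, call. = FALSE)
    ge[, keep]
}

.pcsOrNull <- function(ge, config) {
    n_pcs <- config$n_pcs
    if (n_pcs < 1) return(NULL)
    computePCs(ge, k = n_pcs, maf_min = config$pc_maf_min,
               prune_window = config$prune_window,
               prune_step = config$prune_step, prune_r2 = config$prune_r2)
}

#' Run one train/test direction of the stratified-GWAS flow
#'
#' Executes, on quality-filtered variants: (1) a sex + PC adjusted GWAS on
#' the training cohort; (2) clumping, the P-threshold grid and AUC-based
#' selection on the test cohort; (3) the MCC-optimal PRS cutoff on the
#' test-cohort scores; (4) stratification (low <=> PRS <= cutoff);
#' (5) a GWAS of low-PRS cases versus low-PRS controls; (6) a GWAS of all
#' test-cohort cases versus all test-cohort controls; (7) an odds-ratio
#' heterogeneity test at every variant genome-wide significant in at least
#' one of the two analyses; (8) locus calling on the low-stratum hits.
#'
#' @param ge a \linkS4class{GenotypeExperiment} with phenotypes and cohort
#'   labels (run \code{\link{splitCohorts}} first if unassigned).
#' @param train_cohort,test_cohort cohort labels, e.g. "A" and "B".
#' @param config list from \code{\link{pipelineConfig}}.
#' @param known_loci optional \code{GRanges} of known loci for novelty
#'   calling.
#' @return a \linkS4class{StratifiedResult}.
#' @export
runDirection <- function(ge, train_cohort = "A", test_cohort = "B",
                         config = pipelineConfig(), known_loci = NULL) {
    ge <- filterVariants(ge, config$min_quality_r2, config$maf_range)
    train <- .cohortSubset(ge, train_cohort)
    test <- .cohortSubset(ge, test_cohort)

    # (1) training GWAS
    pcs_tr <- .pcsOrNull(train, config)
    cov_tr <- makeCovariates(sampleInfo(train), pcs_tr)
    train_res <- runAssoc(train, cov_tr)

    # (2) threshold grid, AUC selection on the test cohort
    sel <- selectPThreshold(train_res, train, test, grid = config$grid,
                            clump_r2 = config$clump_r2,
                            clump_window_kb = config$clump_window_kb)
    model <- buildPrsModel(train_res, sel$clumped_ids, sel$best_threshold,
                           config$clump_r2, config$clump_window_kb)
    sc <- scorePrs(model, test)
    labels <- sampleInfo(test)$phenotype

    # (3) MCC-optimal cutoff, (4) stratification
    rep_ <- bestMccCutoff(sc$prs, labels)
    strat <- stratifyByScore(sc$prs, labels, rep_@cutoff,
                             sample_ids = sc$sample_id)
    low_ids <- strat$low
    low <- test[, sampleInfo(test)$sample_id %in% low_ids]
    s_low <- sampleInfo(low)
    if (!any(s_low$phenotype == "case") || !any(s_low$phenotype == "control"))
        stop("empty low-PRS case or control stratum at cutoff ",
             format(rep_@cutoff), call. = FALSE)
    stratum <- list(
        low_cases = s_low$sample_id[s_low$phenotype == "case"],
        low_controls = s_low$sample_id[s_low$phenotype == "control"],
        pct_low_cases = strat$pct_low_cases,
        pct_low_controls = strat$pct_low_controls,
        confusion = strat$confusion)

    # (5) low-PRS stratum GWAS
    pcs_low <- if (config$recompute_pcs_low) .pcsOrNull(low, config) else {
        pcs_te <- .pcsOrNull(test, config)
        pcs_te[pcs_te$sample_id %in% s_low$sample_id, , drop = FALSE]
    }
    cov_low <- makeCovariates(s_low, pcs_low)
    low_res <- runAssoc(low, cov_low)

    # (6) overall GWAS on the test cohort
    pcs_te <- .pcsOrNull(test, config)
    cov_te <- makeCovariates(sampleInfo(test), pcs_te)
    overall_res <- runAssoc(test, cov_te)

    # (7) heterogeneity at lead variants significant in either analysis
    sig <- union(genomeWideHits(low_res, config$alpha)$id,
                 genomeWideHits(overall_res, config$alpha)$id)
    het <- do.call(rbind, lapply(sig, function(vid) {
        r1 <- low_res[low_res$id == vid, ]
        r2 <- overall_res[overall_res$id == vid, ]
        if (nrow(r1) != 1 || nrow(r2) != 1 ||
            is.na(r1$beta) || is.na(r2$beta)) return(NULL)
        cbind(orHeterogeneity(r1, r2),
              p_low = r1$p, p_overall = r2$p)
    }))
    if (is.null(het))
        het <- data.frame(id = character(0), beta1 = numeric(0),
                          se1 = numeric(0), beta2 = numeric(0),
                          se2 = numeric(0), z = numeric(0),
                          p_het = numeric(0), p_low = numeric(0),
                          p_overall = numeric(0))

    # (8) loci from the low-stratum hits
    loci <- callLoci(genomeWideHits(low_res, config$alpha),
                     merge_kb = config$loci_merge_kb,
                     known_loci = known_loci,
                     flank_kb = config$loci_flank_kb)

    scores <- stats::setNames(sc$prs, sc$sample_id)
    new("StratifiedResult",
        direction = paste0(train_cohort, "->", test_cohort),
        p_threshold = sel$best_threshold,
        auc_grid = sel$grid,
        cutoff_report = rep_,
        scores = scores,
        low_assoc = low_res, overall_assoc = overall_res,
        het = het, loci = loci, strata = stratum)
}

#' Run both directions of the cohort switch
#'
#' Trains on A / tests on B, then switches the two cohorts and repeats,
#' mirroring the replication-by-switch design.
#'
#' @inheritParams runDirection
#' @return list with elements \code{AtoB} and \code{BtoA}
#'   (\linkS4class{StratifiedResult}), and \code{auc_grids}, the two AUC
#'   tables side by side.
#' @export
runSwitched <- function(ge, config = pipelineConfig(), known_loci = NULL) {
    ab <- runDirection(ge, "A", "B", config, known_loci)
    ba <- runDirection(ge, "B", "A", config, known_loci)
    grids <- merge(ab@auc_grid, ba@auc_grid, by = "threshold",
                   suffixes = c("_AtoB", "_BtoA"))
    list(AtoB = ab, BtoA = ba, auc_grids = grids)
}

#' Merge genome-wide hits into loci and classify them
#'
#' Single-linkage merge of hits within \code{merge_kb} on a chromosome; the
#' lead variant is the smallest P (ties to the smaller position). A locus
#' is \code{known} iff its lead lies within \code{flank_kb} of any
#' known-locus interval, else \code{novel}; quality class is \code{high}
#' iff the lead's imputation quality exceeds 0.9 (strict), and the rare
#' flag marks lead MAF < 0.05 (strict).
#'
#' @param hits association data.frame of genome-wide-significant records
#'   (see \code{\link{genomeWideHits}}); empty input gives an empty call
#'   set.
#' @param merge_kb single-linkage merge distance, default 500.
#' @param known_loci \code{GRanges} of known loci, or NULL (everything
#'   novel).
#' @param flank_kb novelty flank, default 300.
#' @return data.frame: chrom, start, end, n_hits, lead_id, lead_pos,
#'   lead_p, lead_maf, lead_quality_r2, quality_class, rare_flag, novelty.
#' @export
callLoci <- function(hits, merge_kb = 500, known_loci = NULL,
                     flank_kb = 300) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), n_hits = integer(0),
                        lead_id = character(0), lead_pos = integer(0),
                        lead_p = numeric(0), lead_maf = numeric(0),
                        lead_quality_r2 = numeric(0),
                        quality_class = character(0),
                        rare_flag = logical(0), novelty = character(0))
    if (is.null(hits) || !nrow(hits)) return(empty)
    if (!is.null(known_loci)) {
        if (!is(known_loci, "GRanges"))
            stop("known_loci must be a GRanges (see readKnownLoci)",
                 call. = FALSE)
        if (any(GenomicRanges::width(known_loci) < 1))
            stop("malformed known-locus interval", call. = FALSE)
    }
    hits <- hits[order(.chromNum(hits$chrom), hits$pos), , drop = FALSE]
    gap <- merge_kb * 1000
    grp <- integer(nrow(hits)); g <- 0L
    for (i in seq_len(nrow(hits))) {
        if (i == 1 || hits$chrom[i] != hits$chrom[i - 1] ||
            hits$pos[i] - hits$pos[i - 1] > gap) g <- g + 1L
        grp[i] <- g
    }
    out <- do.call(rbind, lapply(split(hits, grp), function(h) {
        lead <- h[order(h$p, h$pos), ][1, ]
        data.frame(chrom = lead$chrom, start = min(h$pos),
                   end = max(h$pos), n_hits = nrow(h),
                   lead_id = lead$id, lead_pos = lead$pos,
                   lead_p = lead$p, lead_maf = lead$maf,
                   lead_quality_r2 = lead$quality_r2,
                   quality_class = if (lead$quality_r2 > 0.9) "high"
                                   else "low",
                   rare_flag = lead$maf < 0.05,
                   novelty = .novelty(lead, known_loci, flank_kb),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.novelty <- function(lead, known_loci, flank_kb) {
    if (is.null(known_loci) || !length(known_loci)) return("novel")
    pt <- GenomicRanges::GRanges(
        lead$chrom, IRanges::IRanges(lead$pos, lead$pos))
    dists <- suppressWarnings(
        GenomicRanges::distanceToNearest(pt, known_loci,
                                         ignore.strand = TRUE))
    if (!length(dists)) return("novel")  # lead chromosome absent from BED
    d <- S4Vectors::mcols(dists)$distance
    if (d <= flank_kb * 1000) "known" else "novel"
}

#' Plot-ready Manhattan table
#'
#' Emits (chrom, pos, -log10 P) sorted by chromosome and position; no
#' graphics are rendered.
#'
#' @param results association data.frame.
#' @param path optional TSV output path.
#' @return the table, invisibly when written.
#' @export
manhattanTable <- function(results, path = NULL) {
    out <- data.frame(chrom = results$chrom, pos = results$pos,
                      neglog10p = -log10(results$p),
                      stringsAsFactors = FALSE)
    out <- out[order(.chromNum(out$chrom), out$pos), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(path)) {
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(out))
    }
    out
}
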