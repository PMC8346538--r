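#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Container for sample-by-variant dosage genotypes
#'
#' \code{GenotypeExperiment} extends \linkS4class{SummarizedExperiment}: the
#' single assay \code{"dosage"} holds effect-allele dosages in \code{[0, 2]}
#' (NA = missing) with variants as rows and samples as columns.
#' \code{rowData} carries the variant annotation (\code{chrom}, \code{pos},
#' \code{id}, \code{effect_allele}, \code{other_allele}, \code{maf},
#' \code{quality_r2}, \code{genotyped}) and \code{colData} the sample
#' annotation (\code{sample_id}, \code{sex}, \code{phenotype},
#' \code{cohort}). Positions are 1-based; the genome build is carried in
#' \code{metadata(x)$genome_build} and never validated against a reference.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

.validGenotypeExperiment <- function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        dd <- d[!is.na(d)]
        if (length(dd) && (min(dd) < 0 || max(dd) > 2))
            msg <- c(msg, "non-missing dosages must lie in [0, 2]")
    }
    rd <- rowData(object)
    need <- c("chrom", "pos", "id", "effect_allele", "other_allele",
              "maf", "quality_r2", "genotyped")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("pos" %in% colnames(rd) && length(rd$pos) && any(rd$pos < 1))
        msg <- c(msg, "positions must be >= 1")
    if ("maf" %in% colnames(rd) && length(rd$maf) &&
        any(rd$maf < 0 | rd$maf > 0.5, na.rm = TRUE))
        msg <- c(msg, "maf must lie in [0, 0.5]")
    if ("quality_r2" %in% colnames(rd) && length(rd$quality_r2) &&
        any(rd$quality_r2 < 0 | rd$quality_r2 > 1, na.rm = TRUE))
        msg <- c(msg, "quality_r2 must lie in [0, 1]")
    cd <- colData(object)
    needc <- c("sample_id", "sex", "phenotype", "cohort")
    missc <- setdiff(needc, colnames(cd))
    if (length(missc))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missc, collapse = ", ")))
    if ("sample_id" %in% colnames(cd) && anyDuplicated(cd$sample_id))
        msg <- c(msg, "sample_id must be unique")
    if ("phenotype" %in% colnames(cd) && length(cd$phenotype) &&
        !all(is.na(cd$phenotype) | cd$phenotype %in% c("case", "control")))
        msg <- c(msg, "phenotype must be 'case' or 'control' (NA allowed only
                 for genotype-only stubs)")
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Construct a GenotypeExperiment
#'
#' @param dosages numeric matrix, variants x samples, values in \code{[0,2]}
#'   or NA.
#' @param variants data.frame (or DataFrame) of variant annotation with
#'   columns \code{chrom}, \code{pos}, \code{id}, \code{effect_allele},
#'   \code{other_allele}; optional \code{maf}, \code{quality_r2},
#'   \code{genotyped}. A missing \code{maf} is computed from the dosages;
#'   \code{quality_r2} defaults to 1 for genotyped variants.
#' @param samples data.frame of sample annotation with columns
#'   \code{sample_id}; optional \code{sex} (\code{male}/\code{female}/
#'   \code{unknown}), \code{phenotype} (\code{case}/\code{control}),
#'   \code{cohort}.
#' @param genome_build metadata string, e.g. \code{"hg38"}; never validated.
#' @return a \linkS4class{GenotypeExperiment}.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), nrow = 2,
#'             dimnames = list(c("v1", "v2"), c("s1", "s2")))
#' v <- data.frame(chrom = "1", pos = c(100L, 200L), id = c("v1", "v2"),
#'                 effect_allele = "A", other_allele = "G")
#' s <- data.frame(sample_id = c("s1", "s2"),
#'                 phenotype = c("case", "control"))
#' ge <- GenotypeExperiment(d, v, s)
#' @export
GenotypeExperiment <- function(dosages, variants, samples,
                               genome_build = "hg38") {
    dosages <- as.matrix(dosages)
    variants <- as.data.frame(variants)
    samples <- as.data.frame(samples)
    stopifnot(nrow(dosages) == nrow(variants),
              ncol(dosages) == nrow(samples))
    if (is.null(variants$maf)) {
        af <- rowMeans(dosages, na.rm = TRUE) / 2
        variants$maf <- pmin(af, 1 - af)
    }
    if (is.null(variants$genotyped))
        variants$genotyped <- "Genotyped"
    if (is.null(variants$quality_r2))
        variants$quality_r2 <- NA_real_
    # genotyped variants carry quality 1 unless a score was provided
    fill <- is.na(variants$quality_r2) & variants$genotyped == "Genotyped"
    variants$quality_r2[fill] <- 1.0
    variants$quality_r2[is.na(variants$quality_r2)] <- 1.0
    variants$strand_ambiguous <- .strandAmbiguous(variants$effect_allele,
                                                  variants$other_allele)
    if (is.null(samples$sex)) samples$sex <- "unknown"
    samples$sex[is.na(samples$sex) | samples$sex == ""] <- "unknown"
    if (is.null(samples$phenotype)) samples$phenotype <- NA_character_
    if (is.null(samples$cohort)) samples$cohort <- "unassigned"
    rownames(dosages) <- variants$id
    colnames(dosages) <- samples$sample_id
    se <- SummarizedExperiment(
        assays = list(dosage = dosages),
        rowData = DataFrame(variants, row.names = variants$id),
        colData = DataFrame(samples, row.names = samples$sample_id))
    obj <- new("GenotypeExperiment", se)
    metadata(obj)$genome_build <- genome_build
    obj
}

.strandAmbiguous <- function(a1, a2) {
    p <- paste0(toupper(as.character(a1)), toupper(as.character(a2)))
    p %in% c("AT", "TA", "CG", "GC")
}

#' Trained clumping-and-thresholding PRS model
#'
#' Holds the scored variants (id, effect allele, beta = ln OR from the
#' training GWAS and its training P-value), the inclusion P-threshold and the
#' clumping parameters used.
#'
#' @slot entries data.frame with columns \code{id}, \code{effect_allele},
#'   \code{beta}, \code{train_p}.
#' @slot p_threshold numeric inclusion cutoff.
#' @slot clump_r2 numeric LD r-squared used for clumping.
#' @slot clump_window_kb numeric clumping window in kb.
#' @export
setClass("PRSModel", representation(
    entries = "data.frame",
    p_threshold = "numeric",
    clump_r2 = "numeric",
    clump_window_kb = "numeric"))

setValidity("PRSModel", function(object) {
    e <- object@entries
    need <- c("id", "effect_allele", "beta", "train_p")
    if (!all(need %in% colnames(e)))
        return("entries must have columns id, effect_allele, beta, train_p")
    if (nrow(e) && any(e$train_p > object@p_threshold))
        return("every entry's training P must be <= p_threshold")
    TRUE
})

#' Classifier cutoff report
#'
#' Confusion matrix and summary statistics at a PRS cutoff, with the
#' prediction rule case <=> score > cutoff; "low risk" is score <= cutoff.
#'
#' @slot cutoff numeric score cutoff.
#' @slot mcc Matthews correlation coefficient in [-1, 1].
#' @slot sensitivity,specificity proportions.
#' @slot auc area under the ROC curve of the scores.
#' @slot confusion named integer vector (tp, fp, tn, fn).
#' @export
setClass("CutoffReport", representation(
    cutoff = "numeric", mcc = "numeric",
    sensitivity = "numeric", specificity = "numeric",
    auc = "numeric", confusion = "integer"))

setValidity("CutoffReport", function(object) {
    cm <- object@confusion
    if (!all(c("tp", "fp", "tn", "fn") %in% names(cm)))
        return("confusion must be named tp, fp, tn, fn")
    if (any(cm < 0)) return("confusion counts must be non-negative")
    TRUE
})

#' Result of one stratified-GWAS direction
#'
#' Bundles everything one train-on-A / test-on-B pass produces: the selected
#' P-threshold with its AUC grid, the MCC cutoff report, the low-PRS-stratum
#' and overall association tables, the per-lead-variant odds-ratio
#' heterogeneity tests and the called loci.
#'
#' @slot direction e.g. \code{"A->B"}.
#' @slot p_threshold selected SNP-inclusion P cutoff.
#' @slot auc_grid data.frame (threshold, n_snps, auc).
#' @slot cutoff_report \linkS4class{CutoffReport} on the test-cohort scores.
#' @slot scores per-sample PRS of the test cohort (named numeric).
#' @slot low_assoc,overall_assoc association data.frames (see
#'   \code{\link{runAssoc}}).
#' @slot het heterogeneity data.frame (see \code{\link{orHeterogeneity}}).
#' @slot loci locus calls (see \code{\link{callLoci}}).
#' @slot strata list with \code{low_cases}, \code{low_controls},
#'   \code{pct_low_cases}, \code{pct_low_controls}.
#' @export
setClass("StratifiedResult", representation(
    direction = "character",
    p_threshold = "numeric",
    auc_grid = "data.frame",
    cutoff_report = "CutoffReport",
    scores = "numeric",
    low_assoc = "data.frame",
    overall_assoc = "data.frame",
    het = "data.frame",
    loci = "data.frame",
    strata = "list"))

#' Synthetic cohort simulation settings
#'
#' Parameters of the two-subtype disease model: a majority ("autoimmune-like")
#' subtype whose liability is driven by a small panel of common large-effect
#' variants and a minority subtype driven by rare moderate-to-large-effect
#' variants. Within a subtype, logit Pr(case) = intercept + sum ln(OR_i) G_i;
#' intercepts are solved so each subtype's marginal case probability equals
#' \code{baseline_prevalence}.
#'
#' @slot n_cases,n_controls target counts.
#' @slot n_null_variants effect-free variants to add.
#' @slot common_panel data.frame (maf, or_) of the majority-subtype panel.
#' @slot rare_panel data.frame (maf, or_) of the minority-subtype panel.
#' @slot subtype_fraction proportion of cases from the minority subtype.
#' @slot baseline_prevalence marginal disease probability per subtype model.
#' @slot structure_fst Balding-Nichols divergence of two subpopulations
#'   (0 disables structure).
#' @slot case_pop2_fraction,control_pop2_fraction subpopulation-2 membership
#'   probability for cases and controls (unequal values induce confounding).
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig", representation(
    n_cases = "integer", n_controls = "integer",
    n_null_variants = "integer",
    common_panel = "data.frame", rare_panel = "data.frame",
    subtype_fraction = "numeric", baseline_prevalence = "numeric",
    structure_fst = "numeric",
    case_pop2_fraction = "numeric", control_pop2_fraction = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@subtype_fraction <= 0 || object@subtype_fraction >= 1)
        msg <- c(msg, "subtype_fraction must lie in (0, 1)")
    pan <- rbind(object@common_panel, object@rare_panel)
    if (nrow(pan)) {
        if (any(pan$maf <= 0 | pan$maf >= 0.5))
            msg <- c(msg, "panel maf must lie in (0, 0.5)")
        if (any(pan$or_ <= 0))
            msg <- c(msg, "panel or_ must be > 0")
    }
    if (object@baseline_prevalence <= 0 || object@baseline_prevalence >= 1)
        msg <- c(msg, "baseline_prevalence must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
})
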