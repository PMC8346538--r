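#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("variantInfo", function(x, ...) standardGeneric("variantInfo"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' Accessors for GenotypeExperiment
#'
#' \code{dosages} returns the variants x samples dosage matrix;
#' \code{variantInfo} and \code{sampleInfo} return the variant and sample
#' annotation as plain data.frames.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param ... unused.
#' @return matrix or data.frame, see above.
#' @name GenotypeExperiment-accessors
#' @aliases dosages variantInfo sampleInfo
NULL

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("dosages", "GenotypeExperiment", function(x, ...)
    assay(x, "dosage"))

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("variantInfo", "GenotypeExperiment", function(x, ...)
    as.data.frame(rowData(x)))

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("sampleInfo", "GenotypeExperiment", function(x, ...)
    as.data.frame(colData(x)))

setMethod("show", "GenotypeExperiment", function(object) {
    cd <- colData(object)
    cat("GenotypeExperiment:", nrow(object), "variants x",
        ncol(object), "samples\n")
    if ("phenotype" %in% colnames(cd)) {
        tab <- table(factor(cd$phenotype, c("case", "control")))
        cat("  cases:", tab[["case"]], " controls:", tab[["control"]], "\n")
    }
    gb <- metadata(object)$genome_build
    if (!is.null(gb)) cat("  genome build (metadata):", gb, "\n")
    invisible(NULL)
})

setMethod("show", "PRSModel", function(object) {
    cat("PRSModel:", nrow(object@entries), "variants, P threshold <=",
        format(object@p_threshold), "\n")
    cat("  clumping: r2 <=", object@clump_r2, ", window",
        object@clump_window_kb, "kb\n")
    invisible(NULL)
})

setMethod("show", "CutoffReport", function(object) {
    cm <- object@confusion
    cat("CutoffReport: cutoff =", format(object@cutoff, digits = 4),
        " MCC =", round(object@mcc, 4), " AUC =", round(object@auc, 4), "\n")
    cat(sprintf("  tp=%d fp=%d tn=%d fn=%d  sens=%.1f%% spec=%.1f%%\n",
                cm["tp"], cm["fp"], cm["tn"], cm["fn"],
                100 * object@sensitivity, 100 * object@specificity))
    invisible(NULL)
})

setMethod("show", "StratifiedResult", function(object) {
    cat("StratifiedResult", object@direction, "\n")
    cat("  selected P threshold:", format(object@p_threshold),
        " (AUC", round(max(object@auc_grid$auc, na.rm = TRUE), 4), ")\n")
    s <- object@strata
    cat(sprintf("  low-PRS stratum: %d cases (%.1f%%), %d controls (%.1f%%)\n",
                length(s$low_cases), s$pct_low_cases,
                length(s$low_controls), s$pct_low_controls))
    cat("  genome-wide hits: low stratum",
        sum(object@low_assoc$p <= 5e-8, na.rm = TRUE),
        ", overall", sum(object@overall_assoc$p <= 5e-8, na.rm = TRUE),
        "; loci called:", nrow(object@loci), "\n")
    invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@n_cases, "cases /", object@n_controls,
        "controls;", object@n_null_variants, "null variants\n")
    cat("  common panel:", nrow(object@common_panel),
        "variants; rare panel:", nrow(object@rare_panel), "variants\n")
    cat("  minority subtype fraction:", object@subtype_fraction,
        "; baseline prevalence:", object@baseline_prevalence, "\n")
    if (object@structure_fst > 0)
        cat("  structure: Fst =", object@structure_fst, "\n")
    invisible(NULL)
})
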