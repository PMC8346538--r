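#' Evaluate an expression under a fixed RNG seed, restoring RNG state.
#' @noRd
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Filter variants on imputation quality and minor allele frequency
#'
#' Retains variants with \code{quality_r2 >= min_quality_r2} (inclusive, the
#' TOPMed-style R2 >= 0.3 default) and \code{maf} inside \code{maf_range}
#' (inclusive bounds).
#'
#' @param x variant data.frame (as from \code{\link{variantInfo}}) or a
#'   \linkS4class{GenotypeExperiment} (which is subset row-wise).
#' @param min_quality_r2 minimum imputation quality, default 0.3.
#' @param maf_range length-2 numeric, default \code{c(0, 0.5)}.
#' @param ... unused.
#' @return same class as \code{x}, restricted to passing variants.
#' @export
setGeneric("filterVariants",
           function(x, min_quality_r2 = 0.3, maf_range = c(0, 0.5), ...)
               standardGeneric("filterVariants"))

#' @rdname filterVariants
#' @export
setMethod("filterVariants", "data.frame",
          function(x, min_quality_r2 = 0.3, maf_range = c(0, 0.5), ...) {
    stopifnot(min_quality_r2 >= 0, min_quality_r2 <= 1,
              length(maf_range) == 2)
    keep <- x$quality_r2 >= min_quality_r2 &
        x$maf >= maf_range[1] & x$maf <= maf_range[2]
    x[keep & !is.na(keep), , drop = FALSE]
})

#' @rdname filterVariants
#' @export
setMethod("filterVariants", "GenotypeExperiment",
          function(x, min_quality_r2 = 0.3, maf_range = c(0, 0.5), ...) {
    v <- variantInfo(x)
    keep <- v$quality_r2 >= min_quality_r2 &
        v$maf >= maf_range[1] & v$maf <= maf_range[2]
    x[keep & !is.na(keep), ]
})

#' Randomized half-split into two cohorts, stratified by phenotype
#'
#' Partitions the samples into cohorts A and B (disjoint, exhaustive) with a
#' random half-split within each phenotype stratum; when a stratum count is
#' odd, cohort A receives the extra sample. Deterministic given \code{seed}.
#'
#' @param x sample data.frame (columns sample_id, phenotype) or a
#'   \linkS4class{GenotypeExperiment}.
#' @param seed integer seed.
#' @param ... unused.
#' @return for a data.frame, a list with elements \code{A} and \code{B}
#'   (sample data.frames with \code{cohort} set); for a
#'   GenotypeExperiment, the object with \code{cohort} filled in colData.
#' @export
setGeneric("splitCohorts", function(x, seed = 1L, ...)
    standardGeneric("splitCohorts"))

#' @rdname splitCohorts
#' @export
setMethod("splitCohorts", "data.frame", function(x, seed = 1L, ...) {
    if (any(x$cohort != "unassigned"))
        stop("samples must be unassigned before splitting", call. = FALSE)
    x$cohort <- .splitLabels(x$phenotype, seed)
    list(A = x[x$cohort == "A", , drop = FALSE],
         B = x[x$cohort == "B", , drop = FALSE])
})

#' @rdname splitCohorts
#' @export
setMethod("splitCohorts", "GenotypeExperiment", function(x, seed = 1L, ...) {
    cd <- colData(x)
    if (any(cd$cohort != "unassigned"))
        stop("samples must be unassigned before splitting", call. = FALSE)
    cd$cohort <- .splitLabels(cd$phenotype, seed)
    colData(x) <- cd
    x
})

.splitLabels <- function(phenotype, seed) {
    lab <- rep(NA_character_, length(phenotype))
    .withSeed(seed, {
        for (ph in c("case", "control")) {
            idx <- which(phenotype == ph)
            n <- length(idx)
            if (n < 2)
                stop("fewer than 2 samples in the '", ph, "' stratum",
                     call. = FALSE)
            perm <- sample(idx)
            nA <- ceiling(n / 2)  # odd remainder goes to cohort A
            lab[perm[seq_len(nA)]] <- "A"
            lab[perm[-seq_len(nA)]] <- "B"
        }
    })
    lab
}
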