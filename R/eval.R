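#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (case, control) pairs in which
#' the case scores higher, ties counted one half. Computed from mid-ranks,
#' so exact under ties.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels case/control character, factor, or 0/1 (1 = case).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
    y <- .asCase(labels)
    n1 <- sum(y); n0 <- sum(!y)
    if (n1 == 0 || n0 == 0)
        stop("both classes must be present", call. = FALSE)
    r <- rank(scores)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.asCase <- function(labels) {
    if (is.character(labels) || is.factor(labels)) {
        as.character(labels) == "case"
    } else as.numeric(labels) == 1
}

#' Matthews correlation coefficient
#'
#' (tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)); any zero factor in
#' the denominator yields 0 by convention.
#'
#' @param tp,fp,tn,fn non-negative counts; alternatively \code{tp} may be a
#'   named vector with elements tp, fp, tn, fn.
#' @return MCC in [-1, 1].
#' @export
mccScore <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
    if (is.null(fp)) {
        cm <- tp
        tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
    }
    stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
    den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (den == 0) return(0)
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

#' MCC-maximizing score cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' scores plus below-minimum and above-maximum sentinels; each is evaluated
#' with the prediction rule case <=> score > cutoff. Returns the report at
#' the maximizing cutoff (ties resolved toward the smallest cutoff).
#' Midpoint candidates keep the inclusive low-risk rule
#' (low <=> score <= cutoff) unambiguous under floating-point equality.
#'
#' @param scores numeric scores.
#' @param labels case/control labels (see \code{\link{aucScore}}).
#' @return a \linkS4class{CutoffReport}.
#' @export
bestMccCutoff <- function(scores, labels) {
    y <- .asCase(labels)
    n1 <- sum(y); n0 <- sum(!y)
    if (n1 == 0 || n0 == 0)
        stop("both classes must be present", call. = FALSE)
    s <- sort(unique(scores))
    cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
              s[length(s)] + 1)
    # counts of cases/controls at each distinct score, cumulated
    caseCum <- cumsum(vapply(s, function(v) sum(scores == v & y),
                             numeric(1)))
    ctrlCum <- cumsum(vapply(s, function(v) sum(scores == v & !y),
                             numeric(1)))
    idx <- findInterval(cand, s)          # scores <= cutoff
    fn <- c(0, caseCum)[idx + 1]          # cases predicted control (low)
    tn <- c(0, ctrlCum)[idx + 1]
    tp <- n1 - fn
    fp <- n0 - tn
    mcc <- vapply(seq_along(cand),
                  function(i) mccScore(tp[i], fp[i], tn[i], fn[i]),
                  numeric(1))
    best <- which.max(mcc)                # ties -> smallest cutoff
    cm <- c(tp = as.integer(tp[best]), fp = as.integer(fp[best]),
            tn = as.integer(tn[best]), fn = as.integer(fn[best]))
    new("CutoffReport",
        cutoff = cand[best], mcc = mcc[best],
        sensitivity = cm[["tp"]] / n1, specificity = cm[["tn"]] / n0,
        auc = aucScore(scores, labels), confusion = cm)
}

#' Stratify samples at a PRS cutoff
#'
#' Low risk is inclusive: score <= cutoff. Returns the low/high index sets,
#' the confusion matrix of the implied classifier (case <=> score > cutoff)
#' and the per-class low fractions as percentages rounded to one decimal
#' for reporting.
#'
#' @param scores numeric scores.
#' @param labels case/control labels.
#' @param cutoff finite numeric cutoff.
#' @param sample_ids optional ids to return instead of indices.
#' @return list: low, high (ids or indices), confusion (tp/fp/tn/fn),
#'   pct_low_cases, pct_low_controls.
#' @export
stratifyByScore <- function(scores, labels, cutoff, sample_ids = NULL) {
    stopifnot(is.finite(cutoff))
    y <- .asCase(labels)
    low <- scores <= cutoff
    ids <- if (is.null(sample_ids)) seq_along(scores) else sample_ids
    cm <- c(tp = sum(!low & y), fp = sum(!low & !y),
            tn = sum(low & !y), fn = sum(low & y))
    list(low = ids[low], high = ids[!low],
         confusion = as.integer(cm) |> stats::setNames(names(cm)),
         pct_low_cases = round(100 * sum(low & y) / max(sum(y), 1), 1),
         pct_low_controls = round(100 * sum(low & !y) / max(sum(!y), 1), 1))
}
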