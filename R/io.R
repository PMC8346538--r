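#' Read genotype dosages from a VCF
#'
#' Builds a \linkS4class{GenotypeExperiment} from a VCF 4.x file. Dosage of
#' the ALT (effect) allele is taken from the \code{DS} FORMAT field when
#' present, otherwise derived from \code{GT} as the ALT-allele count.
#' Imputation quality is taken from the INFO \code{R2} field when present
#' (1.0 otherwise); records flagged \code{IMPUTED} in INFO are marked
#' Imputed, all others Genotyped.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param multiallelic \code{"error"} (default) to refuse multi-allelic
#'   records, \code{"drop"} to discard them with a message.
#' @param genome_build metadata label, default \code{"hg38"}.
#' @return a \linkS4class{GenotypeExperiment} whose samples are phenotype
#'   stubs (phenotype NA) until \code{\link{attachPhenotypes}} is called.
#' @export
readGenotypeVcf <- function(path, multiallelic = c("error", "drop"),
                            genome_build = "hg38") {
    multiallelic <- match.arg(multiallelic)
    vcf <- tryCatch(
        VariantAnnotation::readVcf(path, genome = genome_build),
        error = function(e) stop("malformed VCF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    alt <- VariantAnnotation::alt(vcf)
    nalt <- S4Vectors::elementNROWS(alt)
    if (any(nalt != 1)) {
        bad <- which(nalt != 1)
        if (multiallelic == "error")
            stop("multi-allelic record(s) at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 "; rerun with multiallelic = 'drop'", call. = FALSE)
        message("dropping ", length(bad), " multi-allelic record(s)")
        vcf <- vcf[nalt == 1]
    }
    gen <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gen)) {
        dos <- gen$DS
        storage.mode(dos) <- "double"
    } else if ("GT" %in% names(gen)) {
        dos <- .gtToDosage(gen$GT)
    } else {
        stop("VCF '", path, "' has neither DS nor GT FORMAT fields",
             call. = FALSE)
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altc <- as.character(unlist(VariantAnnotation::alt(vcf)))
    ids <- names(rr)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    fallback <- paste(chrom, pos, ref, altc, sep = ":")
    ids[is.na(ids) | ids == "." | ids == ""] <- fallback[
        is.na(ids) | ids == "." | ids == ""]
    inf <- VariantAnnotation::info(vcf)
    q2 <- if ("R2" %in% colnames(inf)) as.numeric(inf$R2) else
        rep(NA_real_, length(rr))
    gtyped <- if ("IMPUTED" %in% colnames(inf)) {
        ifelse(isTRUE_vec(inf$IMPUTED), "Imputed", "Genotyped")
    } else rep("Genotyped", length(rr))
    variants <- data.frame(
        chrom = chrom, pos = pos, id = ids,
        effect_allele = altc, other_allele = ref,
        quality_r2 = q2, genotyped = gtyped,
        stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = colnames(dos),
                          sex = "unknown",
                          phenotype = NA_character_,
                          cohort = "unassigned",
                          stringsAsFactors = FALSE)
    GenotypeExperiment(dos, variants, samples, genome_build = genome_build)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

.gtToDosage <- function(gt) {
    u <- unique(as.vector(gt))
    val <- vapply(u, function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".")) return(NA_real_)
        sum(al == "1")
    }, numeric(1))
    m <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
    m
}

#' Write a GenotypeExperiment as a dosage VCF
#'
#' Emits a minimal VCF 4.2 with both \code{GT} (rounded dosage; \code{./.}
#' when missing) and \code{DS} FORMAT fields, plus INFO \code{R2} and
#' \code{IMPUTED}. Round-trips through \code{\link{readGenotypeVcf}}.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(ge, path) {
    v <- variantInfo(ge)
    d <- dosages(ge)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
        "##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"Imputed marker\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
    gtcode <- function(x) {
        g <- ifelse(is.na(x), "./.",
                    c("0/0", "0/1", "1/1")[pmin(pmax(round(x), 0), 2) + 1])
        g
    }
    for (i in seq_len(nrow(v))) {
        info <- sprintf("R2=%s%s", format(v$quality_r2[i], digits = 6),
                        if (v$genotyped[i] == "Imputed") ";IMPUTED" else "")
        ds <- ifelse(is.na(d[i, ]), ".", format(d[i, ], digits = 8,
                                                trim = TRUE))
        field <- paste(gtcode(d[i, ]), ds, sep = ":")
        writeLines(paste(c(v$chrom[i], v$pos[i], v$id[i],
                           v$other_allele[i], v$effect_allele[i], ".", "PASS",
                           info, "GT:DS", field), collapse = "\t"), con)
    }
    invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with header columns \code{sample_id}, \code{sex},
#' \code{phenotype} and optionally \code{cohort}. Blank or missing sex is
#' mapped to \code{"unknown"} and the record is kept (sex-undetermined
#' samples stay in the analysis); phenotype is strictly parsed as
#' \code{case}/\code{control}.
#'
#' @param path path to the TSV.
#' @return data.frame with columns sample_id, sex, phenotype, cohort.
#' @export
readPhenotypes <- function(path) {
    ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample_id", "sex", "phenotype")
    if (!all(need %in% colnames(ph)))
        stop("phenotype file must have columns sample_id, sex, phenotype",
             call. = FALSE)
    if (anyDuplicated(ph$sample_id))
        stop("duplicate sample_id in '", path, "': ",
             ph$sample_id[duplicated(ph$sample_id)][1], call. = FALSE)
    ph$sex[is.na(ph$sex) | !(ph$sex %in% c("male", "female"))] <- "unknown"
    bad <- !(ph$phenotype %in% c("case", "control"))
    if (any(bad))
        stop("unparseable phenotype value(s): ",
             paste(unique(ph$phenotype[bad]), collapse = ", "), call. = FALSE)
    if (is.null(ph$cohort)) ph$cohort <- "unassigned"
    ph$cohort[is.na(ph$cohort) | ph$cohort == ""] <- "unassigned"
    ph[c("sample_id", "sex", "phenotype", "cohort")]
}

#' Attach phenotypes to a genotype container
#'
#' Joins a phenotype table (see \code{\link{readPhenotypes}}) onto the
#' samples of a \linkS4class{GenotypeExperiment} by \code{sample_id}.
#'
#' @param ge a \linkS4class{GenotypeExperiment}.
#' @param phenotypes data.frame from \code{\link{readPhenotypes}}.
#' @return the updated \linkS4class{GenotypeExperiment}.
#' @export
attachPhenotypes <- function(ge, phenotypes) {
    cd <- colData(ge)
    idx <- match(cd$sample_id, phenotypes$sample_id)
    if (anyNA(idx))
        stop("phenotype table lacks ", sum(is.na(idx)), " sample(s), e.g. ",
             cd$sample_id[which(is.na(idx))[1]], call. = FALSE)
    cd$sex <- phenotypes$sex[idx]
    cd$phenotype <- phenotypes$phenotype[idx]
    cd$cohort <- phenotypes$cohort[idx]
    colData(ge) <- cd
    validObject(ge)
    ge
}

#' @importFrom SummarizedExperiment colData<-
NULL

.assocCols <- c("CHR", "SNP", "BP", "A1", "QUALITY_R2", "GENOTYPED",
                "MAF", "N", "OR", "L95", "U95", "P")

#' Write / read a PLINK-style association table
#'
#' The TSV layout has columns CHR, SNP, BP, A1, QUALITY_R2, GENOTYPED, MAF,
#' N, OR, L95, U95, P. Numeric fields are serialized with 6 significant
#' digits; the OR is written as a decimal odds ratio, never as a log.
#'
#' @param results association data.frame as returned by
#'   \code{\link{runAssoc}}.
#' @param path output (input) path.
#' @return \code{writeAssocTable}: \code{path} invisibly;
#'   \code{readAssocTable}: association data.frame with \code{beta} and
#'   \code{se} reconstructed from OR and its CI.
#' @export
writeAssocTable <- function(results, path) {
    num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    out <- data.frame(
        CHR = results$chrom, SNP = results$id, BP = results$pos,
        A1 = results$effect_allele,
        QUALITY_R2 = num(results$quality_r2),
        GENOTYPED = results$genotyped,
        MAF = num(results$maf), N = results$n,
        OR = num(results$or_), L95 = num(results$l95),
        U95 = num(results$u95), P = num(results$p),
        stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeAssocTable
#' @export
readAssocTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(CHR = "character",
                                            SNP = "character"))
    if (!all(.assocCols %in% colnames(tab)))
        stop("association table must have columns ",
             paste(.assocCols, collapse = ", "), call. = FALSE)
    data.frame(
        chrom = tab$CHR, id = tab$SNP, pos = tab$BP,
        effect_allele = tab$A1, quality_r2 = tab$QUALITY_R2,
        genotyped = tab$GENOTYPED, maf = tab$MAF, n = tab$N,
        beta = log(tab$OR), se = log(tab$U95 / tab$L95) / (2 * 1.96),
        or_ = tab$OR, l95 = tab$L95, u95 = tab$U95, p = tab$P,
        test = rep(NA_character_, nrow(tab)), stringsAsFactors = FALSE)
}

#' Read a known-locus BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based closed
#' \linkS4class{GRanges} internally.
#'
#' @param path path to a BED file.
#' @return a \code{GRanges} of known loci.
#' @export
readKnownLoci <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("malformed BED '", path, "': ",
                                            conditionMessage(e),
                                            call. = FALSE))
    if (any(GenomicRanges::width(gr) < 1))
        stop("malformed known-locus interval (end < start)", call. = FALSE)
    gr
}
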