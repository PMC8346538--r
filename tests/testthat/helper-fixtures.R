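# in-code fixtures shared across test files

toyGenotypes <- function(n_var = 4, n_sam = 6, seed = 1) {
    set.seed(seed)
    d <- matrix(sample(0:2, n_var * n_sam, replace = TRUE), n_var, n_sam)
    v <- data.frame(chrom = as.character(rep(1:2, length.out = n_var)),
                    pos = seq(1e6, by = 5e4, length.out = n_var),
                    id = paste0("rs", seq_len(n_var)),
                    effect_allele = "A", other_allele = "G",
                    stringsAsFactors = FALSE)
    s <- data.frame(sample_id = paste0("s", seq_len(n_sam)),
                    sex = rep(c("male", "female"), length.out = n_sam),
                    phenotype = rep(c("case", "control"),
                                    length.out = n_sam),
                    stringsAsFactors = FALSE)
    GenotypeExperiment(d, v, s)
}

# a GenotypeExperiment from explicit pieces, with defaults filled
makeGe <- function(dosages, chrom = "1", pos = NULL, ids = NULL,
                   phenotype = NULL, quality_r2 = NULL, maf = NULL) {
    m <- nrow(dosages); n <- ncol(dosages)
    v <- data.frame(
        chrom = rep_len(chrom, m),
        pos = if (is.null(pos)) seq(1e6, by = 1e5, length.out = m) else pos,
        id = if (is.null(ids)) sprintf("v%03d", seq_len(m)) else ids,
        effect_allele = "A", other_allele = "G", stringsAsFactors = FALSE)
    if (!is.null(quality_r2)) v$quality_r2 <- quality_r2
    if (!is.null(maf)) v$maf <- maf
    s <- data.frame(
        sample_id = sprintf("s%03d", seq_len(n)),
        phenotype = if (is.null(phenotype))
            rep(c("case", "control"), length.out = n) else phenotype,
        stringsAsFactors = FALSE)
    GenotypeExperiment(dosages, v, s)
}

# association-result rows for PRS / clumping tests
fakeTrainResults <- function(p, chrom = "1", pos = NULL, beta = NULL,
                             ids = NULL) {
    m <- length(p)
    data.frame(
        chrom = rep_len(chrom, m),
        id = if (is.null(ids)) sprintf("v%03d", seq_len(m)) else ids,
        pos = if (is.null(pos)) seq(1e6, by = 1e5, length.out = m) else pos,
        effect_allele = "A", other_allele = "G",
        maf = 0.2, quality_r2 = 1, genotyped = "Genotyped", n = 100L,
        beta = if (is.null(beta)) rep(0.1, m) else beta,
        se = 0.05, or_ = exp(if (is.null(beta)) rep(0.1, m) else beta),
        l95 = NA, u95 = NA, p = p, test = "wald",
        stringsAsFactors = FALSE)
}
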