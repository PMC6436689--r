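# Case-control genotype container and the two supported input dialects.

#' @rdname GenotypeDataset-class
#' @param genotypes individuals x SNPs matrix of minor-allele counts
#'   (0/1/2, NA for missing).
#' @param phenotype binary vector, 1 = case, 0 = control.
#' @param snpIds SNP identifiers; defaults to column names or SNP1..SNPp.
#' @export
GenotypeDataset <- function(genotypes, phenotype, snpIds = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(snpIds))
    snpIds <- colnames(genotypes)
  if (is.null(snpIds))
    snpIds <- paste0("SNP", seq_len(ncol(genotypes)))
  colnames(genotypes) <- snpIds
  phenotype <- as.integer(phenotype)
  ctrl <- genotypes[phenotype == 0L, , drop = FALSE]
  freq <- colMeans(ctrl, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  new("GenotypeDataset", genotypes = genotypes, phenotype = phenotype,
      snpIds = as.character(snpIds), controlMaf = pmin(freq, 1 - freq))
}

#' @rdname GenotypeDataset-class
#' @export
setMethod("genotypes", "GenotypeDataset", function(x) x@genotypes)

#' @rdname GenotypeDataset-class
#' @export
setMethod("phenotype", "GenotypeDataset", function(x) x@phenotype)

#' @rdname GenotypeDataset-class
#' @export
setMethod("snpIds", "GenotypeDataset", function(x) x@snpIds)

#' @rdname GenotypeDataset-class
#' @export
setMethod("controlMaf", "GenotypeDataset", function(x) x@controlMaf)

#' @rdname GenotypeDataset-class
#' @export
setMethod("nIndividuals", "GenotypeDataset", function(x) nrow(x@genotypes))

#' @rdname GenotypeDataset-class
#' @export
setMethod("nSnps", "GenotypeDataset", function(x) ncol(x@genotypes))

setMethod("show", "GenotypeDataset", function(object) {
  cat(sprintf(paste0("GenotypeDataset: %d individuals (%d cases, %d ",
                     "controls) x %d SNPs; control MAF range [%.3f, %.3f]\n"),
              nIndividuals(object), sum(object@phenotype == 1L),
              sum(object@phenotype == 0L), nSnps(object),
              min(object@controlMaf), max(object@controlMaf)))
})

#' Read case-control genotypes
#'
#' Two dialects are supported.  `simple_tsv`: a tab-separated table with a
#' `sample_id` column, a binary `phenotype` column (1 = case, 0 = control)
#' and one column of minor-allele counts (0/1/2, NA) per SNP.  `plink_raw`:
#' PLINK additive recode (`--recode A`) with the header
#' `FID IID PAT MAT SEX PHENOTYPE SNP...`; phenotypes 1/2 map to control/case
#' and NA is honored.
#'
#' After parsing, any SNP whose control allele frequency exceeds 0.5 is
#' re-oriented (counts flipped c -> 2 - c) so the minor allele is counted;
#' flipped SNPs are reported in a message and in the `flipped` attribute.
#'
#' @param path input file.
#' @param dialect `"simple_tsv"` or `"plink_raw"`.
#' @return a [`GenotypeDataset`][GenotypeDataset-class].
#' @export
readGenotypes <- function(path, dialect = c("simple_tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "simple_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample_id", "phenotype")
    if (!all(need %in% names(df)))
      stop("simple_tsv requires columns: ", paste(need, collapse = ", "))
    ids <- as.character(df$sample_id)
    phen <- df$phenotype
    geno <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)))
      stop("plink_raw requires the header columns ",
           paste(meta, collapse = " "))
    ids <- paste(df$FID, df$IID, sep = ":")
    raw_phen <- df$PHENOTYPE
    if (!all(raw_phen %in% c(1, 2, NA)))
      stop("plink_raw phenotype must be 1 (control) or 2 (case); offending ",
           "line ", which(!raw_phen %in% c(1, 2, NA))[1])
    phen <- raw_phen - 1
    geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  }
  if (anyDuplicated(ids))
    stop("duplicate sample id at line ", which(duplicated(ids))[1] + 1)
  bad_phen <- which(!phen %in% c(0, 1))
  if (length(bad_phen))
    stop("non-binary phenotype at line ", bad_phen[1] + 1)
  bad <- which(!(geno %in% c(0, 1, 2) | is.na(geno)))
  if (length(bad)) {
    row <- (bad[1] - 1) %% nrow(geno) + 1
    stop("unknown genotype symbol '", geno[bad[1]], "' at line ", row + 1)
  }
  storage.mode(geno) <- "integer"
  # minor-allele orientation from control frequencies
  ctrl <- geno[phen == 0, , drop = FALSE]
  freq <- colMeans(ctrl, na.rm = TRUE) / 2
  flip <- which(!is.nan(freq) & freq > 0.5)
  if (length(flip)) {
    geno[, flip] <- 2L - geno[, flip]
    message("re-oriented ", length(flip), " SNP(s) to minor-allele counts: ",
            paste(utils::head(colnames(geno)[flip], 5), collapse = ", "),
            if (length(flip) > 5) ", ..." else "")
  }
  rownames(geno) <- ids
  ds <- GenotypeDataset(geno, phen)
  attr(ds, "flipped") <- colnames(geno)[flip]
  ds
}

#' Write a dataset in the simple TSV dialect
#'
#' @param ds a [`GenotypeDataset`][GenotypeDataset-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(ds, path) {
  stopifnot(is(ds, "GenotypeDataset"))
  ids <- rownames(ds@genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nIndividuals(ds)))
  df <- data.frame(sample_id = ids, phenotype = ds@phenotype,
                   ds@genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
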