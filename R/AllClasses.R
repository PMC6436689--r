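#' @import methods
NULL

#' TTTC disease model
#'
#' A two-locus, two-allele, two-phenotype, complete-penetrance (TTTC) disease
#' model: a 3x3 table of binary risk indicators over the genotype combinations
#' of a SNP pair.  Rows are indexed by the minor-allele count of SNP A
#' (0 = AA, 1 = Aa, 2 = aa), columns by the count of SNP B (0 = BB, 1 = Bb,
#' 2 = bb).  A 1 marks a genotype combination that elevates disease risk.
#'
#' Models serialize to a 9-character 0/1 string in row-major order
#' (string index = 3 * countA + countB + 1), which is the canonical id used
#' in prototype-library files and screening output.
#'
#' @slot cells integer 3x3 matrix with entries in \{0, 1\}.
#'
#' @seealso [DiseaseModel()], [modelId()], [enumerateNontrivial()]
#' @export
setClass("DiseaseModel", representation(cells = "matrix"))

setValidity("DiseaseModel", function(object) {
  m <- object@cells
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    return("cells must be a 3x3 numeric matrix")
  if (!all(m %in% c(0, 1)))
    return("cells must be binary (0/1)")
  TRUE
})

#' Population context for the model-distance metric
#'
#' The population and sampling parameters that calibrate the directional
#' distance between disease models: the minor-allele frequencies of the two
#' SNPs (Hardy-Weinberg equilibrium is assumed), the disease prevalence
#' P(D), the heritability h^2 attributed to the SNP pair, and the
#' case-control ratio r of the sample (cases per control).  The
#' population-wide case-control ratio r0 = P(D) / (1 - P(D)) is derived,
#' never stored.
#'
#' @slot mafA,mafB minor-allele frequencies in (0, 0.5].
#' @slot prevalence disease prevalence P(D) in (0, 1); default 0.02.
#' @slot heritability heritability h^2 >= 0; default 0.02.
#' @slot sampleRatio case-control ratio r > 0 of the sample; default 1.
#'
#' @seealso [PopulationContext()], [modelPhi()], [modelDistance()]
#' @export
setClass("PopulationContext",
         representation(mafA = "numeric", mafB = "numeric",
                        prevalence = "numeric", heritability = "numeric",
                        sampleRatio = "numeric"))

setValidity("PopulationContext", function(object) {
  msg <- character()
  for (s in c("mafA", "mafB")) {
    q <- slot(object, s)
    if (length(q) != 1 || is.na(q) || q <= 0 || q > 0.5)
      msg <- c(msg, sprintf("%s must be a single value in (0, 0.5]", s))
  }
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must be in (0, 1)")
  if (object@heritability < 0)
    msg <- c(msg, "heritability must be >= 0")
  if (object@sampleRatio <= 0)
    msg <- c(msg, "sampleRatio must be > 0")
  if (length(msg)) msg else TRUE
})

#' Case-control genotype dataset
#'
#' Individuals by SNPs matrix of minor-allele counts (0/1/2, NA allowed for
#' missing genotypes) together with a binary phenotype (1 = case,
#' 0 = control).  Per-SNP minor-allele frequencies estimated from the control
#' sample are computed at construction and used to pick prototype sets at
#' screening time.
#'
#' @slot genotypes integer matrix, individuals in rows, SNPs in columns.
#' @slot phenotype integer vector, one per individual, 0/1.
#' @slot snpIds character vector of SNP identifiers (column names).
#' @slot controlMaf numeric vector of per-SNP control minor-allele
#'   frequencies, in [0, 0.5].
#'
#' @seealso [GenotypeDataset()], [readGenotypes()], [marginalScreen()]
#' @export
setClass("GenotypeDataset",
         representation(genotypes = "matrix", phenotype = "integer",
                        snpIds = "character", controlMaf = "numeric"))

setValidity("GenotypeDataset", function(object) {
  g <- object@genotypes
  msg <- character()
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotypes must be minor-allele counts 0/1/2 or NA")
  if (length(object@phenotype) != nrow(g))
    msg <- c(msg, "phenotype length must equal the number of individuals")
  if (!all(object@phenotype %in% 0:1))
    msg <- c(msg, "phenotype must be binary 0/1")
  if (sum(object@phenotype == 1L) < 1 || sum(object@phenotype == 0L) < 1)
    msg <- c(msg, "need at least one case and one control")
  if (length(object@snpIds) != ncol(g))
    msg <- c(msg, "snpIds length must equal the number of SNPs")
  if (length(object@controlMaf) != ncol(g))
    msg <- c(msg, "controlMaf length must equal the number of SNPs")
  if (any(object@controlMaf < 0 | object@controlMaf > 0.5, na.rm = TRUE))
    msg <- c(msg, "controlMaf must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Library of prototype disease models
#'
#' For every ordered pair of MAF bins on the grid
#' \{0.05, 0.1, 0.2, 0.3, 0.4, 0.45\} (36 entries), an ordered set of K
#' prototype disease models selected a priori by the global K-means
#' algorithm under the directional model distance, together with the cluster
#' membership of every clustered model and the build parameters.
#'
#' @slot binGrid numeric vector of MAF grid values.
#' @slot entries named list, one element per bin pair (key "mafA,mafB"),
#'   each with components `prototypes` (character, K model ids, in selection
#'   order), `members` (character, clustered model ids), `assignment`
#'   (character, nearest prototype id per member), `withinDistance`
#'   (numeric, total within-cluster distance after each selection step) and
#'   `excluded` (character, model ids infeasible at that bin pair).
#' @slot params list with `k`, `prevalence`, `heritability`, `sampleRatio`.
#' @slot version character format tag.
#'
#' @seealso [buildPrototypeLibrary()], [prototypesFor()],
#'   [writePrototypeLibrary()]
#' @export
setClass("PrototypeLibrary",
         representation(binGrid = "numeric", entries = "list",
                        params = "list", version = "character"))

setValidity("PrototypeLibrary", function(object) {
  msg <- character()
  want <- as.vector(outer(object@binGrid, object@binGrid,
                          function(a, b)
                            paste(as.character(a), as.character(b),
                                  sep = ",")))
  if (!setequal(names(object@entries), want))
    msg <- c(msg, "entries must cover every bin-grid pair exactly once")
  k <- object@params$k
  nproto <- vapply(object@entries, function(e) length(e$prototypes), 1L)
  if (!is.null(k) && any(nproto != k))
    msg <- c(msg, sprintf("every entry must hold exactly k = %d prototypes", k))
  ok <- vapply(object@entries,
               function(e) all(grepl("^[01]{9}$", e$prototypes)), TRUE)
  if (!all(ok))
    msg <- c(msg, "prototype ids must be 9-character 0/1 strings")
  if (length(msg)) msg else TRUE
})
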