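#' @rdname DiseaseModel-class
#' @param object,m a `DiseaseModel`.
#' @export
setGeneric("modelId", function(m) standardGeneric("modelId"))

#' @rdname DiseaseModel-class
#' @export
setGeneric("modelCells", function(m) standardGeneric("modelCells"))

#' @rdname DiseaseModel-class
#' @export
setGeneric("transposeModel", function(m) standardGeneric("transposeModel"))

#' @rdname DiseaseModel-class
#' @export
setGeneric("complementModel", function(m) standardGeneric("complementModel"))

#' @rdname DiseaseModel-class
#' @export
setGeneric("canonicalModel", function(m) standardGeneric("canonicalModel"))

#' @rdname GenotypeDataset-class
#' @param x a `GenotypeDataset`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("controlMaf", function(x) standardGeneric("controlMaf"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname PopulationContext-class
#' @param ctx a `PopulationContext`.
#' @export
setGeneric("populationRatio", function(ctx) standardGeneric("populationRatio"))

#' @rdname PrototypeLibrary-class
#' @param lib a `PrototypeLibrary`.
#' @param mafA,mafB minor-allele frequencies of the two SNPs of a pair.
#' @export
setGeneric("prototypesFor",
           function(lib, mafA, mafB) standardGeneric("prototypesFor"))

#' @rdname PrototypeLibrary-class
#' @export
setGeneric("libraryParams", function(lib) standardGeneric("libraryParams"))
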