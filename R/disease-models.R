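# Representation and symmetry algebra of TTTC disease models.
#
# Index convention (used everywhere in the package): a genotype is the
# minor-allele count, so 0 = homozygous major (AA), 1 = heterozygous (Aa),
# 2 = homozygous minor (aa).  Model cell (i, j) refers to countA = i,
# countB = j; the serialized id is row-major, id character 3*i + j + 1.

.GENO_LABELS_A <- c("AA", "Aa", "aa")
.GENO_LABELS_B <- c("BB", "Bb", "bb")

.id_to_cells <- function(id) {
  if (!is.character(id) || length(id) != 1 || !grepl("^[01]{9}$", id))
    stop("model id must be a 9-character 0/1 string, got: ",
         deparse(substitute(id)))
  matrix(as.integer(strsplit(id, "")[[1]]), nrow = 3, byrow = TRUE)
}

.cells_to_id <- function(cells) paste(as.integer(t(cells)), collapse = "")

#' Construct a TTTC disease model
#'
#' @param x either a 9-character 0/1 string (row-major id) or a 3x3 binary
#'   matrix (rows = SNP-A minor-allele count 0/1/2, columns = SNP-B count).
#' @return a [`DiseaseModel`][DiseaseModel-class] object.
#' @examples
#' DiseaseModel("001010100")         # the anti-diagonal (XOR-like) model
#' DiseaseModel(diag(3))             # risky iff equal minor-allele counts
#' @export
DiseaseModel <- function(x) {
  cells <- if (is.character(x)) .id_to_cells(x) else {
    if (!is.matrix(x)) stop("x must be a 9-character 0/1 string or 3x3 matrix")
    matrix(as.integer(x), 3, 3)
  }
  new("DiseaseModel", cells = cells)
}

#' @rdname DiseaseModel-class
#' @export
setMethod("modelId", "DiseaseModel", function(m) .cells_to_id(m@cells))

#' @rdname DiseaseModel-class
#' @export
setMethod("modelCells", "DiseaseModel", function(m) {
  cells <- m@cells
  dimnames(cells) <- list(.GENO_LABELS_A, .GENO_LABELS_B)
  cells
})

setMethod("show", "DiseaseModel", function(object) {
  cat("TTTC disease model", modelId(object), "\n")
  print(modelCells(object))
})

#' @rdname DiseaseModel-class
#' @export
setMethod("transposeModel", "DiseaseModel", function(m)
  new("DiseaseModel", cells = t(m@cells)))

#' @rdname DiseaseModel-class
#' @export
setMethod("complementModel", "DiseaseModel", function(m)
  new("DiseaseModel", cells = 1L - m@cells))

#' @rdname DiseaseModel-class
#' @export
setGeneric("isTrivial", function(m) standardGeneric("isTrivial"))

#' @rdname DiseaseModel-class
#' @export
setMethod("isTrivial", "DiseaseModel", function(m)
  all(m@cells == 0L) || all(m@cells == 1L))

# orbit of an id under {identity, transpose, complement, both}
.orbit_ids <- function(id) {
  cells <- .id_to_cells(id)
  unique(c(.cells_to_id(cells), .cells_to_id(t(cells)),
           .cells_to_id(1L - cells), .cells_to_id(1L - t(cells))))
}

#' @describeIn DiseaseModel-class the canonical representative of `m` under
#'   the symmetry group generated by locus exchange (transpose) and disease
#'   status exchange (complement): the orbit member with the
#'   lexicographically smallest id.  Errors on trivial models.
#' @export
setMethod("canonicalModel", "DiseaseModel", function(m) {
  if (isTrivial(m)) stop("trivial models have no canonical representative")
  DiseaseModel(min(.orbit_ids(modelId(m))))
})

.all_nontrivial_ids <- function() {
  ids <- vapply(1:510, function(v)
    paste(rev(as.integer(intToBits(v))[1:9]), collapse = ""), "")
  sort(ids)
}

#' Enumerate all non-trivial TTTC disease models
#'
#' There are 2^9 - 2 = 510 non-trivial models (the all-0 and all-1 tables
#' are excluded).  Returned in lexicographic id order.
#'
#' @param ids logical; if `TRUE` return the character ids instead of
#'   `DiseaseModel` objects.
#' @return a list of [`DiseaseModel`][DiseaseModel-class] objects (or a
#'   character vector of ids).
#' @export
enumerateNontrivial <- function(ids = FALSE) {
  out <- .all_nontrivial_ids()
  if (ids) out else lapply(out, DiseaseModel)
}

#' Symmetry-reduced set of disease models
#'
#' One canonical representative per orbit of the non-trivial models under
#' the order-4 group \{identity, transpose, complement, both\}; there are
#' 143 orbits.  Sorted lexicographically by id.
#'
#' @inheritParams enumerateNontrivial
#' @return a list of [`DiseaseModel`][DiseaseModel-class] objects (or ids).
#' @export
reducedModelSet <- function(ids = FALSE) {
  all_ids <- .all_nontrivial_ids()
  canon <- vapply(all_ids, function(id) min(.orbit_ids(id)), "",
                  USE.NAMES = FALSE)
  out <- sort(unique(canon))
  if (ids) out else lapply(out, DiseaseModel)
}

#' Per-individual risk assignment under a disease model
#'
#' Looks up the model cell for each individual's genotype combination.
#'
#' @param m a [`DiseaseModel`][DiseaseModel-class].
#' @param genoA,genoB integer vectors of minor-allele counts (0/1/2) at the
#'   two SNPs; must be the same length.  `NA` propagates.
#' @return integer vector of 0/1 risk indicators.
#' @export
riskVector <- function(m, genoA, genoB) {
  stopifnot(is(m, "DiseaseModel"), length(genoA) == length(genoB))
  if (!all(genoA %in% c(0:2, NA)) || !all(genoB %in% c(0:2, NA)))
    stop("genotype counts must be 0, 1, 2 or NA")
  m@cells[cbind(genoA + 1L, genoB + 1L)]
}

# k x 9 binary matrix of model rows (row-major cell order), for the
# vectorized screening / metric engines
.model_matrix <- function(model_ids) {
  t(vapply(model_ids, function(id) as.integer(strsplit(id, "")[[1]]),
           integer(9)))
}

.transpose_id <- function(id) .cells_to_id(t(.id_to_cells(id)))
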