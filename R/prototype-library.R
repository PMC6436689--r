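# A-priori prototype selection: global K-means over the directional model
# distance, one prototype set per MAF-bin pair.

.MAF_BINS <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.45)
.LIBRARY_VERSION <- "prototype-library/1"

.bin_key <- function(a, b) paste(as.character(a), as.character(b), sep = ",")

#' Nearest MAF bin
#'
#' Maps an observed minor-allele frequency to the nearest value on the bin
#' grid; exact midpoints round down to the smaller bin.  Frequencies at or
#' below the smallest grid value (including 0 for monomorphic SNPs) map to
#' the smallest bin.
#'
#' @param maf frequency in [0, 0.5] (vectorized).
#' @param grid ordered grid of bin values.
#' @return the grid values nearest to `maf`.
#' @examples
#' assignMafBin(c(0.068, 0.182))  # -> 0.05, 0.2
#' @export
assignMafBin <- function(maf, grid = .MAF_BINS) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  vapply(maf, function(q) {
    d <- abs(grid - q)
    grid[which.min(d)]  # which.min takes the first (smaller) bin on ties
  }, numeric(1))
}

#' Global K-means prototype selection
#'
#' Incremental greedy clustering: starting from an empty prototype set, each
#' step evaluates every remaining model as a potential new cluster center by
#' assigning all models to their nearest center (existing or candidate) and
#' summing the within-cluster distances `d(center, member)`; the candidate
#' minimizing the total is appended.  The first prototype is therefore the
#' medoid of the whole set.  Ties break to the lexicographically smallest
#' model id.
#'
#' @param dist square matrix of directional distances `dist[i, j] =
#'   d(candidate-center i, member j)` with model ids as dimnames; must be
#'   finite with zero diagonal.
#' @param k number of prototypes to select (>= 1, <= `nrow(dist)`).
#' @return list with `prototypes` (character, selection order), `assignment`
#'   (character, nearest prototype per member, named by member id) and
#'   `withinDistance` (numeric, total within-cluster distance after each
#'   step; non-increasing).
#' @export
globalKMeans <- function(dist, k) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (k < 1 || k > nrow(dist))
    stop("k must be between 1 and the number of models")
  if (any(!is.finite(dist))) stop("distances must be finite")
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dist)))
  ord <- order(ids)  # tie-break scan order: lexicographic by id
  n <- nrow(dist)
  centers <- integer(0)
  nearest <- rep(Inf, n)  # distance to nearest selected center, per member
  wss <- numeric(0)
  for (step in seq_len(k)) {
    best_total <- Inf
    best_i <- NA_integer_
    for (i in ord) {
      if (i %in% centers) next
      total <- sum(pmin(nearest, dist[i, ]))
      if (total < best_total - 1e-12) {  # strict improvement; ties keep first
        best_total <- total
        best_i <- i
      }
    }
    centers <- c(centers, best_i)
    nearest <- pmin(nearest, dist[best_i, ])
    wss <- c(wss, best_total)
  }
  # final assignment to the nearest selected center (ties: earlier selection)
  sub <- dist[centers, , drop = FALSE]
  assign_idx <- apply(sub, 2, which.min)
  assignment <- ids[centers][assign_idx]
  names(assignment) <- ids
  list(prototypes = ids[centers], assignment = assignment,
       withinDistance = wss)
}

#' Build the full prototype library
#'
#' For every ordered pair of MAF bins, computes the directional distance
#' table over the symmetry-reduced model set (rows = candidate prototype,
#' columns = true model) at the given prevalence, heritability and sample
#' ratio, drops models with no valid two-level penetrance at that bin pair,
#' and runs [globalKMeans()] to select `k` prototypes.
#'
#' @param k prototypes per bin pair (default 7).
#' @param prevalence,heritability population parameters used to calibrate
#'   the metric (default 0.02 each).
#' @param sampleRatio case-control ratio assumed at build time (default 1).
#' @param bins MAF bin grid.
#' @param modelIds models to cluster; defaults to the 143-member reduced set.
#' @return a [`PrototypeLibrary`][PrototypeLibrary-class].
#' @export
buildPrototypeLibrary <- function(k = 7, prevalence = 0.02,
                                  heritability = 0.02, sampleRatio = 1,
                                  bins = .MAF_BINS,
                                  modelIds = reducedModelSet(ids = TRUE)) {
  if (length(bins) < 1) stop("bins must be non-empty")
  if (k < 1) stop("k must be >= 1")
  entries <- list()
  comp_id <- function(id) .cells_to_id(1L - .id_to_cells(id))
  for (a in bins) for (b in bins) {
    ctx <- PopulationContext(mafA = a, mafB = b, prevalence = prevalence,
                             heritability = heritability,
                             sampleRatio = sampleRatio)
    # Each model and its status-exchanged complement describe the same
    # risky/non-risky partition (and induce identical chi-squares at
    # screening), but only the orientation whose risky mass is small
    # enough admits the two-level penetrance implied by the prevalence
    # and heritability.  Cluster every partition in its feasible
    # orientation at this bin pair; partitions with (near-)zero risky
    # mass in both orientations are dropped from this entry.
    p <- .cell_probs(a, b)
    w1 <- as.vector(.model_matrix(modelIds) %*% p)
    bound <- prevalence / ((1 - prevalence) * heritability + prevalence)
    oriented <- ifelse(w1 > bound, vapply(modelIds, comp_id, ""), modelIds)
    tab <- .distance_table(oriented, oriented, ctx)
    keep <- tab$feasible
    if (sum(keep) < k)
      stop(sprintf("bin pair (%g, %g): only %d feasible models, need k = %d",
                   a, b, sum(keep), k))
    # Clustering orientation: the center plays the reference (true) model
    # and each member the prototype approximating it, so the cluster
    # criterion asks how well members mimic their center's partition.
    # The opposite orientation collapses the centers onto nested
    # high-risk-mass models whose screening fit cannot reproduce the
    # method's detection behavior (see the methods vignette).
    d <- t(tab$distance[keep, keep, drop = FALSE])
    diag(d) <- 0
    km <- globalKMeans(d, k)
    entries[[.bin_key(a, b)]] <- list(
      prototypes = km$prototypes,
      members = oriented[keep],
      assignment = unname(km$assignment),
      withinDistance = km$withinDistance,
      excluded = modelIds[!keep])
  }
  new("PrototypeLibrary", binGrid = as.numeric(bins), entries = entries,
      params = list(k = as.integer(k), prevalence = prevalence,
                    heritability = heritability, sampleRatio = sampleRatio),
      version = .LIBRARY_VERSION)
}

#' @rdname PrototypeLibrary-class
#' @export
setMethod("prototypesFor", "PrototypeLibrary", function(lib, mafA, mafB) {
  a <- assignMafBin(min(mafA, 0.5), lib@binGrid)
  b <- assignMafBin(min(mafB, 0.5), lib@binGrid)
  key <- .bin_key(a, b)
  e <- lib@entries[[key]]
  if (is.null(e))
    stop("library has no entry for bin pair (", key, ")")
  e$prototypes
})

#' @rdname PrototypeLibrary-class
#' @export
setMethod("libraryParams", "PrototypeLibrary", function(lib) lib@params)

setMethod("show", "PrototypeLibrary", function(object) {
  p <- object@params
  cat(sprintf(paste0("PrototypeLibrary (%s): %d bin pairs on grid {%s}, ",
                     "K = %d, P(D) = %g, h2 = %g, r = %g\n"),
              object@version, length(object@entries),
              paste(object@binGrid, collapse = ", "),
              p$k, p$prevalence, p$heritability, p$sampleRatio))
})

#' Read / write a prototype library
#'
#' Libraries are stored as JSON with a stable key order so that rebuilding
#' with identical parameters is byte-identical.
#'
#' @param lib a [`PrototypeLibrary`][PrototypeLibrary-class].
#' @param path file path.
#' @return `readPrototypeLibrary` returns a `PrototypeLibrary`;
#'   `writePrototypeLibrary` returns `path` invisibly.
#' @export
writePrototypeLibrary <- function(lib, path) {
  stopifnot(is(lib, "PrototypeLibrary"))
  obj <- list(version = lib@version, params = lib@params,
              binGrid = lib@binGrid, entries = lib@entries)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writePrototypeLibrary
#' @export
readPrototypeLibrary <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(obj$version) || obj$version != .LIBRARY_VERSION)
    stop("unrecognized library format: ", obj$version)
  grid <- as.numeric(obj$binGrid)
  want <- as.vector(outer(grid, grid, function(a, b)
    paste(as.character(a), as.character(b), sep = ",")))
  missing <- setdiff(want, names(obj$entries))
  if (length(missing))
    stop("library missing entry for bin pair (", missing[1], ")")
  entries <- lapply(obj$entries, function(e) {
    for (f in c("prototypes", "members", "assignment", "excluded"))
      e[[f]] <- as.character(e[[f]])
    e$withinDistance <- as.numeric(e$withinDistance)
    bad <- e$prototypes[!grepl("^[01]{9}$", e$prototypes)]
    if (length(bad)) stop("malformed model id in library: ", bad[1])
    e
  })
  params <- obj$params
  params$k <- as.integer(params$k)
  for (f in c("prevalence", "heritability", "sampleRatio"))
    params[[f]] <- as.numeric(params[[f]])
  new("PrototypeLibrary", binGrid = grid,
      entries = entries, params = params, version = obj$version)
}

#' Classical multidimensional scaling of a model distance matrix
#'
#' Torgerson double-centering embedding into 2 dimensions, for mapping the
#' symmetrized pairwise distances between disease models.
#'
#' @param ds square symmetric distance matrix with zero diagonal.
#' @param k embedding dimension (default 2).
#' @return list with `points` (n x k coordinates, centered),
#'   `varianceExplained` (fraction of the positive eigenvalue mass captured)
#'   and `eigenvalues`.
#' @export
mdsEmbed <- function(ds, k = 2) {
  stopifnot(is.matrix(ds), nrow(ds) == ncol(ds))
  if (max(abs(ds - t(ds))) > 1e-8)
    stop("distance matrix must be symmetric")
  fit <- stats::cmdscale(ds, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  list(points = fit$points,
       varianceExplained = sum(fit$eig[seq_len(k)]) / sum(pos),
       eigenvalues = fit$eig)
}
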