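test_that("MAF bin assignment picks the nearest grid value", {
  expect_equal(assignMafBin(0.068), 0.05)
  expect_equal(assignMafBin(0.182), 0.2)
  expect_equal(assignMafBin(0.45), 0.45)
  # exact midpoints round down to the smaller bin
  expect_equal(assignMafBin(c(0.075, 0.15, 0.25, 0.35, 0.425)),
               c(0.05, 0.1, 0.2, 0.3, 0.4))
  expect_equal(assignMafBin(0), 0.05)
  expect_equal(assignMafBin(0.5), 0.45)
  expect_error(assignMafBin(0.6), "0, 0.5")
})

test_that("global K-means matches an independent re-implementation", {
  set.seed(10)
  for (trial in 1:3) {
    n <- 15
    d <- matrix(runif(n * n, 0.1, 2), n, n)
    diag(d) <- 0
    rownames(d) <- colnames(d) <-
      sample(enumerateNontrivial(ids = TRUE), n)
    km <- globalKMeans(d, 5)
    oracle <- slow_global_kmeans(d, 5)
    expect_identical(km$prototypes, oracle$prototypes)
    expect_equal(km$withinDistance, oracle$withinDistance, tolerance = 1e-9)
    # monotone objective and medoid-first property
    expect_true(all(diff(km$withinDistance) <= 1e-9))
    medoid <- rownames(d)[which.min(rowSums(d))]
    expect_identical(km$prototypes[1], medoid)
    # assignment maps every member to a selected center
    expect_true(all(km$assignment %in% km$prototypes))
  }
  d <- matrix(runif(9), 3, 3); diag(d) <- 0
  expect_error(globalKMeans(d, 4), "between 1")
})

test_that("the default library holds 36 entries of 7 feasible prototypes", {
  lib <- test_library()
  expect_s4_class(lib, "PrototypeLibrary")
  expect_length(lib@entries, 36)
  for (e in lib@entries) {
    expect_length(e$prototypes, 7)
    expect_true(all(grepl("^[01]{9}$", e$prototypes)))
    expect_true(all(e$prototypes %in% e$members))
    expect_true(all(diff(e$withinDistance) <= 1e-9))
    # every clustered member's partition descends from the canonical set
    expect_true(all(vapply(e$members, function(id)
      modelId(canonicalModel(DiseaseModel(id))), "") %in%
        reducedModelSet(ids = TRUE)))
  }
  # only extreme-MAF entries drop partitions, and only a few
  excl <- vapply(lib@entries, function(e) length(e$excluded), 1L)
  expect_true(all(excl[c("0.05,0.05", "0.05,0.1", "0.1,0.05")] > 0))
  expect_true(all(excl <= 5))
  # worked example of the bin lookup on estimated MAFs
  expect_identical(prototypesFor(lib, 0.068, 0.182),
                   lib@entries[["0.05,0.2"]]$prototypes)
})

test_that("rebuilding with identical parameters is deterministic", {
  lib <- test_library()
  lib2 <- buildPrototypeLibrary()
  expect_identical(lib@entries, lib2@entries)
  expect_identical(libraryParams(lib), libraryParams(lib2))
})

test_that("clustering is stable under moderate prevalence/h2 changes", {
  lib <- test_library()
  lib2 <- buildPrototypeLibrary(heritability = 0.04)
  canon <- function(ids) vapply(ids, function(i)
    modelId(canonicalModel(DiseaseModel(i))), "")
  a1 <- stats::setNames(lib@entries[["0.2,0.2"]]$assignment,
                        canon(lib@entries[["0.2,0.2"]]$members))
  a2 <- stats::setNames(lib2@entries[["0.2,0.2"]]$assignment,
                        canon(lib2@entries[["0.2,0.2"]]$members))
  common <- intersect(names(a1), names(a2))
  expect_gt(adjusted_rand(a1[common], a2[common]), 0.5)
})

test_that("library JSON round-trips and rejects malformed files", {
  lib <- test_library()
  path <- withr::local_tempfile(fileext = ".json")
  writePrototypeLibrary(lib, path)
  lib2 <- readPrototypeLibrary(path)
  expect_equal(lib@entries, lib2@entries, tolerance = 1e-12)
  expect_identical(lib@binGrid, lib2@binGrid)
  expect_equal(libraryParams(lib), libraryParams(lib2))
  # rewriting is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  writePrototypeLibrary(lib2, path2)
  expect_identical(readLines(path), readLines(path2))

  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  obj$entries[["0.05,0.05"]] <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), bad)
  expect_error(readPrototypeLibrary(bad), "0.05")

  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  obj$entries[["0.05,0.05"]]$prototypes[1] <- "00101"
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), bad)
  expect_error(readPrototypeLibrary(bad), "malformed")
})

test_that("classical scaling embeds exact configurations and centers output", {
  set.seed(11)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(stats::dist(pts))
  emb <- mdsEmbed(d)
  expect_equal(as.matrix(stats::dist(emb$points)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colMeans(emb$points), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(mdsEmbed(matrix(runif(25), 5, 5)), "symmetric")

  # symmetrized model-distance map at MAF (0.2, 0.2): the planar map
  # captures a recognizable but partial share of the variation
  ctx <- PopulationContext(0.2)
  ids <- reducedModelSet(ids = TRUE)
  d <- distanceMatrix(ctx, ids)
  keep <- !apply(is.na(d), 2, any)
  ds <- (d[keep, keep] + t(d[keep, keep])) / 2
  diag(ds) <- 0
  emb <- mdsEmbed(ds)
  expect_gt(emb$varianceExplained, 0.3)
  expect_lte(emb$varianceExplained, 1)
})
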