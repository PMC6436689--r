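make_dataset <- function(n = 60, p = 6, seed = 14, maf = 0.3) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * p, TRUE, prob = hweProbs(maf)), n, p)
  GenotypeDataset(g, rep(c(1L, 0L), length.out = n))
}

test_that("chi-square test follows the 2x2 conventions", {
  risk <- rep(c(1, 0), each = 50)
  status <- rep(c(1, 0, 1, 0), each = 25)
  expect_equal(chi2Test(risk, status)$chi2, 0)
  # plain Pearson arithmetic: 80 * (900 - 100)^2 / 40^4
  risk <- c(rep(1, 40), rep(0, 40))
  status <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  expect_equal(chi2Test(risk, status, correct = FALSE)$chi2, 20)
  # the continuity-corrected default shrinks the statistic
  expect_equal(chi2Test(risk, status)$chi2,
               80 * (abs(900 - 100) - 40)^2 / 40^4)
  # degenerate margins give 0 / p-value 1
  expect_equal(chi2Test(rep(1, 20), rep(c(1, 0), 10))$chi2, 0)
  expect_equal(chi2Test(rep(1, 20), rep(c(1, 0), 10))$pvalue, 1)
  expect_error(chi2Test(1:3, 1:2), "same length")
})

test_that("chi-square is invariant under complementing the risk vector", {
  set.seed(15)
  for (i in 1:20) {
    risk <- sample(0:1, 80, TRUE)
    status <- sample(0:1, 80, TRUE)
    expect_equal(chi2Test(risk, status)$chi2,
                 chi2Test(1 - risk, status)$chi2)
  }
})

test_that("pair contingency matches a per-individual tally", {
  ds <- make_dataset()
  g <- genotypes(ds)
  g[2, 1] <- NA
  ds <- GenotypeDataset(g, phenotype(ds))
  arr <- pairContingency(ds, 1, 4)
  for (a in 0:2) for (b in 0:2) for (st in 0:1) {
    oracle <- sum(!is.na(g[, 1]) & !is.na(g[, 4]) & g[, 1] == a &
                    g[, 4] == b & phenotype(ds) == st)
    expect_identical(arr[a + 1, b + 1, if (st == 1) "case" else "ctrl"],
                     as.integer(oracle))
  }
  expect_equal(sum(arr), sum(!is.na(g[, 1]) & !is.na(g[, 4])))
  expect_error(pairContingency(ds, 2, 2), "distinct")
})

test_that("MDR thresholds cell ratios at the sample case:control ratio", {
  arr <- array(0L, c(3, 3, 2), dimnames = list(NULL, NULL, c("case", "ctrl")))
  arr[1, 1, ] <- c(10L, 10L)   # ratio exactly 1 -> high risk on balanced data
  arr[2, 2, ] <- c(3L, 9L)     # below threshold -> low risk
  arr[3, 3, ] <- c(4L, 0L)     # cases only -> high risk
  res <- selectModelMdr(arr)
  cells <- modelCells(res$model)
  expect_identical(cells[1, 1], 1L)
  expect_identical(cells[2, 2], 0L)
  expect_identical(cells[3, 3], 1L)
  expect_identical(cells[1, 2], 0L)  # empty cell stays low risk
  # every cell below threshold -> trivial model, statistic 0
  arr[1, 1, ] <- c(1L, 10L); arr[3, 3, ] <- c(1L, 10L)
  expect_equal(selectModelMdr(arr, ratioThreshold = 1)$chi2, 0)
})

test_that("baselines recover a strongly separated generating partition", {
  truth <- DiseaseModel("000011011")
  sim <- analytic_conditional(
    matrix(ifelse(modelCells(truth) == 1, 0.9, 0.01), 3, 3), 0.4, 0.4)
  set.seed(16)
  n <- 5000
  sc <- sample(9, n, TRUE, sim$case); st <- sample(9, n, TRUE, sim$ctrl)
  arr <- array(0L, c(3, 3, 2), dimnames = list(NULL, NULL, c("case", "ctrl")))
  arr[, , "case"] <- matrix(tabulate(sc, 9), 3, 3, byrow = TRUE)
  arr[, , "ctrl"] <- matrix(tabulate(st, 9), 3, 3, byrow = TRUE)
  expect_identical(modelId(selectModelMdr(arr)$model), modelId(truth))
  expect_identical(modelId(selectModelRs(arr)$model), modelId(truth))
})

test_that("ratio-split evaluates 8 nested candidates and keeps the best", {
  set.seed(17)
  for (i in 1:25) {
    arr <- random_contingency()
    res <- selectModelRs(arr)
    expect_true(res$x %in% 1:8)
    # the chosen statistic dominates each of the 8 nested candidates
    caseC <- as.vector(t(arr[, , "case"]))
    ctrlC <- as.vector(t(arr[, , "ctrl"]))
    ratio <- caseC / ctrlC
    ratio[caseC == 0 & ctrlC == 0] <- -Inf
    ord <- order(-ratio)
    for (x in 1:8) {
      risk <- integer(9); risk[ord[1:x]] <- 1L
      a <- sum(risk * caseC); b <- sum(risk * ctrlC)
      stat <- chi2Test(c(rep(1, a + b), rep(0, sum(caseC + ctrlC) - a - b)),
                       c(rep(1, a), rep(0, b),
                         rep(1, sum(caseC) - a), rep(0, sum(ctrlC) - b)))
      expect_lte(stat$chi2, res$chi2 + 1e-9)
    }
  }
})

test_that("prototype selection maximizes over prototypes and transposes", {
  arr <- random_contingency()
  protos <- c("000011011", "010000000", "001010100")
  res <- selectModelPty(arr, protos)
  # asymmetric prototypes contribute their transpose; symmetric ones do not
  cand <- c("000011011", "010000000", "000100000", "001010100")
  stats <- vapply(cand, function(id) {
    caseC <- as.vector(t(arr[, , "case"]))
    ctrlC <- as.vector(t(arr[, , "ctrl"]))
    cells <- as.integer(strsplit(id, "")[[1]])
    a <- sum(cells * caseC); b <- sum(cells * ctrlC)
    chi2Test(c(rep(1, a + b), rep(0, sum(caseC + ctrlC) - a - b)),
             c(rep(1, a), rep(0, b), rep(1, sum(caseC) - a),
               rep(0, sum(ctrlC) - b)))$chi2
  }, 1)
  expect_equal(res$chi2, max(stats))
  expect_error(selectModelPty(arr, character(0)), "empty")
})

test_that("prototype chi-square never exceeds the 510-model brute force", {
  lib <- test_library()
  protos <- lib@entries[["0.3,0.3"]]$prototypes
  set.seed(18)
  for (i in 1:30) {
    arr <- random_contingency(80, 80)
    expect_lte(selectModelPty(arr, protos)$chi2,
               brute_force_chi2(arr) + 1e-9)
  }
})

test_that("marginal screening scores every unordered pair consistently", {
  lib <- test_library()
  ds <- make_dataset(n = 120, p = 8, seed = 19)
  for (m in c("pty", "mdr", "rs")) {
    sc <- marginalScreen(ds, m, library = lib)
    expect_equal(nrow(sc), choose(8, 2))
    expect_true(all(diff(sc$chi2) <= 1e-12))
    expect_true(all(sc$pvalue >= 0 & sc$pvalue <= 1))
    # vectorized engine agrees with the single-pair selectors
    for (k in c(1, 10, 25)) {
      row <- sc[sc$i == sc$i[k] & sc$j == sc$j[k], ][1, ]
      arr <- pairContingency(ds, row$i, row$j)
      single <- switch(m,
        mdr = selectModelMdr(arr, ratioThreshold = 1),
        rs = selectModelRs(arr),
        pty = selectModelPty(arr, prototypesFor(lib,
          controlMaf(ds)[row$i], controlMaf(ds)[row$j])))
      expect_equal(row$chi2, single$chi2, tolerance = 1e-9)
    }
  }
  expect_error(marginalScreen(ds, "pty"), "library")
})

test_that("screening is invariant to SNP column order up to relabeling", {
  lib <- test_library()
  ds <- make_dataset(n = 100, p = 6, seed = 20)
  perm <- c(4, 1, 6, 2, 5, 3)
  dsP <- GenotypeDataset(genotypes(ds)[, perm], phenotype(ds),
                         snpIds = snpIds(ds)[perm])
  for (m in c("pty", "mdr", "rs")) {
    a <- marginalScreen(ds, m, library = lib)
    b <- marginalScreen(dsP, m, library = lib)
    key <- function(x) paste(pmin(x$snp_i, x$snp_j), pmax(x$snp_i, x$snp_j))
    expect_equal(stats::setNames(a$chi2, key(a))[sort(key(a))],
                 stats::setNames(b$chi2, key(b))[sort(key(b))],
                 tolerance = 1e-9)
  }
})

test_that("sequential screening extends the marginal top pair", {
  lib <- test_library()
  ds <- make_dataset(n = 150, p = 10, seed = 21)
  for (m in c("pty", "mdr", "rs")) {
    seq3 <- sequentialScreen(ds, m, nSelect = 3, library = lib)
    marg <- marginalScreen(ds, m, library = lib)
    expect_identical(seq3$i[1], marg$i[1])
    expect_identical(seq3$j[1], marg$j[1])
    expect_equal(seq3$chi2[1], marg$chi2[1])
    keys <- paste(seq3$i, seq3$j)
    expect_identical(anyDuplicated(keys), 0L)
    expect_identical(seq3$round, 1:3)
  }
  expect_error(sequentialScreen(ds, "mdr", nSelect = 100), "between 1")
})

test_that("both pathological two-pair scenarios are detected sequentially", {
  lib <- test_library()
  for (preset in c("ex2.1-1", "ex2.1-2")) {
    for (m in c("pty", "mdr", "rs")) {
      hits <- 0
      for (r in 1:4) {
        set.seed(400 + r)
        ds <- episcreen:::.simulate_preset(scenarioPreset(preset))
        sel <- sequentialScreen(ds, m, nSelect = 2, library = lib)
        hits <- hits + any(sel$i == 3 & sel$j == 4)
      }
      # the stronger pair {C/c, D/d} is found essentially always
      expect_identical(hits, 4)
    }
  }
})

test_that("score files are deterministic and complete", {
  lib <- test_library()
  ds <- make_dataset(n = 80, p = 5, seed = 22)
  sc <- marginalScreen(ds, "mdr")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScores(sc, path)
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(out), choose(5, 2))
  expect_true(all(out$pvalue >= 0 & out$pvalue <= 1))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeScores(marginalScreen(ds, "mdr"), path2)
  expect_identical(readLines(path), readLines(path2))
})
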