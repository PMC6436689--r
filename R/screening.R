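# Chi-square SNP-pair screening with three model-selection methods:
#   PTY — test only the a-priori prototype models (plus their transposes),
#   MDR — one model per pair by thresholding the cell case:control ratios,
#   RS  — 8 nested models from the sorted cell ratios, keep the best.
#
# The engine is vectorized across pairs: per-pair 3x3x2 contingency tables
# for all choose(p, 2) pairs are obtained from 18 cross-products of
# genotype indicator matrices, and every candidate model's chi-square is a
# matrix product of the candidate's 9-cell indicator row with the 9 x nPairs
# count matrices.

# unordered pairs in lexicographic (i asc, j asc) order, with the linear
# index into a p x p matrix for extracting cross-product counts
.pair_index <- function(p) {
  if (p < 2) stop("need at least 2 SNPs")
  i <- rep(seq_len(p - 1), times = (p - 1):1)
  j <- unlist(lapply(seq_len(p - 1), function(a) (a + 1):p))
  list(i = i, j = j, lin = i + (j - 1L) * p)
}

# 9 x nPairs case/control cell counts for all pairs; cell row = 3*gA + gB + 1
# with gA the genotype of the smaller-index SNP.  Individuals missing at
# either SNP of a pair contribute to no cell (complete-case per pair).
.pair_cell_counts <- function(geno, status, rows = NULL) {
  if (!is.null(rows)) {
    geno <- geno[rows, , drop = FALSE]
    status <- status[rows]
  }
  p <- ncol(geno)
  px <- .pair_index(p)
  np <- length(px$lin)
  out <- list()
  for (st in c(1L, 0L)) {
    sub <- geno[status == st, , drop = FALSE]
    Z <- lapply(0:2, function(g) {
      M <- sub == g
      M[is.na(M)] <- FALSE
      storage.mode(M) <- "double"
      M
    })
    counts <- matrix(0, 9, np)
    for (a in 0:2) for (b in 0:2) {
      Tab <- crossprod(Z[[a + 1]], Z[[b + 1]])
      counts[3 * a + b + 1, ] <- Tab[px$lin]
    }
    out[[if (st == 1L) "case" else "ctrl"]] <- counts
  }
  out$pairs <- px
  out
}

# vectorized chi-square of the 2x2 (risk x status) table; continuity
# correction on by default (the package's nominal association measure —
# see the methods vignette); degenerate margins give 0 by convention
.chi2_from_counts <- function(a, b, totCase, totCtrl, correct = TRUE) {
  cc <- totCase - a
  d <- totCtrl - b
  n <- totCase + totCtrl
  den <- (a + b) * (cc + d) * totCase * totCtrl
  dev <- abs(a * d - b * cc)
  if (correct) dev <- pmax(0, dev - n / 2)
  out <- ifelse(den > 0, n * dev^2 / den, 0)
  out[!is.finite(out)] <- 0
  out
}

#' Chi-square independence test of a binary risk assignment
#'
#' Chi-square statistic (1 df) for the 2x2 table of a binary risk
#' assignment against case-control status.  By default the continuity
#' (Yates) correction is applied — this corrected statistic is the nominal
#' association measure used throughout the screening engine; set
#' `correct = FALSE` for the plain Pearson form.  A degenerate margin (all
#' individuals in one risk group, or a single status) gives statistic 0
#' and p-value 1 by convention.
#'
#' @param risk binary (0/1) risk indicator per individual; NA excluded
#'   together with the matching status entry.
#' @param status binary (1 = case, 0 = control) per individual.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list with `chi2` and `pvalue` (upper tail of chi-square with
#'   1 df).
#' @export
chi2Test <- function(risk, status, correct = TRUE) {
  if (length(risk) != length(status))
    stop("risk and status must have the same length")
  keep <- !is.na(risk) & !is.na(status)
  risk <- risk[keep]; status <- status[keep]
  a <- sum(risk == 1 & status == 1)
  b <- sum(risk == 1 & status == 0)
  chi2 <- .chi2_from_counts(a, b, sum(status == 1), sum(status == 0),
                            correct = correct)
  list(chi2 = chi2, pvalue = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Pair contingency table
#'
#' Cross-tabulates the complete cases of one SNP pair: a 3 x 3 x 2 array of
#' counts indexed by the genotype of SNP `i`, the genotype of SNP `j`, and
#' status (`"case"`, `"ctrl"`).
#'
#' @param ds a [`GenotypeDataset`][GenotypeDataset-class].
#' @param i,j distinct SNP indices.
#' @return 3 x 3 x 2 integer array.
#' @export
pairContingency <- function(ds, i, j) {
  stopifnot(is(ds, "GenotypeDataset"))
  if (i == j || i < 1 || j < 1 || i > nSnps(ds) || j > nSnps(ds))
    stop("i and j must be distinct valid SNP indices")
  gA <- ds@genotypes[, i]
  gB <- ds@genotypes[, j]
  keep <- !is.na(gA) & !is.na(gB)
  if (!any(keep)) stop("no complete cases for pair (", i, ", ", j, ")")
  arr <- array(0L, c(3, 3, 2),
               dimnames = list(.GENO_LABELS_A, .GENO_LABELS_B,
                               c("case", "ctrl")))
  for (st in 0:1) {
    rows <- keep & ds@phenotype == st
    tab <- table(factor(gA[rows], levels = 0:2),
                 factor(gB[rows], levels = 0:2))
    arr[, , if (st == 1) "case" else "ctrl"] <- as.integer(tab)
  }
  arr
}

# contingency array -> row-major 9-vectors
.contingency_vectors <- function(contingency) {
  list(case = as.vector(t(contingency[, , "case"])),
       ctrl = as.vector(t(contingency[, , "ctrl"])))
}

# ---- MDR ----------------------------------------------------------------

# 9 x nPairs binary high-risk indicator: cell high iff cases >= threshold *
# controls, with truly empty cells (0 cases, 0 controls) low-risk
.mdr_models <- function(caseC, ctrlC, ratio) {
  H <- (caseC >= ratio * ctrlC) & !(caseC == 0 & ctrlC == 0)
  storage.mode(H) <- "double"
  H
}

#' Model selection for one pair: MDR rule
#'
#' Labels each genotype-combination cell high-risk when its case:control
#' count ratio is at least `ratioThreshold` (cells with cases but no
#' controls are high-risk; empty cells are low-risk), then tests the induced
#' risk assignment against status.
#'
#' @param contingency a 3 x 3 x 2 array from [pairContingency()].
#' @param ratioThreshold case:control ratio cut-off; defaults to the
#'   sample's case:control ratio (the classic "ratio >= 1" rule on balanced
#'   data).
#' @return list with `model` ([`DiseaseModel`][DiseaseModel-class]), `chi2`
#'   and `pvalue`.
#' @export
selectModelMdr <- function(contingency, ratioThreshold = NULL) {
  v <- .contingency_vectors(contingency)
  totCase <- sum(v$case); totCtrl <- sum(v$ctrl)
  if (is.null(ratioThreshold))
    ratioThreshold <- if (totCtrl > 0) totCase / totCtrl else 1
  H <- .mdr_models(cbind(v$case), cbind(v$ctrl), ratioThreshold)
  chi2 <- .chi2_from_counts(sum(H * v$case), sum(H * v$ctrl),
                            totCase, totCtrl)
  list(model = DiseaseModel(matrix(H, 3, 3, byrow = TRUE)), chi2 = chi2,
       pvalue = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# ---- RS -----------------------------------------------------------------

# rank the 9 cells of every pair by descending case:control ratio; empty
# cells rank last; ties break by row-major cell index.  Returns a 9 x
# nPairs matrix of cell orderings.
.rs_rank <- function(caseC, ctrlC) {
  ratio <- caseC / ctrlC                # 0/0 -> NaN, x/0 -> Inf
  ratio[caseC == 0 & ctrlC == 0] <- -Inf
  apply(ratio, 2, function(v) order(-v))  # stable: ties by index asc
}

# chi-square of the 8 nested top-x models given an ordering; aOff/bOff are
# case/control counts forced into the high-risk group (sequential history)
.rs_chi2 <- function(caseC, ctrlC, ord, totCase, totCtrl,
                     aOff = 0, bOff = 0) {
  np <- ncol(caseC)
  lin <- ord + 9 * rep(seq_len(np) - 1L, each = 9)
  sc <- matrix(caseC[lin], 9, np)
  st <- matrix(ctrlC[lin], 9, np)
  A <- apply(sc, 2, cumsum)[1:8, , drop = FALSE]
  B <- apply(st, 2, cumsum)[1:8, , drop = FALSE]
  A <- A + rep(aOff, each = 8)
  B <- B + rep(bOff, each = 8)
  .chi2_from_counts(A, B, rep(totCase, each = 8), rep(totCtrl, each = 8))
}

#' Model selection for one pair: ratio-split rule
#'
#' Sorts the 9 cells by descending case:control ratio (empty cells last,
#' ties by row-major index), forms the 8 nested candidate models that mark
#' the top x cells high-risk (x = 1..8), and keeps the candidate with the
#' largest chi-square; ties go to the smaller x.
#'
#' @inheritParams selectModelMdr
#' @return list with `model`, `chi2`, `pvalue` and `x` (the chosen split).
#' @export
selectModelRs <- function(contingency) {
  v <- .contingency_vectors(contingency)
  caseC <- cbind(v$case); ctrlC <- cbind(v$ctrl)
  totCase <- sum(v$case); totCtrl <- sum(v$ctrl)
  ord <- .rs_rank(caseC, ctrlC)
  chi2 <- .rs_chi2(caseC, ctrlC, ord, totCase, totCtrl)
  x <- which.max(chi2)  # first max -> smallest x on ties
  cells <- integer(9)
  cells[ord[1:x, 1]] <- 1L
  list(model = DiseaseModel(matrix(cells, 3, 3, byrow = TRUE)),
       chi2 = chi2[x],
       pvalue = stats::pchisq(chi2[x], 1, lower.tail = FALSE),
       x = x)
}

# ---- PTY ----------------------------------------------------------------

# candidate rows for a prototype set: each prototype followed by its
# transpose (skipped when symmetric), in library order
.pty_candidates <- function(protoIds) {
  ids <- character(0)
  for (id in protoIds) {
    ids <- c(ids, id)
    tid <- .transpose_id(id)
    if (tid != id) ids <- c(ids, tid)
  }
  ids
}

#' Model selection for one pair: prototype rule
#'
#' Tests every prototype and (for locus-asymmetric prototypes) its
#' transpose, and keeps the candidate with the largest chi-square; ties go
#' to the earlier library entry, untransposed before transposed.
#'
#' @inheritParams selectModelMdr
#' @param prototypes character vector of prototype model ids (the library
#'   entry for this pair's MAF bins).
#' @return list with `model`, `chi2`, `pvalue`.
#' @export
selectModelPty <- function(contingency, prototypes) {
  if (length(prototypes) == 0) stop("prototype list is empty")
  v <- .contingency_vectors(contingency)
  cand <- .pty_candidates(prototypes)
  C <- .model_matrix(cand)
  a <- as.vector(C %*% v$case)
  b <- as.vector(C %*% v$ctrl)
  chi2 <- .chi2_from_counts(a, b, sum(v$case), sum(v$ctrl))
  best <- which.max(chi2)
  list(model = DiseaseModel(cand[best]), chi2 = chi2[best],
       pvalue = stats::pchisq(chi2[best], 1, lower.tail = FALSE))
}

# ---- vectorized per-method engines --------------------------------------

# each returns list(chi2 = numeric nPairs, model = character nPairs)

.screen_mdr <- function(cnt, totCase, totCtrl, ratio) {
  H <- .mdr_models(cnt$case, cnt$ctrl, ratio)
  a <- colSums(H * cnt$case)
  b <- colSums(H * cnt$ctrl)
  chi2 <- .chi2_from_counts(a, b, totCase, totCtrl)
  model <- apply(H, 2, paste, collapse = "")
  list(chi2 = chi2, model = model)
}

.screen_rs <- function(cnt, totCase, totCtrl, ord = NULL,
                       aOff = 0, bOff = 0) {
  if (is.null(ord)) ord <- .rs_rank(cnt$case, cnt$ctrl)
  chi2 <- .rs_chi2(cnt$case, cnt$ctrl, ord, totCase, totCtrl, aOff, bOff)
  best <- max.col(t(chi2), ties.method = "first")
  np <- ncol(cnt$case)
  model <- vapply(seq_len(np), function(q) {
    cells <- integer(9)
    cells[ord[seq_len(best[q]), q]] <- 1L
    paste(cells, collapse = "")
  }, "")
  list(chi2 = chi2[cbind(best, seq_len(np))], model = model, x = best,
       ord = ord)
}

# bins: per-SNP MAF bin values; groups pairs by bin pair and evaluates the
# matching prototype candidates
.screen_pty <- function(cnt, totCase, totCtrl, lib, bins,
                        aOff = 0, bOff = 0) {
  px <- cnt$pairs
  np <- length(px$i)
  keyA <- bins[px$i]
  keyB <- bins[px$j]
  key <- paste(as.character(keyA), as.character(keyB), sep = ",")
  chi2 <- numeric(np)
  model <- character(np)
  if (length(aOff) == 1) aOff <- rep(aOff, np)
  if (length(bOff) == 1) bOff <- rep(bOff, np)
  for (kk in unique(key)) {
    cols <- which(key == kk)
    e <- lib@entries[[kk]]
    if (is.null(e)) stop("library has no entry for bin pair (", kk, ")")
    cand <- .pty_candidates(e$prototypes)
    C <- .model_matrix(cand)
    A <- C %*% cnt$case[, cols, drop = FALSE] +
      rep(aOff[cols], each = nrow(C))
    B <- C %*% cnt$ctrl[, cols, drop = FALSE] +
      rep(bOff[cols], each = nrow(C))
    ch <- .chi2_from_counts(A, B,
                            rep(totCase[cols], each = nrow(C)),
                            rep(totCtrl[cols], each = nrow(C)))
    ch <- matrix(ch, nrow(C))
    best <- max.col(t(ch), ties.method = "first")
    chi2[cols] <- ch[cbind(best, seq_along(cols))]
    model[cols] <- cand[best]
  }
  list(chi2 = chi2, model = model)
}

# dispatch: counts + per-pair totals for the complete cases
.screen_engine <- function(geno, status, method, lib = NULL, bins = NULL) {
  cnt <- .pair_cell_counts(geno, status)
  totCase <- colSums(cnt$case)
  totCtrl <- colSums(cnt$ctrl)
  res <- switch(method,
    mdr = .screen_mdr(cnt, totCase, totCtrl,
                      ratio = sum(status == 1) / sum(status == 0)),
    rs = .screen_rs(cnt, totCase, totCtrl),
    pty = .screen_pty(cnt, totCase, totCtrl, lib, bins))
  res$pairs <- cnt$pairs
  res
}

.check_method <- function(method, library) {
  method <- match.arg(tolower(method), c("pty", "mdr", "rs"))
  if (method == "pty" && is.null(library))
    stop("PTY screening requires a prototype library")
  method
}

.score_frame <- function(ds, px, method, model, chi2, sorted = TRUE) {
  df <- data.frame(snp_i = snpIds(ds)[px$i], snp_j = snpIds(ds)[px$j],
                   method = method, model_id = model, chi2 = chi2,
                   pvalue = stats::pchisq(chi2, 1, lower.tail = FALSE),
                   i = px$i, j = px$j, stringsAsFactors = FALSE)
  if (sorted) {
    df <- df[order(-df$chi2, df$i, df$j), ]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
  }
  df
}

#' Marginal pair screening
#'
#' Scores every unordered SNP pair independently: the method's
#' model-selection rule picks a disease model for the pair, and the pair's
#' nominal association is the chi-square (1 df) of the induced risk
#' assignment against status.  Pairs are returned ranked by chi-square
#' (ties by SNP indices).
#'
#' @param ds a [`GenotypeDataset`][GenotypeDataset-class].
#' @param method `"pty"`, `"mdr"` or `"rs"`.
#' @param library a [`PrototypeLibrary`][PrototypeLibrary-class]; required
#'   for PTY.  Prototype sets are chosen per pair from the control-sample
#'   MAFs via [assignMafBin()].
#' @return a data.frame with columns `snp_i`, `snp_j`, `method`,
#'   `model_id`, `chi2`, `pvalue`, `i`, `j`, `rank`.
#' @export
marginalScreen <- function(ds, method = c("pty", "mdr", "rs"),
                           library = NULL) {
  stopifnot(is(ds, "GenotypeDataset"))
  method <- .check_method(method[1], library)
  if (nSnps(ds) < 2) stop("need at least 2 SNPs")
  bins <- if (method == "pty")
    assignMafBin(controlMaf(ds), library@binGrid) else NULL
  res <- .screen_engine(ds@genotypes, ds@phenotype, method, library, bins)
  .score_frame(ds, res$pairs, method, res$model, res$chi2)
}

#' Sequential pair screening
#'
#' Selects pairs one at a time.  The first selection is the marginal top
#' pair.  Afterwards, every unselected pair is re-assessed by the
#' chi-square of the elementwise OR of the accumulated high-risk assignment
#' (the history) with the candidate pair's risk assignment; each method
#' re-chooses the candidate's model per round to maximize that conditional
#' chi-square (MDR's model is ratio-determined and does not change).
#'
#' @inheritParams marginalScreen
#' @param nSelect number of pairs to select.
#' @param refitModels if `FALSE`, rounds after the first reuse each pair's
#'   marginally chosen model instead of re-optimizing it.
#' @return a data.frame as in [marginalScreen()] with one row per selection
#'   and a `round` column; `chi2`/`pvalue` are conditional on the history.
#' @export
sequentialScreen <- function(ds, method = c("pty", "mdr", "rs"), nSelect,
                             library = NULL, refitModels = TRUE) {
  stopifnot(is(ds, "GenotypeDataset"))
  method <- .check_method(method[1], library)
  geno <- ds@genotypes
  status <- ds@phenotype
  px <- .pair_index(ncol(geno))
  np <- length(px$i)
  if (nSelect < 1 || nSelect > np)
    stop("nSelect must be between 1 and the number of pairs")
  bins <- if (method == "pty")
    assignMafBin(controlMaf(ds), library@binGrid) else NULL
  full <- .pair_cell_counts(geno, status)
  fullTotCase <- colSums(full$case)
  fullTotCtrl <- colSums(full$ctrl)
  ratio <- sum(status == 1) / sum(status == 0)
  mdrFixed <- if (method == "mdr")
    .screen_mdr(full, fullTotCase, fullTotCtrl, ratio) else NULL
  rsOrd <- if (method == "rs") .rs_rank(full$case, full$ctrl) else NULL
  marginalFit <- if (!refitModels && method != "mdr")
    .screen_engine(geno, status, method, library, bins) else NULL

  hist_risk <- rep(FALSE, nrow(geno))
  selected <- integer(0)
  rows <- list()
  for (round in seq_len(nSelect)) {
    if (round == 1) {
      cnt <- full
      aOff <- rep(0, np); bOff <- rep(0, np)
    } else {
      cnt <- .pair_cell_counts(geno, status, rows = which(!hist_risk))
      aOff <- rep(sum(status == 1 & hist_risk), np)
      bOff <- rep(sum(status == 0 & hist_risk), np)
    }
    totCase <- colSums(cnt$case) + aOff
    totCtrl <- colSums(cnt$ctrl) + bOff
    if (method == "mdr" || (!refitModels && round > 1)) {
      fixed <- if (method == "mdr") mdrFixed else marginalFit
      C <- .model_matrix(fixed$model)           # np x 9
      a <- rowSums(C * t(cnt$case)) + aOff
      b <- rowSums(C * t(cnt$ctrl)) + bOff
      chi2 <- .chi2_from_counts(a, b, totCase, totCtrl)
      model <- fixed$model
    } else if (method == "rs") {
      res <- .screen_rs(cnt, totCase, totCtrl, ord = rsOrd,
                        aOff = aOff, bOff = bOff)
      chi2 <- res$chi2; model <- res$model
    } else {  # pty (refit) or round-1 rs/pty
      res <- switch(method,
        pty = .screen_pty(cnt, totCase, totCtrl, library, bins, aOff, bOff),
        rs = .screen_rs(cnt, totCase, totCtrl, ord = rsOrd,
                        aOff = aOff, bOff = bOff))
      chi2 <- res$chi2; model <- res$model
    }
    chi2[selected] <- -Inf
    pick <- order(-chi2, px$i, px$j)[1]
    selected <- c(selected, pick)
    rv <- riskVector(DiseaseModel(model[pick]),
                     geno[, px$i[pick]], geno[, px$j[pick]])
    hist_risk <- hist_risk | (!is.na(rv) & rv == 1L)
    rows[[round]] <- data.frame(
      snp_i = snpIds(ds)[px$i[pick]], snp_j = snpIds(ds)[px$j[pick]],
      method = method, model_id = model[pick], chi2 = chi2[pick],
      pvalue = stats::pchisq(chi2[pick], 1, lower.tail = FALSE),
      i = px$i[pick], j = px$j[pick], round = round,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write ranked pair scores
#'
#' Tab-separated output of a screening result, in its existing
#' (deterministic) row order.
#'
#' @param scores data.frame from [marginalScreen()] or
#'   [sequentialScreen()].
#' @param path output file.
#' @export
writeScores <- function(scores, path) {
  keep <- intersect(c("snp_i", "snp_j", "method", "model_id", "chi2",
                      "pvalue", "rank", "round"), names(scores))
  utils::write.table(scores[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
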