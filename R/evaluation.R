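# Scoring and replicated-experiment drivers: F-measure, Bonferroni
# thresholds, null-inflation summaries and Q-Q diagnostics.

#' F-measure of a detection result
#'
#' With a single true causal pair, precision is `1 / #detected` when the
#' true pair is among the detected pairs and 0 otherwise; recall is the
#' detection indicator.  The F-measure is their harmonic mean (0 for an
#' empty detected set).
#'
#' @param detected two-column matrix/data.frame of detected SNP index
#'   pairs (unordered), possibly with zero rows.
#' @param truePair length-2 vector, the causal pair's indices.
#' @return F in [0, 1].
#' @export
fMeasure <- function(detected, truePair) {
  detected <- as.matrix(detected)
  if (nrow(detected) == 0) return(0)
  norm <- cbind(pmin(detected[, 1], detected[, 2]),
                pmax(detected[, 1], detected[, 2]))
  hit <- any(norm[, 1] == min(truePair) & norm[, 2] == max(truePair))
  if (!hit) return(0)
  precision <- 1 / nrow(norm)
  2 * precision / (precision + 1)
}

#' Bonferroni significance threshold
#'
#' `alpha / nPairs / nModels`: the easy threshold corrects for the number
#' of pairs only; setting `nModels = 8` additionally corrects for the 8
#' candidate models the ratio-split rule always evaluates.
#'
#' @param alpha familywise level, in (0, 1).
#' @param nPairs number of SNP pairs tested.
#' @param nModels candidate disease models per pair (default 1).
#' @export
bonferroniThreshold <- function(alpha, nPairs, nModels = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nPairs < 1 || nModels < 1) stop("counts must be >= 1")
  alpha / nPairs / nModels
}

#' Mean nominal chi-square of a screening result
#'
#' The null-inflation summary: the arithmetic mean of the per-pair nominal
#' chi-square statistics.
#'
#' @param scores data.frame from [marginalScreen()] (or any data.frame
#'   with a `chi2` column), or a numeric vector of statistics.
#' @export
meanChi2 <- function(scores) {
  x <- if (is.data.frame(scores)) scores$chi2 else scores
  if (length(x) == 0) stop("no scores")
  mean(x)
}

#' Q-Q points against the chi-square(1) reference
#'
#' @param scores as in [meanChi2()].
#' @return data.frame with `theoretical` (chi-square(1) quantiles at
#'   `(k - 0.5) / m`) and `observed` (sorted statistics).
#' @export
qqPoints <- function(scores) {
  x <- if (is.data.frame(scores)) scores$chi2 else scores
  if (length(x) == 0) stop("no scores")
  m <- length(x)
  data.frame(theoretical = stats::qchisq((seq_len(m) - 0.5) / m, df = 1),
             observed = sort(x))
}

.sorted_pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

#' Replicated screening experiment
#'
#' Runs simulate-screen-score for `reps` replications of a preset (see
#' [scenarioPreset()]), seeding replication r with `baseSeed + r`, and
#' aggregates the appropriate metric: the F-measure at threshold `alpha`
#' for marginal screening of a one-pair scenario, top-`nSelect` detection
#' counts for sequential screening, or the mean nominal chi-square for
#' null scenarios.  Several methods can be evaluated on the same simulated
#' data by passing a vector.
#'
#' @param preset a preset name or the list returned by [scenarioPreset()].
#' @param methods character vector among `"pty"`, `"mdr"`, `"rs"`.
#' @param procedure `"marginal"` or `"sequential"`.
#' @param reps number of replications.
#' @param alpha significance threshold on the nominal p-value (marginal
#'   F-measure experiments).
#' @param nSelect selections per replication (sequential experiments).
#' @param baseSeed integer; replication r uses seed `baseSeed + r`.
#' @param library [`PrototypeLibrary`][PrototypeLibrary-class] (required
#'   when `"pty"` is among the methods).
#' @return an object of class `ExperimentSummary`: a list with `summary`
#'   (data.frame: preset, method, metric, mean, se, reps), `perRep`
#'   (replication x method matrix of metric values), `seeds`, and for
#'   sequential runs `selectionCounts` (per-method tables of how often
#'   each pair was among the selections) and `truthCounts`.
#' @export
replicateExperiment <- function(preset, methods = "pty",
                                procedure = c("marginal", "sequential"),
                                reps = 100, alpha = NULL, nSelect = 2,
                                baseSeed = 1, library = NULL) {
  procedure <- match.arg(procedure)
  if (is.character(preset)) preset <- scenarioPreset(preset)
  methods <- vapply(methods, .check_method, "", library = library,
                    USE.NAMES = FALSE)
  if (reps < 1) stop("reps must be >= 1")
  isNull <- isTRUE(preset$null)
  metric <- if (isNull) "meanChi2"
            else if (procedure == "sequential") "top2detect"
            else "fMeasure"
  if (metric == "fMeasure") {
    if (is.null(alpha)) stop("marginal F-measure experiments need alpha")
    if (length(preset$truth) != 1)
      stop("the F-measure is defined for a single true pair")
  }
  perRep <- matrix(NA_real_, reps, length(methods),
                   dimnames = list(NULL, methods))
  seeds <- baseSeed + seq_len(reps)
  selCount <- lapply(methods, function(m) list())
  names(selCount) <- methods
  truthCounts <- NULL
  if (procedure == "sequential" && !is.null(preset$truth)) {
    truthCounts <- matrix(0L, length(preset$truth), length(methods),
                          dimnames = list(vapply(preset$truth, paste,
                                                 "", collapse = "-"),
                                          methods))
  }
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    ds <- .simulate_preset(preset)
    for (m in methods) {
      if (procedure == "marginal") {
        sc <- marginalScreen(ds, m, library = library)
        perRep[r, m] <- if (isNull) meanChi2(sc) else {
          det <- sc[sc$pvalue < alpha, c("i", "j"), drop = FALSE]
          fMeasure(det, preset$truth[[1]])
        }
      } else {
        sel <- sequentialScreen(ds, m, nSelect = nSelect,
                                library = library)
        keys <- .sorted_pair_key(sel$i, sel$j)
        for (k in keys)
          selCount[[m]][[k]] <- (selCount[[m]][[k]] %||% 0L) + 1L
        if (!is.null(preset$truth)) {
          tk <- vapply(preset$truth, paste, "", collapse = "-")
          hits <- tk %in% keys
          truthCounts[, m] <- truthCounts[, m] + hits
          perRep[r, m] <- sum(hits)
        }
      }
    }
  }
  summ <- data.frame(
    preset = preset$name %||% "custom", method = methods, metric = metric,
    mean = colMeans(perRep),
    se = if (reps > 1) apply(perRep, 2, stats::sd) / sqrt(reps)
         else rep(0, length(methods)),
    reps = reps, row.names = NULL, stringsAsFactors = FALSE)
  out <- list(summary = summ, perRep = perRep, seeds = seeds,
              metric = metric, preset = preset$name %||% "custom",
              procedure = procedure)
  if (procedure == "sequential") {
    out$selectionCounts <- lapply(selCount, function(x) {
      v <- unlist(x)
      if (is.null(v)) integer(0) else sort(v, decreasing = TRUE)
    })
    out$truthCounts <- truthCounts
  }
  class(out) <- "ExperimentSummary"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ExperimentSummary <- function(x, ...) {
  cat(sprintf("Replicated experiment: preset %s, %s procedure, %d reps\n",
              x$preset, x$procedure, nrow(x$perRep)))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$truthCounts)) {
    cat("detections of the true pair(s):\n")
    print(x$truthCounts)
  }
  invisible(x)
}

#' Write an experiment summary as TSV
#'
#' @param x an `ExperimentSummary`.
#' @param path output file.
#' @export
writeSummary <- function(x, path) {
  utils::write.table(x$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
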