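# Shared fixtures and independent oracles for the test suite.

.cache <- new.env(parent = emptyenv())

# default prototype library, built once per test run
test_library <- function() {
  if (is.null(.cache$lib)) .cache$lib <- buildPrototypeLibrary()
  .cache$lib
}

# independent straightforward re-implementation of the incremental greedy
# clustering (used as an oracle for globalKMeans)
slow_global_kmeans <- function(dist, k) {
  ids <- rownames(dist)
  centers <- character(0)
  wss <- numeric(0)
  for (step in seq_len(k)) {
    cand <- sort(setdiff(ids, centers))
    totals <- vapply(cand, function(ci) {
      cen <- c(centers, ci)
      sum(vapply(ids, function(m)
        min(vapply(cen, function(cc) dist[cc, m], 1)), 1))
    }, 1)
    best <- cand[which(totals <= min(totals) + 1e-12)][1]
    centers <- c(centers, best)
    wss <- c(wss, min(totals))
  }
  list(prototypes = centers, withinDistance = wss)
}

# exact conditional genotype-state distribution for a single causal pair
analytic_conditional <- function(pen, mafA, mafB) {
  pA <- hweProbs(mafA); pB <- hweProbs(mafB)
  prior <- as.vector(t(outer(pA, pB)))
  pv <- as.vector(t(pen))
  pd <- sum(prior * pv)
  list(case = prior * pv / pd, ctrl = prior * (1 - pv) / (1 - pd),
       prevalence = pd)
}

# brute-force best chi-square over all 510 non-trivial models for a
# contingency array (oracle for the PTY upper bound)
brute_force_chi2 <- function(contingency) {
  caseC <- as.vector(t(contingency[, , "case"]))
  ctrlC <- as.vector(t(contingency[, , "ctrl"]))
  best <- 0
  for (m in enumerateNontrivial(ids = TRUE)) {
    cells <- as.integer(strsplit(m, "")[[1]])
    a <- sum(cells * caseC); b <- sum(cells * ctrlC)
    risk <- c(rep(1, a + b), rep(0, sum(caseC) + sum(ctrlC) - a - b))
    status <- c(rep(1, a), rep(0, b), rep(1, sum(caseC) - a),
                rep(0, sum(ctrlC) - b))
    best <- max(best, chi2Test(risk, status)$chi2)
  }
  best
}

# random contingency array with given totals
random_contingency <- function(nCase = 100, nCtrl = 100) {
  arr <- array(0L, c(3, 3, 2), dimnames = list(NULL, NULL, c("case", "ctrl")))
  arr[, , "case"] <- matrix(as.vector(stats::rmultinom(1, nCase, rep(1, 9))),
                            3, 3, byrow = TRUE)
  arr[, , "ctrl"] <- matrix(as.vector(stats::rmultinom(1, nCtrl, rep(1, 9))),
                            3, 3, byrow = TRUE)
  arr
}

# Monte-Carlo oracle for the phi metric: retrospective case-control sample,
# empirical phi of the two risk assignments; returns estimate and MC se
mc_phi <- function(mProto, mTrue, ctx, nCtrl = 2e5, reps = 3) {
  pA <- hweProbs(ctx@mafA); pB <- hweProbs(ctx@mafB)
  p <- as.vector(t(outer(pA, pB)))
  kT <- as.integer(t(modelCells(mTrue)))
  kP <- as.integer(t(modelCells(mProto)))
  pen <- solvePenetrance(sum(p[kT == 1]), ctx@prevalence, ctx@heritability)
  pv <- ifelse(kT == 1, pen$p1, pen$p0)
  pd <- sum(p * pv)
  vals <- replicate(reps, {
    sc <- sample(9, round(ctx@sampleRatio * nCtrl), TRUE, p * pv / pd)
    st <- sample(9, nCtrl, TRUE, p * (1 - pv) / (1 - pd))
    s <- c(sc, st)
    rT <- kT[s]; rP <- kP[s]
    phiEmpirical(as.numeric(sum(rT == 1 & rP == 1)),
                 as.numeric(sum(rT == 1 & rP == 0)),
                 as.numeric(sum(rT == 0 & rP == 1)),
                 as.numeric(sum(rT == 0 & rP == 0)))
  })
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(reps))
}

# adjusted Rand index of two labelings
adjusted_rand <- function(x, y) {
  ct <- table(x, y)
  n <- sum(ct)
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  sij <- sum(choose(ct, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# exact case-control ratio per pair-1 genotype combination in a two-pair
# joint-penetrance scenario (for the pathological equal-ratio property)
pair1_case_control_ratios <- function(joint, maf1, maf2) {
  w <- as.vector(t(outer(hweProbs(maf1), hweProbs(maf1))))
  v <- as.vector(t(outer(hweProbs(maf2), hweProbs(maf2))))
  caseMass <- numeric(9); ctrlMass <- numeric(9)
  for (i in 1:9) {
    caseMass[i] <- sum(w[i] * v * joint[i, ])
    ctrlMass[i] <- sum(w[i] * v * (1 - joint[i, ]))
  }
  caseMass / ctrlMass
}
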