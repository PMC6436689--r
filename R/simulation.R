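# Case-control simulation harness: HWE genotypes, penetrance- and
# odds-parameterized two-locus disease models calibrated to prevalence and
# heritability, two-pair joint scenarios, and pure-null data.
#
# Sampling is retrospective: the distribution of the causal genotypes
# conditional on case/control status is computed exactly by Bayes' rule
# over the 9 (one causal pair) or 81 (two causal pairs) genotype states
# with HWE priors, and the causal genotypes are drawn from it; noise SNPs
# are drawn independently from HWE for every individual.

#' Prevalence and heritability of a penetrance table
#'
#' Under HWE at the given MAFs, `prevalence = sum_i P(D|G_i) P(G_i)` and
#' `h2 = sum_i (P(D|G_i) - P(D))^2 P(G_i) / (P(D) (1 - P(D)))`.
#'
#' @param pen 3x3 penetrance table (rows = SNP-A minor-allele count).
#' @param mafA,mafB minor-allele frequencies.
#' @return list with `prevalence` and `h2`.
#' @export
prevalenceAndH2 <- function(pen, mafA, mafB = mafA) {
  pen <- as.vector(t(pen))
  if (length(pen) != 9 || any(pen < 0 | pen > 1))
    stop("pen must be a 3x3 table of penetrances in [0, 1]")
  if (all(pen == 0))
    stop("constant-zero penetrance table: heritability undefined")
  p <- .cell_probs(mafA, mafB)
  prev <- sum(pen * p)
  h2 <- sum((pen - prev)^2 * p) / (prev * (1 - prev))
  list(prevalence = prev, h2 = h2)
}

# odds-table exponents per family, row-major; odds = alpha * (1 + theta)^e
.ODDS_EXPONENTS <- list(
  T   = c(0, 0, 0, 0, 0, 1, 0, 1, 1),
  DD  = c(0, 0, 0, 0, 1, 1, 0, 1, 1),
  MOD = c(0, 0, 0, 0, 0, 1, 1, 1, 1),
  XOR = c(0, 0, 1, 0, 0, 1, 1, 1, 0),
  ME  = c(0, 1, 2, 1, 2, 3, 2, 3, 4),
  MET = c(0, 0, 0, 0, 1, 2, 0, 2, 4))

.odds_penetrance <- function(family, alpha, theta) {
  e <- .ODDS_EXPONENTS[[family]]
  odds <- alpha * (1 + theta)^e
  matrix(odds / (1 + odds), 3, 3, byrow = TRUE)
}

#' Calibrate an odds-parameterized disease model
#'
#' The six main-effect model families (T, DD, MOD, XOR, ME, MET) specify
#' cell odds `alpha * (1 + theta)^e` with family-specific exponents; the
#' penetrance of a cell is odds/(1 + odds).  Given the MAF (common to both
#' SNPs), prevalence and heritability, `alpha > 0` and `theta > 0` are
#' determined by root-finding so the implied penetrance table reproduces
#' both to 1e-8.
#'
#' @param family one of `"T"`, `"DD"`, `"MOD"`, `"XOR"`, `"ME"`, `"MET"`.
#' @param maf minor-allele frequency of both SNPs.
#' @param prevalence,h2 targets.
#' @return list with `family`, `alpha`, `theta` and the 3x3 `penetrance`
#'   table.
#' @export
solveAlphaTheta <- function(family, maf, prevalence, h2) {
  family <- match.arg(family, names(.ODDS_EXPONENTS))
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (h2 < 0) stop("h2 must be >= 0")
  if (h2 == 0)
    return(list(family = family, alpha = prevalence / (1 - prevalence),
                theta = 0,
                penetrance = .odds_penetrance(family,
                                              prevalence / (1 - prevalence),
                                              0)))
  alpha_for <- function(theta) {
    f <- function(la)
      prevalenceAndH2(.odds_penetrance(family, exp(la), theta),
                      maf)$prevalence - prevalence
    stats::uniroot(f, c(-40, 10), tol = 1e-14)$root
  }
  h2_at <- function(theta) {
    la <- alpha_for(theta)
    prevalenceAndH2(.odds_penetrance(family, exp(la), theta), maf)$h2 - h2
  }
  upper <- 1
  while (h2_at(upper) < 0) {
    upper <- upper * 4
    if (upper > 1e8)
      stop(sprintf("no theta reaches h2 = %g for family %s at MAF %g",
                   h2, family, maf))
  }
  theta <- stats::uniroot(h2_at, c(1e-10, upper), tol = 1e-12)$root
  alpha <- exp(alpha_for(theta))
  pen <- .odds_penetrance(family, alpha, theta)
  chk <- prevalenceAndH2(pen, maf)
  if (abs(chk$prevalence - prevalence) > 1e-8 || abs(chk$h2 - h2) > 1e-8)
    stop(sprintf("calibration failed for family %s at MAF %g", family, maf))
  list(family = family, alpha = alpha, theta = theta, penetrance = pen)
}

#' Pathological fourth penetrance level
#'
#' In the two-pair scenario where each genotype combination of each pair is
#' either risky or not and the four penetrance levels are `p_kl` (k, l =
#' whether the first/second pair's combination is risky), the case-control
#' ratio is constant over the first pair's combinations exactly when
#' `p11 = p01 - (sum_N v / sum_R v) (p10 - p00)`, where `v` are the HWE
#' probabilities of the second pair's combinations split by its model's
#' risky set.
#'
#' @param p10,p01,p00 the other three penetrance levels, in [0, 1].
#' @param model2 the second pair's [`DiseaseModel`][DiseaseModel-class].
#' @param maf MAF of both SNPs of the second pair.
#' @return the implied `p11`.
#' @export
pathologicalP11 <- function(p10, p01, p00, model2, maf) {
  stopifnot(is(model2, "DiseaseModel"))
  if (any(c(p10, p01, p00) < 0 | c(p10, p01, p00) > 1))
    stop("penetrances must lie in [0, 1]")
  if (isTrivial(model2)) stop("model2 must be non-trivial")
  v <- .cell_probs(maf, maf)
  risky <- as.integer(t(model2@cells)) == 1L
  vR <- sum(v[risky])
  if (vR <= 0) stop("second pair's risky set has zero probability mass")
  p11 <- p01 - (sum(v[!risky]) / vR) * (p10 - p00)
  if (p11 < 0 || p11 > 1)
    stop(sprintf("implied p11 = %.4g lies outside [0, 1]", p11))
  p11
}

#' Joint penetrance of two independently acting pairs
#'
#' Independent-mechanism union: an individual escapes disease only by
#' escaping both mechanisms, so `joint(g1, g2) = 1 - (1 - pen1(g1)) *
#' (1 - pen2(g2))`.
#'
#' @param pen1,pen2 3x3 penetrance tables.
#' @return 9 x 9 joint penetrance matrix (rows = first pair's combination,
#'   row-major; columns = second pair's).
#' @export
combineIndependent <- function(pen1, pen2) {
  v1 <- as.vector(t(pen1)); v2 <- as.vector(t(pen2))
  if (any(c(v1, v2) < 0 | c(v1, v2) > 1))
    stop("penetrances must lie in [0, 1]")
  1 - outer(1 - v1, 1 - v2)
}

# exact P(causal state | case) and P(state | control).
# For one causal pair: states are the 9 combinations row-major; for two:
# 81 states, state = 9 * (s1 - 1) + s2.
.conditional_state_probs <- function(prior, pen) {
  pd <- sum(prior * pen)
  if (pd <= 0) stop("penetrance is identically zero: no cases can arise")
  if (pd >= 1) stop("penetrance is identically one: no controls can arise")
  list(case = prior * pen / pd, ctrl = prior * (1 - pen) / (1 - pd),
       prevalence = pd)
}

# prior over causal states and the per-state penetrance for a causal spec
.causal_states <- function(causal) {
  if (causal$type == "pair") {
    prior <- .cell_probs(causal$mafA, causal$mafB)
    pen <- as.vector(t(causal$penetrance))
    list(prior = prior, pen = pen, nPairs = 1)
  } else if (causal$type == "twoPair") {
    w <- .cell_probs(causal$maf1A, causal$maf1B)
    v <- .cell_probs(causal$maf2A, causal$maf2B)
    joint <- causal$joint  # 9 x 9, rows = pair 1 state
    prior <- as.vector(t(outer(w, v)))    # state = 9*(s1-1)+s2
    pen <- as.vector(t(joint))
    list(prior = prior, pen = pen, nPairs = 2)
  } else stop("unknown causal type: ", causal$type)
}

# state index -> minor-allele counts of the causal SNPs
.state_genotypes <- function(states, nPairs) {
  if (nPairs == 1) {
    s <- states - 1L
    cbind(s %/% 3L, s %% 3L)
  } else {
    s <- states - 1L
    s1 <- s %/% 9L; s2 <- s %% 9L
    cbind(s1 %/% 3L, s1 %% 3L, s2 %/% 3L, s2 %% 3L)
  }
}

.sample_hwe_matrix <- function(n, mafs) {
  vapply(mafs, function(q)
    sample(0:2, n, replace = TRUE, prob = hweProbs(q)), integer(n))
}

#' Simulate a case-control dataset with a causal SNP block
#'
#' Draws the causal genotypes from their exact conditional distribution
#' given status (retrospective sampling) and all noise SNPs independently
#' from HWE.  The causal SNPs occupy the first columns.
#'
#' @param nCases,nControls sample sizes.
#' @param nSnps total number of SNPs (causal + noise).
#' @param causal causal-block description: either
#'   `list(type = "pair", penetrance = 3x3, mafA, mafB)` or
#'   `list(type = "twoPair", joint = 9x9, maf1A, maf1B, maf2A, maf2B)`.
#' @param noiseMaf either a single MAF for all noise SNPs or a length-2
#'   range from which each noise SNP's MAF is drawn uniformly.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return a [`GenotypeDataset`][GenotypeDataset-class]; cases first.
#' @export
simulateDataset <- function(nCases, nControls, nSnps, causal,
                            noiseMaf = 0.3, seed = NULL) {
  if (nCases < 1 || nControls < 1) stop("need at least one case and control")
  if (!is.null(seed)) set.seed(seed)
  cs <- .causal_states(causal)
  cond <- .conditional_state_probs(cs$prior, cs$pen)
  nCausal <- 2 * cs$nPairs
  if (nSnps < nCausal) stop("nSnps smaller than the causal block")
  stCase <- sample(length(cs$prior), nCases, replace = TRUE,
                   prob = cond$case)
  stCtrl <- sample(length(cs$prior), nControls, replace = TRUE,
                   prob = cond$ctrl)
  causalGeno <- .state_genotypes(c(stCase, stCtrl), cs$nPairs)
  n <- nCases + nControls
  nNoise <- nSnps - nCausal
  noiseMafs <- if (length(noiseMaf) == 2)
    stats::runif(nNoise, noiseMaf[1], noiseMaf[2]) else rep(noiseMaf, nNoise)
  noise <- if (nNoise > 0) .sample_hwe_matrix(n, noiseMafs) else NULL
  geno <- cbind(causalGeno, noise)
  colnames(geno) <- paste0("SNP", seq_len(nSnps))
  GenotypeDataset(geno, c(rep(1L, nCases), rep(0L, nControls)))
}

#' Simulate a pure-null dataset
#'
#' All SNPs are drawn from HWE at the given MAF and the phenotype (half
#' cases, half controls) is assigned independently of every genotype.
#'
#' @param maf MAF of all SNPs.
#' @param n total sample size (cases = `ceiling(n/2)`).
#' @param nSnps number of SNPs.
#' @param seed optional integer seed.
#' @return a [`GenotypeDataset`][GenotypeDataset-class].
#' @export
nullDataset <- function(maf, n, nSnps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- .sample_hwe_matrix(n, rep(maf, nSnps))
  colnames(geno) <- paste0("SNP", seq_len(nSnps))
  nCases <- ceiling(n / 2)
  GenotypeDataset(geno, c(rep(1L, nCases), rep(0L, n - nCases)))
}
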