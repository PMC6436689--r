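# The directional phi-based distance between disease models.
#
# The similarity of a prototype model M' to a true model M is the
# phi-coefficient of the 2x2 cross-classification of individuals into
# high/low risk by the two models, computed for an idealized case-control
# sample: under Hardy-Weinberg equilibrium the genotype-combination
# probabilities P(G_i) give joint weights W_kl (k = M's assignment,
# l = M''s), the true model's two penetrance levels (P1, P0) follow from
# prevalence and heritability, and the sampling design enters through
#   U = r P1 (1 - P(D)) + (1 - P1) P(D)
#   V = r P0 (1 - P(D)) + (1 - P0) P(D),
# the relative weights that a case-control sample at ratio r places on the
# risky and non-risky rows.  Then
#   Phi(M', M) = (W11 W00 - W10 W01) /
#                sqrt( ((U/V) W11 + W01) (W10 + (V/U) W00) W1. W0. )
# and d(M', M) = 1 - Phi(M', M), a directional distance.

# weights below this are treated as exactly zero (catastrophic-cancellation
# guard in the denominator)
.W_FLOOR <- 1e-15

#' @rdname PopulationContext-class
#' @param mafA,mafB minor-allele frequencies in (0, 0.5].
#' @param prevalence disease prevalence P(D); default 0.02.
#' @param heritability heritability h^2; default 0.02.
#' @param sampleRatio cases per control in the sample; default 1 (balanced).
#' @export
PopulationContext <- function(mafA, mafB = mafA, prevalence = 0.02,
                              heritability = 0.02, sampleRatio = 1) {
  new("PopulationContext", mafA = mafA, mafB = mafB,
      prevalence = prevalence, heritability = heritability,
      sampleRatio = sampleRatio)
}

#' @rdname PopulationContext-class
#' @export
setMethod("populationRatio", "PopulationContext", function(ctx)
  ctx@prevalence / (1 - ctx@prevalence))

setMethod("show", "PopulationContext", function(object) {
  cat(sprintf(paste0("PopulationContext: MAF = (%g, %g), P(D) = %g, ",
                     "h2 = %g, r = %g (r0 = %.4g)\n"),
              object@mafA, object@mafB, object@prevalence,
              object@heritability, object@sampleRatio,
              populationRatio(object)))
})

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf minor-allele frequency q in (0, 0.5].
#' @return numeric vector `c((1-q)^2, 2q(1-q), q^2)` — the probabilities of
#'   carrying 0, 1 and 2 copies of the minor allele.
#' @export
hweProbs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) ||
      maf <= 0 || maf > 0.5)
    stop("maf must be a single frequency in (0, 0.5]")
  q <- maf
  c(p0 = (1 - q)^2, p1 = 2 * q * (1 - q), p2 = q^2)
}

# P(G_i) for the 9 genotype combinations, row-major (3*countA + countB + 1)
.cell_probs <- function(mafA, mafB) {
  as.vector(t(outer(hweProbs(mafA), hweProbs(mafB))))
}

#' Joint weights of two disease models
#'
#' Cross-classifies the nine genotype combinations by the true model `mTrue`
#' (index k) and the prototype `mProto` (index l) and sums the HWE
#' probabilities: `W_kl = sum over cells with mTrue = k, mProto = l of
#' P(G_i)`.
#'
#' @param mTrue,mProto [`DiseaseModel`][DiseaseModel-class] objects.
#' @param mafA,mafB minor-allele frequencies of the two SNPs.
#' @return named list with `w11`, `w10`, `w01`, `w00` and the margins
#'   `w1dot`, `w0dot` (true model) and `wdot1`, `wdot0` (prototype).
#' @export
jointWeights <- function(mTrue, mProto, mafA, mafB = mafA) {
  stopifnot(is(mTrue, "DiseaseModel"), is(mProto, "DiseaseModel"))
  p <- .cell_probs(mafA, mafB)
  k <- as.integer(t(mTrue@cells))
  l <- as.integer(t(mProto@cells))
  w <- function(ki, li) sum(p[k == ki & l == li])
  out <- list(w11 = w(1, 1), w10 = w(1, 0), w01 = w(0, 1), w00 = w(0, 0))
  out$w1dot <- out$w11 + out$w10
  out$w0dot <- out$w01 + out$w00
  out$wdot1 <- out$w11 + out$w01
  out$wdot0 <- out$w10 + out$w00
  out
}

#' Two-level penetrance from prevalence and heritability
#'
#' For a true model whose risky genotype mass is `w1dot`, the two penetrance
#' levels consistent with a given prevalence and heritability are
#' `P1 = P(D) + sqrt((W0./W1.) P(D)(1-P(D)) h^2)` and
#' `P0 = P(D) - sqrt((W1./W0.) P(D)(1-P(D)) h^2)`; substituting back
#' recovers the prevalence and heritability exactly.
#'
#' @param w1dot probability mass of the risky genotype combinations,
#'   in (0, 1).
#' @param prevalence P(D) in (0, 1).
#' @param heritability h^2 >= 0.
#' @return named list with `p1` and `p0`.
#' @export
solvePenetrance <- function(w1dot, prevalence, heritability) {
  if (w1dot <= 0 || w1dot >= 1)
    stop("w1dot must be strictly between 0 and 1")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  if (heritability < 0) stop("heritability must be >= 0")
  w0dot <- 1 - w1dot
  base <- prevalence * (1 - prevalence) * heritability
  p1 <- prevalence + sqrt(w0dot / w1dot * base)
  p0 <- prevalence - sqrt(w1dot / w0dot * base)
  if (p0 < 0 || p1 > 1)
    stop(sprintf(paste0("no valid two-level penetrance: risky mass %.4g with ",
                        "prevalence %.4g and heritability %.4g gives ",
                        "P1 = %.4g, P0 = %.4g"),
                 w1dot, prevalence, heritability, p1, p0))
  list(p1 = p1, p0 = p0)
}

# U, V sampling weights for a true model's penetrance pair
.uv_weights <- function(p1, p0, prevalence, sampleRatio) {
  list(U = sampleRatio * p1 * (1 - prevalence) + (1 - p1) * prevalence,
       V = sampleRatio * p0 * (1 - prevalence) + (1 - p0) * prevalence)
}

#' Phi similarity of a prototype model to a true model
#'
#' @param mProto the prototype (candidate) model M'.
#' @param mTrue the true model M, assumed to have the two penetrance levels
#'   implied by the context's prevalence and heritability.
#' @param ctx a [`PopulationContext`][PopulationContext-class].
#' @return the phi coefficient in [-1, 1]; `modelPhi(m, m, ctx)` is 1 and
#'   `modelPhi(complementModel(m), m, ctx)` is -1.
#' @export
modelPhi <- function(mProto, mTrue, ctx) {
  stopifnot(is(ctx, "PopulationContext"))
  w <- jointWeights(mTrue, mProto, ctx@mafA, ctx@mafB)
  if (w$w1dot <= 0 || w$w1dot >= 1)
    stop("true model is degenerate at these MAFs (risky mass 0 or 1)")
  if (w$wdot1 <= 0 || w$wdot1 >= 1)
    stop("prototype model is degenerate at these MAFs")
  pen <- solvePenetrance(w$w1dot, ctx@prevalence, ctx@heritability)
  uv <- .uv_weights(pen$p1, pen$p0, ctx@prevalence, ctx@sampleRatio)
  ruv <- uv$U / uv$V
  zap <- function(x) ifelse(x < .W_FLOOR, 0, x)
  w11 <- zap(w$w11); w10 <- zap(w$w10)
  w01 <- zap(w$w01); w00 <- zap(w$w00)
  den2 <- (ruv * w11 + w01) * (w10 + w00 / ruv) * w$w1dot * w$w0dot
  if (den2 <= 0)
    stop("degenerate denominator in phi for these models at these MAFs")
  (w11 * w00 - w10 * w01) / sqrt(den2)
}

#' Directional distance between disease models
#'
#' `d(M', M) = 1 - Phi(M', M)` in [0, 2].  The distance is directional: `M`
#' plays the true model (its penetrance levels are calibrated from the
#' context) and `mProto` the prototype standing in for it.
#'
#' @inheritParams modelPhi
#' @export
modelDistance <- function(mProto, mTrue, ctx) 1 - modelPhi(mProto, mTrue, ctx)

#' @describeIn modelDistance the symmetrized distance
#'   `(d(m1, m2) + d(m2, m1)) / 2`, used for multidimensional scaling maps.
#' @param m1,m2 [`DiseaseModel`][DiseaseModel-class] objects.
#' @export
symmetrizedDistance <- function(m1, m2, ctx)
  (modelDistance(m1, m2, ctx) + modelDistance(m2, m1, ctx)) / 2

#' Empirical phi coefficient of two binary risk assignments
#'
#' @param n11,n10,n01,n00 counts of individuals cross-classified by two risk
#'   assignments (the concordance table).
#' @return `(n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`.
#' @export
phiEmpirical <- function(n11, n10, n01, n00) {
  if (any(c(n11, n10, n01, n00) < 0)) stop("counts must be non-negative")
  m1 <- n11 + n10; m0 <- n01 + n00
  c1 <- n11 + n01; c0 <- n10 + n00
  if (min(m1, m0, c1, c0) == 0)
    stop("phi is undefined when a margin is zero")
  (n11 * n00 - n10 * n01) / sqrt(m1 * m0 * c1 * c0)
}

# Vectorized directional distance table.
#
# proto_ids: P candidate prototypes (M'); true_ids: T members (M).
# Returns list(distance = P x T matrix d(proto, true), feasible = logical T
# marking true models with a valid two-level penetrance at this context).
# Infeasible or degenerate true models get NA columns.
.distance_table <- function(proto_ids, true_ids, ctx) {
  p <- .cell_probs(ctx@mafA, ctx@mafB)
  X <- .model_matrix(proto_ids)   # P x 9
  Y <- .model_matrix(true_ids)    # T x 9
  w1 <- as.vector(Y %*% p)        # risky mass of each true model
  w0 <- 1 - w1
  base <- ctx@prevalence * (1 - ctx@prevalence) * ctx@heritability
  p1 <- ctx@prevalence + sqrt(w0 / w1 * base)
  p0 <- ctx@prevalence - sqrt(w1 / w0 * base)
  feasible <- w1 > 0 & w1 < 1 & p0 >= 0 & p1 <= 1
  U <- ctx@sampleRatio * p1 * (1 - ctx@prevalence) + (1 - p1) * ctx@prevalence
  V <- ctx@sampleRatio * p0 * (1 - ctx@prevalence) + (1 - p0) * ctx@prevalence
  ruv <- U / V
  W11 <- X %*% (p * t(Y))                        # P x T
  wd1 <- as.vector(X %*% p)                      # prototype risky mass
  W10 <- matrix(w1, nrow(X), ncol = length(w1), byrow = TRUE) - W11
  W01 <- wd1 - W11
  W00 <- 1 - W11 - W10 - W01
  W11[W11 < .W_FLOOR] <- 0; W10[W10 < .W_FLOOR] <- 0
  W01[W01 < .W_FLOOR] <- 0; W00[W00 < .W_FLOOR] <- 0
  R <- matrix(ruv, nrow(X), length(ruv), byrow = TRUE)
  den2 <- (R * W11 + W01) * (W10 + W00 / R) *
    matrix(w1 * w0, nrow(X), length(w1), byrow = TRUE)
  den2[!is.finite(den2) | den2 <= 0] <- NA_real_
  phi <- (W11 * W00 - W10 * W01) / sqrt(den2)
  phi[, !feasible] <- NA_real_
  d <- 1 - phi
  dimnames(d) <- list(proto_ids, true_ids)
  list(distance = d, feasible = feasible)
}

#' Directional distance matrix over a set of disease models
#'
#' Computes `d(M_i, M_j)` for every ordered pair of the given models at one
#' population context, with rows playing the prototype (first argument of
#' the directional distance) and columns the true model.  Models without a
#' valid two-level penetrance at this context (risky-mass too small or too
#' large for the prevalence/heritability) yield `NA` columns.
#'
#' @param modelIds character vector of 9-character model ids; defaults to
#'   the symmetry-reduced set.
#' @param ctx a [`PopulationContext`][PopulationContext-class].
#' @return numeric matrix with `modelIds` as row and column names.
#' @export
distanceMatrix <- function(ctx, modelIds = reducedModelSet(ids = TRUE)) {
  .distance_table(modelIds, modelIds, ctx)$distance
}
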