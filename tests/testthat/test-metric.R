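test_that("Hardy-Weinberg genotype probabilities", {
  expect_equal(unname(hweProbs(0.3)), c(0.49, 0.42, 0.09))
  expect_equal(unname(hweProbs(0.5)), c(0.25, 0.5, 0.25))
  for (q in c(0.01, 0.17, 0.44)) expect_equal(sum(hweProbs(q)), 1)
  expect_error(hweProbs(0.6), "0, 0.5")
  expect_error(hweProbs(0), "0, 0.5")
})

test_that("joint weights cross-classify HWE mass correctly", {
  m <- DiseaseModel("001010100")  # anti-diagonal
  w <- jointWeights(m, m, 0.3)
  expect_equal(w$w10, 0)
  expect_equal(w$w01, 0)
  expect_equal(w$w1dot, 0.2646, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    ids <- sample(enumerateNontrivial(ids = TRUE), 2)
    w <- jointWeights(DiseaseModel(ids[1]), DiseaseModel(ids[2]),
                      runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
    expect_equal(w$w11 + w$w10 + w$w01 + w$w00, 1, tolerance = 1e-12)
    expect_true(all(c(w$w11, w$w10, w$w01, w$w00) >= 0))
  }
})

test_that("two-level penetrance solves and round-trips prevalence/h2", {
  p <- solvePenetrance(0.3, 0.05, 0)
  expect_equal(p$p1, 0.05)
  expect_equal(p$p0, 0.05)
  p <- solvePenetrance(0.2646, 0.02, 0.02)
  expect_equal(p$p1, 0.0530, tolerance = 1e-3)
  expect_equal(p$p0, 0.0081, tolerance = 1e-2)
  # substituting the implied two-level table back recovers both parameters
  set.seed(5)
  for (i in 1:10) {
    maf <- runif(1, 0.1, 0.5)
    id <- sample(reducedModelSet(ids = TRUE), 1)
    m <- DiseaseModel(id)
    w1 <- sum((hweProbs(maf) %o% hweProbs(maf)) * modelCells(m))
    pr <- runif(1, 0.01, 0.1)
    h2 <- runif(1, 0.001, 0.01)
    pen <- tryCatch(solvePenetrance(w1, pr, h2), error = function(e) NULL)
    if (is.null(pen)) next
    tab <- matrix(ifelse(modelCells(m) == 1, pen$p1, pen$p0), 3, 3)
    back <- prevalenceAndH2(tab, maf)
    expect_equal(back$prevalence, pr, tolerance = 1e-10)
    expect_equal(back$h2, h2, tolerance = 1e-10)
  }
  expect_error(solvePenetrance(0.9, 0.02, 0.02), "no valid")
})

test_that("phi is 1 for self, -1 for the complement", {
  set.seed(6)
  for (i in 1:12) {
    ctx <- PopulationContext(runif(1, 0.1, 0.5), runif(1, 0.1, 0.5),
                             sampleRatio = sample(c(0.5, 1, 2), 1))
    id <- sample(reducedModelSet(ids = TRUE), 1)
    m <- DiseaseModel(id)
    phi <- tryCatch(modelPhi(m, m, ctx), error = function(e) NULL)
    if (is.null(phi)) next  # infeasible at this context
    expect_equal(phi, 1, tolerance = 1e-9)
    expect_equal(modelPhi(complementModel(m), m, ctx), -1, tolerance = 1e-9)
    expect_equal(modelDistance(m, m, ctx), 0, tolerance = 1e-9)
    expect_equal(modelDistance(complementModel(m), m, ctx), 2,
                 tolerance = 1e-9)
  }
})

test_that("phi agrees with the Monte-Carlo concordance oracle", {
  set.seed(7)
  cases <- list(
    list(p = "000010000", t = "000000111", maf = 0.4, r = 1),
    list(p = "000011011", t = "001010100", maf = 0.4, r = 1),
    list(p = "000010000", t = "000011011", maf = 0.2, r = 2),
    list(p = "001001110", t = "000001011", maf = 0.3, r = 1))
  for (cs in cases) {
    ctx <- PopulationContext(cs$maf, sampleRatio = cs$r)
    mp <- DiseaseModel(cs$p); mt <- DiseaseModel(cs$t)
    mc <- mc_phi(mp, mt, ctx, nCtrl = 2e5, reps = 3)
    expect_lt(abs(modelPhi(mp, mt, ctx) - mc$mean),
              3 * max(mc$se, 1e-4))
  }
})

test_that("sampling-weight identities hold", {
  set.seed(8)
  for (i in 1:20) {
    pr <- runif(1, 0.01, 0.2)
    r <- runif(1, 0.3, 3)
    p1 <- runif(1, pr, 0.9)
    p0 <- runif(1, 0, pr)
    U <- r * p1 * (1 - pr) + (1 - p1) * pr
    V <- r * p0 * (1 - pr) + (1 - p0) * pr
    r0 <- pr / (1 - pr)
    # U/V = (r0 + (r - r0) P1) / (r0 + (r - r0) P0), after scaling by (1-pr)
    expect_equal(U / V, (r0 + (r - r0) * p1) / (r0 + (r - r0) * p0),
                 tolerance = 1e-12)
  }
  # at r = r0 the weights collapse and the denominator reduces to the
  # plain variance product
  ctx <- PopulationContext(0.3, 0.3, prevalence = 0.02,
                           sampleRatio = 0.02 / 0.98)
  m1 <- DiseaseModel("000011011"); m2 <- DiseaseModel("001010100")
  w <- jointWeights(m2, m1, 0.3)
  plain <- (w$w11 * w$w00 - w$w10 * w$w01) /
    sqrt(w$wdot1 * w$wdot0 * w$w1dot * w$w0dot)
  expect_equal(modelPhi(m1, m2, ctx), plain, tolerance = 1e-9)
})

test_that("denominator factorization expands to the variance decomposition", {
  set.seed(9)
  for (i in 1:20) {
    w <- abs(rnorm(4)); w <- w / sum(w)
    ruv <- runif(1, 0.5, 20)
    lhs <- (ruv * w[1] + w[3]) * (w[2] + w[4] / ruv)
    rhs <- ruv * w[1] * w[2] + w[3] * w[2] + w[1] * w[4] +
      w[3] * w[4] / ruv
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("directional distances over the reduced set stay in [0, 2]", {
  ctx <- PopulationContext(0.2)
  d <- distanceMatrix(ctx)
  expect_identical(dim(d), c(143L, 143L))
  finite <- d[is.finite(d)]
  expect_true(all(finite >= -1e-9 & finite <= 2 + 1e-9))
  # symmetrized distance is symmetric and zero on the diagonal
  m1 <- DiseaseModel("000011011"); m2 <- DiseaseModel("000010000")
  expect_equal(symmetrizedDistance(m1, m2, ctx),
               symmetrizedDistance(m2, m1, ctx))
  expect_equal(symmetrizedDistance(m1, m1, ctx), 0, tolerance = 1e-9)
})

test_that("empirical phi computes the 2x2 concordance coefficient", {
  expect_equal(phiEmpirical(30, 10, 10, 30), 0.5)
  expect_equal(phiEmpirical(20, 0, 0, 30), 1)
  # independence: counts proportional to margin products
  expect_equal(phiEmpirical(20, 20, 30, 30), 0)
  expect_error(phiEmpirical(10, 10, 0, 0), "margin")
})
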