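# Built-in simulation scenarios.  Each preset fixes the full study
# condition — sample sizes, MAFs, disease model and its calibration — and
# names the true causal pair(s) by SNP index.

.DMN_TABLES <- list(
  DMN1 = matrix(c(0.08, 0.07, 0.05,
                  0.10, 0.00, 0.10,
                  0.03, 0.10, 0.04), 3, 3, byrow = TRUE),
  DMN2 = matrix(c(0.00, 0.10, 0.09,
                  0.04, 0.01, 0.08,
                  0.07, 0.09, 0.03), 3, 3, byrow = TRUE),
  DMN3 = matrix(c(0.07, 0.05, 0.02,
                  0.05, 0.09, 0.01,
                  0.02, 0.01, 0.03), 3, 3, byrow = TRUE),
  DMN4 = matrix(c(0.090, 0.001, 0.020,
                  0.080, 0.070, 0.005,
                  0.003, 0.007, 0.020), 3, 3, byrow = TRUE))

.DMN_MAFS <- c(DMN1 = 0.25, DMN2 = 0.25, DMN3 = 0.1, DMN4 = 0.1)

# the additive penetrance table of the spurious-pair scenario (both causal
# pairs use it; MAF 0.5 / 0.3 within each pair)
.ADDITIVE_TABLE <- matrix(c(0.0, 0.0, 0.1,
                            0.0, 0.0, 0.1,
                            0.1, 0.1, 0.2), 3, 3, byrow = TRUE)

# two-pair scenario with four penetrance levels p_kl indexed by the risky
# status of each pair's genotype combination under its model
.two_level_joint <- function(model1, model2, p11, p10, p01, p00) {
  r1 <- as.integer(t(model1@cells))
  r2 <- as.integer(t(model2@cells))
  lev <- outer(r1, r2, function(a, b) 2 * a + b)  # 0=00, 1=01, 2=10, 3=11
  matrix(c(p00, p01, p10, p11)[lev + 1], 9, 9)
}

#' Built-in simulation presets
#'
#' `scenarioPresets()` lists the available preset names;
#' `scenarioPreset(name)` returns the full study condition: sample sizes,
#' number of SNPs, causal block, noise-SNP MAF rule, the true causal
#' pair(s) (as index pairs into the SNP columns) and the default
#' significance threshold where one applies.
#'
#' Families: `ex2.1-1` / `ex2.1-2` (pathological two-pair scenarios, n =
#' 800), `ex2.2` (spurious-pair scenario, two additive pairs acting
#' independently, n = 200), `null-0.05` / `null-0.10` / `null-0.40` (pure
#' null, n = 400), `T` / `DD` / `MOD` / `XOR` / `ME` / `MET` at MAF 0.1
#' (n = 600) or 0.4 (n = 300) as e.g. `XOR-0.4`, and `DMN1`..`DMN4`
#' (main-effect-free penetrance tables, n = 600).  All samples are
#' balanced.
#'
#' @param name a preset name.
#' @return `scenarioPreset`: a named list; `scenarioPresets`: character
#'   vector of names.
#' @export
scenarioPreset <- function(name) {
  two_pair <- function(joint, mafs, n, noiseMaf)
    list(nCases = n / 2, nControls = n / 2, nSnps = 100,
         causal = c(list(type = "twoPair", joint = joint),
                    as.list(stats::setNames(mafs, c("maf1A", "maf1B",
                                                    "maf2A", "maf2B")))),
         noiseMaf = noiseMaf,
         truth = list(c(1L, 2L), c(3L, 4L)))
  one_pair <- function(pen, maf, n)
    list(nCases = n / 2, nControls = n / 2, nSnps = 100,
         causal = list(type = "pair", penetrance = pen,
                       mafA = maf, mafB = maf),
         noiseMaf = maf, truth = list(c(1L, 2L)))

  if (name == "ex2.1-1") {
    m <- DiseaseModel("001010100")
    p11 <- pathologicalP11(0.1, 0.28, 0.01, m, 0.3)
    out <- two_pair(.two_level_joint(m, m, p11, 0.1, 0.28, 0.01),
                    rep(0.3, 4), n = 800, noiseMaf = 0.3)
  } else if (name == "ex2.1-2") {
    m1 <- DiseaseModel("000011011")
    m2 <- DiseaseModel("011100100")
    p11 <- pathologicalP11(0.09, 0.12, 0.001, m2, 0.2)
    out <- two_pair(.two_level_joint(m1, m2, p11, 0.09, 0.12, 0.001),
                    rep(0.2, 4), n = 800, noiseMaf = 0.2)
  } else if (name == "ex2.2") {
    out <- two_pair(combineIndependent(.ADDITIVE_TABLE, .ADDITIVE_TABLE),
                    c(0.5, 0.3, 0.5, 0.3), n = 200,
                    noiseMaf = c(0.05, 0.5))
  } else if (grepl("^null-", name)) {
    maf <- as.numeric(sub("^null-", "", name))
    if (is.na(maf)) stop("unknown preset: ", name)
    out <- list(nCases = 200, nControls = 200, nSnps = 100, null = TRUE,
                noiseMaf = maf, truth = NULL)
  } else if (grepl("^(T|DD|MOD|XOR|ME|MET)-", name)) {
    family <- sub("-.*$", "", name)
    maf <- as.numeric(sub("^[A-Z]+-", "", name))
    if (is.na(maf)) stop("unknown preset: ", name)
    h2 <- if (family %in% c("ME", "MET")) 0.015 else 0.02
    cal <- solveAlphaTheta(family, maf, prevalence = 0.02, h2 = h2)
    out <- one_pair(cal$penetrance, maf, n = if (maf < 0.25) 600 else 300)
    out$calibration <- cal[c("family", "alpha", "theta")]
  } else if (name %in% names(.DMN_TABLES)) {
    out <- one_pair(.DMN_TABLES[[name]], .DMN_MAFS[[name]], n = 600)
  } else {
    stop("unknown preset: ", name)
  }
  out$name <- name
  out
}

#' @rdname scenarioPreset
#' @export
scenarioPresets <- function() {
  c("ex2.1-1", "ex2.1-2", "ex2.2",
    "null-0.05", "null-0.10", "null-0.40",
    as.vector(outer(c("T", "DD", "MOD", "XOR", "ME", "MET"),
                    c(0.1, 0.4), paste, sep = "-")),
    names(.DMN_TABLES))
}

# draw one dataset for a preset (uses the current RNG state)
.simulate_preset <- function(preset) {
  if (is.character(preset)) preset <- scenarioPreset(preset)
  if (isTRUE(preset$null))
    nullDataset(preset$noiseMaf, preset$nCases + preset$nControls,
                preset$nSnps)
  else
    simulateDataset(preset$nCases, preset$nControls, preset$nSnps,
                    preset$causal, noiseMaf = preset$noiseMaf)
}
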