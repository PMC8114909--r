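# Shared fixtures, memoised so expensive objects are built once per test
# run regardless of which file asks first.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    assign(name, builder(), envir = .fixture_env)
  .fixture_env[[name]]
}

## two-locus lookup tables
fix_lookup <- function(nHap, nReps, seed = 101) {
  fixture(paste0("lookup", nHap), function()
    buildLookup(nHap, nReps = nReps, seed = seed))
}

## trained summary-regression model at n_hap = 100, 50 kb windows
fix_model100 <- function() {
  fixture("model100", function() {
    training <- simulateTrainingWindows(nWindows = 240, nHap = 100,
                                        windowBp = 5e4, thetaBp = 1e-3,
                                        rhoMax = 100, seed = 111)
    list(training = training,
         model = trainSummaryModel(training, seed = 112))
  })
}

## windows simulated at true rho {5, 20, 80}, 20 replicates each, with
## both estimators' outputs (the parameter-recovery experiment)
fix_recovery <- function() {
  fixture("recovery", function() {
    lk <- fix_lookup(100, nReps = 20000)
    mod <- fix_model100()$model
    L <- 5e4
    out <- NULL
    for (rho in c(5, 20, 80)) for (r in 1:20) {
      m <- constantMap("chr1", L, rho / L / (4 * 10000) * 1e8)
      p <- simulatePanel(100, L, m, 1e-3, seed = 1000 * rho + r)
      cr <- compositeRho(p, lk)
      pr <- predictSummaryRho(mod, windowFeatures(p, spanBp = L))
      out <- rbind(out, data.frame(
        rho = rho, rep = r,
        estC = cr$rhoPerBp * L, varC = cr$variance * L^2,
        estS = as.numeric(pr), varS = attr(pr, "variance")))
    }
    out
  })
}

## the study grid: 10 replicate synthetic cohorts run through the
## phasing / imputation condition grid under the constant and generating
## maps (the study's central comparison)
fix_study_grid <- function() {
  fixture("study_grid", function() {
    lapply(1:10, function(rep) {
      st <- simulateStudy(seed = 1000 + rep)
      experimentGrid(
        st$cohort, st$chip, st$ref,
        maps = list(constant = constantMap("chr1", 4e5, 1),
                    generating = st$generatingMap),
        params = HmmParams(10000, 1e-3), seed = 2000 + rep,
        nIter = 20, nBurn = 10, bins = c(0, 0.004, 0.05, 0.5))
    })
  })
}

## brute-force four-gamete scan: TRUE if any site pair shows all four
## two-locus haplotypes
violates_four_gamete <- function(H) {
  S <- ncol(H)
  if (S < 2) return(FALSE)
  C11 <- crossprod(H)
  ones <- colSums(H)
  n <- nrow(H)
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    n11 <- C11[i, j]
    n10 <- ones[i] - n11
    n01 <- ones[j] - n11
    n00 <- n - n11 - n10 - n01
    if (n11 > 0 && n10 > 0 && n01 > 0 && n00 > 0) return(TRUE)
  }
  FALSE
}

## small deterministic panel for I/O-ish tests
fix_toy_panel <- function() {
  fixture("toy_panel", function()
    simulatePanel(8, 2e4, constantMap("chr1", 2e4, 1), 2e-3, seed = 77))
}
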