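test_that("lookup tables are normalised and encode LD decay", {
  lk <- fix_lookup(8, nReps = 6000)
  expect_true(all(abs(colSums(lk@probs) - 1) < 1e-9))
  expect_true(all(diff(lk@rhoGrid) > 0))

  ## at rho = 0 a single genealogy forbids four-gamete violations
  viol <- recombMap:::.key_violates_4g(lk@configs)
  pViol <- colSums(lk@probs[viol, , drop = FALSE])
  smooth_floor <- sum(viol) / (lk@nKept[1] + length(lk@configs))
  expect_lte(pViol[1], smooth_floor + 1e-12)  # only add-one smoothing mass

  ## violation probability grows with rho (the r2-decay signature)
  expect_gt(cor(pViol, lk@rhoGrid, method = "spearman"), 0.9)
  expect_gt(pViol[length(pViol)], 10 * pViol[1])
  expect_error(buildLookup(2), ">= 4")
})

test_that("composite log-likelihood equals the brute-force pair sum", {
  lk <- fix_lookup(8, nReps = 6000)
  ## toy panel: n_hap = 8 (matching the lookup), 3 segregating sites
  H <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L), c(1L, 0L, 0L), c(1L, 1L, 0L),
             c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 0L, 1L))
  pos <- c(1000, 9000, 21000)
  panel <- HaplotypePanel(H, pos)
  cand <- c(0, 1e-5, 1e-4, 1e-3)
  got <- compositeRho(panel, lk, maxPairSpan = 5e4, candRhoBp = cand)

  ## independent oracle: per pair, canonical key lookup + log1p-linear
  ## interpolation, summed over the three pairs
  keyOf <- function(i, j) {
    n11 <- sum(H[, i] & H[, j]); n10 <- sum(H[, i] & !H[, j])
    n01 <- sum(!H[, i] & H[, j]); n00 <- sum(!H[, i] & !H[, j])
    recombMap:::.config_key(n00, n01, n10, n11)
  }
  interp <- function(key, rhoPair) {
    idx <- match(key, lk@configs)
    if (is.na(idx)) return(log(1 / (min(lk@nKept) + length(lk@configs))))
    ll <- log(lk@probs[idx, ])
    t <- log1p(rhoPair); gt <- log1p(lk@rhoGrid)
    if (t <= gt[1]) return(ll[1])
    if (t >= gt[length(gt)]) return(ll[length(ll)])
    j <- findInterval(t, gt)
    w <- (t - gt[j]) / (gt[j + 1] - gt[j])
    (1 - w) * ll[j] + w * ll[j + 1]
  }
  for (ci in seq_along(cand)) {
    expected <- interp(keyOf(1, 2), cand[ci] * (pos[2] - pos[1])) +
                interp(keyOf(1, 3), cand[ci] * (pos[3] - pos[1])) +
                interp(keyOf(2, 3), cand[ci] * (pos[3] - pos[2]))
    expect_equal(got$logLik[ci], expected, tolerance = 1e-10)
  }
})

test_that("composite estimation flags unusable windows and is deterministic", {
  lk <- fix_lookup(8, nReps = 6000)
  mono <- HaplotypePanel(matrix(0L, 8, 3,
                                dimnames = NULL) + c(0L), c(10, 20, 30))
  r <- compositeRho(mono, lk)
  expect_true(is.na(r$rhoPerBp))
  p <- simulatePanel(8, 2e4, constantMap("chr1", 2e4, 1), 1e-3, seed = 12)
  a <- compositeRho(p, lk)
  b <- compositeRho(p, lk)
  expect_identical(a$rhoPerBp, b$rhoPerBp)
  expect_error(compositeRho(p, fix_lookup(8, 6000), maxPairSpan = 5e4,
                            candRhoBp = NULL), NA)
  lk100 <- fix_lookup(8, 6000)
  expect_error({
    p2 <- simulatePanel(10, 2e4, constantMap("chr1", 2e4, 1), 1e-3, seed = 1)
    compositeRho(p2, lk100)
  }, "lookup was built for")
})

test_that("segmentation tiles the SNP axis exactly once with overhangs", {
  segs <- segmentPanel(25000L, 10000, 1000)
  expect_equal(segs$coreStart, c(1L, 10001L, 20001L))
  expect_equal(segs$coreEnd, c(10000L, 20000L, 25000L))
  expect_equal(segs$segStart, c(1L, 9001L, 19001L))
  expect_equal(segs$segEnd, c(11000L, 21000L, 25000L))

  ## every SNP belongs to exactly one core, for arbitrary sizes
  for (n in c(1L, 9999L, 10000L, 10001L, 34567L)) {
    s <- segmentPanel(n, 10000, 1000)
    covered <- unlist(Map(seq, s$coreStart, s$coreEnd))
    expect_identical(as.integer(covered), seq_len(n))
  }
  expect_equal(nrow(segmentPanel(9000L, 10000, 1000)), 1L)
  expect_error(segmentPanel(100L, 2000, 1000), "exceed")
})

test_that("window features are finite and match hand computation", {
  ## degenerate windows
  empty <- HaplotypePanel(matrix(0L, 4, 2), c(5, 10))
  f0 <- windowFeatures(empty, spanBp = 100)
  expect_true(all(vapply(f0, is.finite, logical(1))))
  expect_equal(f0$S, 0)

  ## known matrix: S, distinct haplotypes, Tajima's D by textbook formula
  H <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L), c(1L, 0L, 0L), c(1L, 1L, 0L))
  fe <- windowFeatures(HaplotypePanel(H, c(10, 20, 30)), spanBp = 20)
  expect_equal(fe$S, 3)
  expect_equal(fe$nDistinct, 4)
  n <- 4; S <- 3
  k <- colSums(H)
  pi_tot <- sum(k * (n - k)) / choose(n, 2)
  a1 <- sum(1 / (1:3)); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(fe$tajimaD, D, tolerance = 1e-12)
  expect_true(fe$meanR2 >= 0 && fe$meanR2 <= 1)
  expect_true(fe$meanAbsDprime >= 0 && fe$meanAbsDprime <= 1)
})

test_that("the summary regressor is deterministic, clipped and flagged", {
  fx <- fix_model100()
  mod <- fx$model
  target <- fx$training[1:3, setdiff(names(fx$training), "rho")]
  p1 <- predictSummaryRho(mod, target)
  p2 <- predictSummaryRho(mod, target)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_true(all(p1 >= 0 & p1 <= max(fx$training$rho)))
  crazy <- target[1, ]
  crazy$S <- 1e6
  expect_true(attr(predictSummaryRho(mod, crazy), "extrapolated")[1])
  expect_error(trainSummaryModel(fx$training[1:50, ]), "200")
})

test_that("held-out recovery of the summary regressor clears R2 0.5", {
  fx <- fix_model100()
  held <- simulateTrainingWindows(nWindows = 50, nHap = 100, windowBp = 5e4,
                                  thetaBp = 1e-3, rhoMax = 100, seed = 991)
  pr <- predictSummaryRho(fx$model, held)
  r2 <- 1 - sum((held$rho - pr)^2) / sum((held$rho - mean(held$rho))^2)
  expect_gt(r2, 0.5)
})

test_that("combineEstimates averages values and propagates variance", {
  tr <- RhoTrack(c(1, 101), c(101, 201), c(2e-4, 4e-4), c(1, 1), c(5L, 5L))
  same <- combineEstimates(tr, tr)
  expect_equal(rhoPerBp(same), rhoPerBp(tr))
  b <- RhoTrack(c(1, 101), c(101, 201), c(4e-4, 2e-4), c(3, 1), c(4L, 6L))
  comb <- combineEstimates(tr, b)
  expect_equal(rhoPerBp(comb), c(3e-4, 3e-4))
  expect_equal(rhoVariance(comb), c(1, 0.5))
  expect_true(all(rhoVariance(comb) <= pmax(rhoVariance(tr),
                                            rhoVariance(b))))

  ## a window missing in one source takes the other's value
  miss <- RhoTrack(c(1, 101), c(101, 201), c(NA, 2e-4), c(NA, 1), c(0L, 6L))
  comb2 <- combineEstimates(tr, miss)
  expect_equal(rhoPerBp(comb2), c(2e-4, 3e-4))

  disjoint <- RhoTrack(c(51, 151), c(151, 251), c(1e-4, 1e-4))
  expect_error(combineEstimates(tr, disjoint), "window schemes")
})

test_that("composite accuracy improves with sample size", {
  ## estimator consistency: MAE at n_hap 100 below MAE at n_hap 20,
  ## 20 replicates at true window rho 20
  lk20 <- fix_lookup(20, nReps = 8000)
  lk100 <- fix_lookup(100, nReps = 20000)
  L <- 5e4
  m <- constantMap("chr1", L, 20 / L / (4 * 1e4) * 1e8)
  err <- function(n, lk) vapply(1:20, function(r) {
    p <- simulatePanel(n, L, m, 1e-3, seed = 60000 + 100 * n + r)
    abs(compositeRho(p, lk)$rhoPerBp * L - 20)
  }, numeric(1))
  expect_lt(mean(err(100, lk100)), mean(err(20, lk20)))
})

test_that("estimateMap recovers structure and reruns byte-identically", {
  lk <- fix_lookup(40, nReps = 8000)
  training <- simulateTrainingWindows(nWindows = 200, nHap = 40,
                                      windowBp = 5e4, thetaBp = 1e-3,
                                      rhoMax = 100, seed = 771)
  mod <- trainSummaryModel(training, seed = 772)

  ## two-level map: the hot half must come out hotter than the cold half
  two <- GeneticMap("chr1", c(1, 2e5, 4e5), c(0.5, 4))
  hotter <- vapply(1:4, function(r) {
    p <- simulatePanel(40, 4e5, two, 1e-3, seed = 880 + r)
    em <- estimateMap(p, 1e4, config = list(lookup = lk, model = mod,
                                            seed = r))
    w <- windowRates(em, 2e5)
    w$rate[2] > w$rate[1]
  }, logical(1))
  expect_gte(sum(hotter), 3)

  ## same seed, same panel -> byte-identical map file
  p <- simulatePanel(40, 4e5, two, 1e-3, seed = 99)
  e1 <- estimateMap(p, 1e4, config = list(lookup = lk, model = mod, seed = 5))
  e2 <- estimateMap(p, 1e4, config = list(lookup = lk, model = mod, seed = 5))
  f1 <- tempfile(); f2 <- tempfile()
  writeGeneticMap(e1, f1); writeGeneticMap(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(is.list(attr(e1, "provenance")))
})
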