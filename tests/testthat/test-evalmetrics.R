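test_that("trio logic resolves child phase exactly where it should", {
  ## forced single-site cases
  tp <- mendelianPhaseChild(2L, 0L, 1L)
  expect_equal(c(tp@hap1, tp@hap2), c(1, 0))
  expect_true(tp@resolvableMask)

  tp2 <- mendelianPhaseChild(1L, 1L, 1L)        # triple het: unresolvable
  expect_false(tp2@resolvableMask)
  expect_true(is.na(tp2@hap1))

  tp3 <- mendelianPhaseChild(2L, 2L, 0L)        # impossible transmission
  expect_equal(tp3@inconsistentSites, 1L)
  expect_false(tp3@resolvableMask)

  tp4 <- mendelianPhaseChild(0L, 0L, 1L)        # het child of two hom-ref
  expect_equal(tp4@inconsistentSites, 1L)

  ## vector case with missing data and hom child
  tp5 <- mendelianPhaseChild(c(1L, NA, 0L, 1L), c(0L, 1L, 0L, 2L),
                             c(1L, 1L, 0L, 2L))
  expect_equal(tp5@resolvableMask, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(tp5@hap1, c(1, NA, 0, 1))        # paternal alleles
  expect_equal(tp5@hap2, c(0, NA, 0, 1))
})

test_that("switch error rate counts relative-phase disagreements", {
  S <- 5
  t1 <- c(1, 0, 1, 1, 0); t2 <- 1 - t1
  tp <- new("TruthPhase", hap1 = t1, hap2 = t2,
            resolvableMask = rep(TRUE, S), inconsistentSites = integer(0))
  expect_equal(switchErrorRate(rbind(t1, t2), tp), 0)
  expect_equal(switchErrorRate(rbind(t2, t1), tp), 0)   # global flip

  ## one persistent flip starting at the 3rd heterozygote: 1 of 4 switches
  e1 <- t1; e2 <- t2
  e1[3:5] <- t2[3:5]; e2[3:5] <- t1[3:5]
  expect_equal(switchErrorRate(rbind(e1, e2), tp), 0.25)

  ## fewer than two resolvable hets is flagged missing
  one <- new("TruthPhase", hap1 = c(1, NA), hap2 = c(0, NA),
             resolvableMask = c(TRUE, FALSE),
             inconsistentSites = integer(0))
  expect_true(is.na(switchErrorRate(rbind(c(1, 0), c(0, 1)), one)))
})

test_that("injecting k alternating switches yields SER k/(H-1) exactly", {
  set.seed(6)
  H <- 12
  t1 <- rep(c(1, 0), 6); t2 <- 1 - t1
  tp <- new("TruthPhase", hap1 = t1, hap2 = t2,
            resolvableMask = rep(TRUE, H), inconsistentSites = integer(0))
  for (k in 1:(H - 2)) {
    cuts <- sort(sample(2:H, k))     # switch before each cut position
    flip <- cumsum(seq_len(H) %in% cuts) %% 2 == 1
    e1 <- ifelse(flip, t2, t1)
    e2 <- ifelse(flip, t1, t2)
    expect_equal(switchErrorRate(rbind(e1, e2), tp), k / (H - 1))
  }
})

test_that("concordance identities hold on constructed imputations", {
  S <- 10; N <- 4
  orig <- matrix(sample(0:2, N * S, replace = TRUE), N, S)
  pos <- seq_len(S) * 100
  masked <- c(2L, 5L, 9L)
  mask <- new("MaskSet", maskedSites = masked,
              original = orig[, masked, drop = FALSE])
  refF <- c(0.3, 0.0005, 0.2, 0.4, 0.02, 0.1, 0.25, 0.33, 0.45, 0.15)

  perfect <- new("ImputedGenotypes",
                 dosage = matrix(as.numeric(orig), N, S),
                 hardCalls = orig, maskedSites = masked,
                 positions = pos, sampleIds = paste0("S", 1:N))
  cc <- imputationConcordance(perfect, mask, refF)
  expect_equal(cc$overall, 100)
  expect_true(all(cc$perBin$concordance[cc$perBin$n > 0] == 100))

  ## site with MAF 0.0005 lands in the rare bin under default edges
  expect_gt(cc$perBin$n[cc$perBin$bin == "rare"], 0)

  wrong <- perfect
  wrong@hardCalls[, masked] <- (orig[, masked] + 1L) %% 3L
  cw <- imputationConcordance(wrong, mask, refF)
  expect_equal(cw$overall, 0)

  ## bin-weighted aggregation equals the overall concordance
  noisy <- perfect
  noisy@hardCalls[1, masked[1]] <- (orig[1, masked[1]] + 1L) %% 3L
  cn <- imputationConcordance(noisy, mask, refF)
  pb <- cn$perBin[cn$perBin$n > 0, ]
  expect_equal(sum(pb$concordance * pb$n) / sum(pb$n), cn$overall,
               tolerance = 1e-9)

  empty <- new("MaskSet", maskedSites = integer(0),
               original = orig[, integer(0), drop = FALSE])
  expect_error(imputationConcordance(perfect, empty, refF), "zero masked")
})

test_that("genotype-flip noise degrades concordance monotonically", {
  set.seed(12)
  S <- 400; N <- 10
  orig <- matrix(sample(0:2, N * S, replace = TRUE), N, S)
  masked <- seq_len(S)
  mask <- new("MaskSet", maskedSites = masked, original = orig)
  refF <- runif(S, 0.05, 0.5)
  conc <- sapply(c(0, 0.1, 0.2, 0.4), function(q) {
    hard <- orig
    flip <- matrix(runif(N * S) < q, N, S)
    hard[flip] <- (orig[flip] + 1L) %% 3L
    im <- new("ImputedGenotypes", dosage = matrix(as.numeric(hard), N, S),
              hardCalls = hard, maskedSites = masked,
              positions = seq_len(S), sampleIds = paste0("S", 1:N))
    imputationConcordance(im, mask, refF)$overall
  })
  expect_true(all(diff(conc) < 0))
  expect_equal(conc[1], 100)
})

test_that("Kruskal-Wallis wrapper matches the rank formula", {
  same <- kruskalWallisCompare(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(same$H, 1e-9)

  g <- list(a = c(1, 2, 3), b = c(10, 20, 30), c = c(100, 200, 300))
  kw <- kruskalWallisCompare(g)
  ## hand computation: no ties, ranks 1..9 in blocks
  N <- 9
  rbar <- c(2, 5, 8)
  H <- 12 / (N * (N + 1)) * sum(3 * (rbar - (N + 1) / 2)^2)
  expect_equal(kw$H, H, tolerance = 1e-8)
  expect_equal(kw$p.value, pchisq(H, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(nrow(kw$pairwise), 3)

  expect_error(kruskalWallisCompare(list(a = 1:3)), "two groups")
  expect_error(kruskalWallisCompare(list(a = 1:3, b = numeric(0))),
               "at least one value")
})

test_that("the experiment grid covers every condition and is reproducible", {
  st <- simulateStudy(seed = 31, regionLength = 1.2e5, refHaps = 60,
                      nTrios = 3, nChip = 4, nHotspots = 4, chipNRare = 40)
  maps <- list(constant = constantMap("chr1", 1.2e5, 1),
               external = st$generatingMap,
               estimated = hotspotMap("chr1", 1.2e5, 0.3, 50, 3, seed = 99))
  r1 <- experimentGrid(st$cohort, st$chip, st$ref, maps,
                       params = HmmParams(1e4, 1e-3), seed = 5,
                       nIter = 6, nBurn = 3)
  ## 3 maps x {none, ref} phasing conditions; 3 imputation map conditions
  cond <- unique(r1@phasing[c("map", "panel")])
  expect_equal(nrow(cond), 6)
  expect_setequal(unique(r1@imputation$map), names(maps))
  expect_equal(nrow(r1@phasing), 6 * 3)
  expect_true(all(r1@tests$p.value >= 0 & r1@tests$p.value <= 1))

  r2 <- experimentGrid(st$cohort, st$chip, st$ref, maps,
                       params = HmmParams(1e4, 1e-3), seed = 5,
                       nIter = 6, nBurn = 3)
  expect_identical(r1@phasing, r2@phasing)
  expect_identical(r1@imputation, r2@imputation)
})
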