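test_that("HmmParams validates its ranges", {
  expect_error(HmmParams(eps = 0.7), "strictly between")
  expect_error(HmmParams(ne = -5), "positive")
  expect_s4_class(HmmParams(), "HmmParams")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(21)
  for (inst in 1:5) {
    K <- sample(2:3, 1)
    S <- 3
    refs <- matrix(rbinom(K * S, 1, 0.5), K, S)
    pos <- sort(sample(1000:90000, S))
    map <- constantMap("chr1", 1e5, runif(1, 5, 60))
    par <- HmmParams(1e4, 1e-3)
    target <- rbinom(S, 1, 0.5)
    fb <- lsForwardBackward(target, refs, map, par, sitePos = pos)

    ## brute force over all K^S copying paths
    cm <- interpolateCm(map, pos)
    s <- 1 - exp(-4 * 1e4 * diff(cm) / 100 / K)
    em <- function(k, j) ifelse(refs[k, j] == target[j], 1 - 1e-3, 1e-3)
    tot <- 0
    for (path in asplit(as.matrix(expand.grid(rep(list(1:K), S))), 1)) {
      p <- em(path[1], 1) / K
      for (j in 2:S)
        p <- p * ((1 - s[j - 1]) * (path[j] == path[j - 1]) + s[j - 1] / K) *
          em(path[j], j)
      tot <- tot + p
    }
    expect_equal(fb$logLik, unname(log(tot)), tolerance = 1e-10)
    expect_true(all(abs(colSums(fb$posterior) - 1) < 1e-9))
  }
})

test_that("the copying posterior locks onto an identical reference", {
  S <- 20
  ## distinct references: the target equals reference 2 everywhere, the
  ## others disagree with it at every site or at alternating sites
  r2 <- rep(c(0L, 1L), length.out = S)
  refs <- rbind(1L - r2, r2, rep(1L, S))
  pos <- seq(2000, by = 4800, length.out = S)
  map <- constantMap("chr1", 1e5, 0.01)      # tight linkage
  fb <- lsForwardBackward(r2, refs, map, HmmParams(1e4, 1e-4),
                          sitePos = pos)
  expect_true(all(fb$posterior[2, ] >= 0.99))
})

test_that("missing sites emit uniformly", {
  S <- 10
  refs <- matrix(rbinom(2 * S, 1, 0.5), 2, S)
  pos <- seq(1000, by = 1000, length.out = S)
  fb <- lsForwardBackward(rep(NA_integer_, S), refs,
                          constantMap("chr1", 2e4, 1), HmmParams(),
                          sitePos = pos)
  expect_true(all(abs(fb$posterior - 0.5) < 1e-12))
  expect_equal(fb$logLik, 0, tolerance = 1e-12)
})

test_that("total switch intensity depends only on the total genetic length", {
  hs <- hotspotMap("chr1", 2e5, 0.2, 120, 6, seed = 13)
  cm <- constantMap("chr1", 2e5, totalCm(hs) / 0.2)   # equal total cM
  pos <- c(1, seq(1000, 199000, by = 997), 2e5 + 1)  # spans both maps fully
  i1 <- switchIntensity(hs, pos, 1e4, 20)
  i2 <- switchIntensity(cm, pos, 1e4, 20)
  ## the interval distances redistribute but their sum is the total span
  expect_equal(i1, i2, tolerance = 1e-6)
  expect_equal(i1, 4 * 1e4 * totalCm(hs) / 100 / 20, tolerance = 1e-9)
})

test_that("phasing solves cohorts with a unique consistent phase", {
  set.seed(3)
  A <- rbinom(40, 1, .5); B <- 1L - A
  pos <- sort(sample(1:2e5, 40))
  ## uniformly tight linkage: with weak links the sampler can lock into a
  ## mode with a spurious switch at the weakest gap (see the vignette)
  map <- constantMap("chr1", 2e5, 0.005)
  tp <- new("TruthPhase", hap1 = as.numeric(A), hap2 = as.numeric(B),
            resolvableMask = rep(TRUE, 40), inconsistentSites = integer(0))

  ## single individual with a reference containing both true haplotypes
  gm1 <- GenotypeMatrix(matrix(A + B, 1, 40), pos, "X")
  ref <- HaplotypePanel(rbind(A, B, A, B), pos)
  ph <- phaseCohort(gm1, map, HmmParams(1e4, 1e-3), ref = ref,
                    nIter = 12, nBurn = 6, seed = 9)
  expect_equal(switchErrorRate(rbind(ph@hap1[1, ], ph@hap2[1, ]), tp), 0)
  expect_true(all(ph@hap1[1, ] + ph@hap2[1, ] == genotypes(gm1)[1, ]))
  expect_true(all(ph@certainty[1, ] >= 0.5 & ph@certainty[1, ] <= 1))

  ## no reference, but homozygous anchors in the cohort
  pairs <- list(c("A", "A"), c("B", "B"), c("A", "B"), c("A", "B"),
                c("A", "B"), c("B", "B"), c("A", "A"), c("A", "B"))
  hap <- list(A = A, B = B)
  G <- t(sapply(pairs, function(p) hap[[p[1]]] + hap[[p[2]]]))
  gm <- GenotypeMatrix(G, pos)
  ph2 <- phaseCohort(gm, map, HmmParams(1e4, 1e-3), nIter = 12, nBurn = 6,
                     seed = 9)
  for (i in which(sapply(pairs, function(p) p[1] != p[2])))
    expect_equal(switchErrorRate(rbind(ph2@hap1[i, ], ph2@hap2[i, ]), tp), 0)

  ## determinism
  ph3 <- phaseCohort(gm, map, HmmParams(1e4, 1e-3), nIter = 12, nBurn = 6,
                     seed = 9)
  expect_identical(ph2@hap1, ph3@hap1)
  expect_identical(ph2@hap2, ph3@hap2)

  ## a lone individual without reference is a warning, not an error
  expect_warning(phaseCohort(gm1, map, HmmParams(), nIter = 3, nBurn = 1,
                             seed = 2), "templates")
})

test_that("a reference panel reduces switch error on simulated cohorts", {
  sers <- sapply(1:3, function(rep) {
    st <- simulateStudy(seed = 7000 + rep, regionLength = 2e5, refHaps = 150,
                        nTrios = 6, nChip = 2, nHotspots = 5)
    G <- genotypes(st$cohort)
    tr <- st$cohort@trios
    ids <- sampleIds(G)
    childG <- GenotypeMatrix(genotypes(G)[match(tr$child, ids), ,
                                          drop = FALSE],
                             positions(G), tr$child, "chr1")
    truths <- lapply(seq_len(nrow(tr)), function(k)
      mendelianPhaseChild(genotypes(G)[match(tr$father[k], ids), ],
                          genotypes(G)[match(tr$mother[k], ids), ],
                          genotypes(G)[match(tr$child[k], ids), ]))
    refIdx <- match(positions(childG), positions(st$ref))
    ref <- HaplotypePanel(haplotypes(st$ref)[, refIdx, drop = FALSE],
                          positions(childG))
    out <- sapply(list(NULL, ref), function(r) {
      ph <- phaseCohort(childG, st$generatingMap, HmmParams(1e4, 1e-3),
                        ref = r, nIter = 12, nBurn = 6, seed = 7100 + rep)
      mean(sapply(seq_len(nrow(tr)), function(k)
        switchErrorRate(rbind(ph@hap1[k, ], ph@hap2[k, ]), truths[[k]])),
        na.rm = TRUE)
    })
    out
  })
  expect_lt(mean(sers[2, ]), mean(sers[1, ]))   # panel beats no panel
})

test_that("imputation recovers masked sites from a perfect reference", {
  set.seed(8)
  S <- 20
  h1 <- rbinom(S, 1, .5); h2 <- rbinom(S, 1, .5)
  pos <- sort(sample(1:5e4, S))
  filler <- matrix(rbinom(6 * S, 1, .5), 6, S)
  ref <- HaplotypePanel(rbind(h1, h2, filler), pos)
  gm <- GenotypeMatrix(matrix(h1 + h2, 1, S), pos, "T1")
  mk <- maskRandom(gm, 0.10, seed = 3)
  map <- constantMap("chr1", 5e4, 0.05)
  par <- HmmParams(1e4, 1e-4)
  ph <- phaseCohort(mk$masked, map, par, ref = ref, nIter = 8, nBurn = 3,
                    seed = 4)
  im <- imputeMasked(mk$masked, mk$mask, ref, map, par, ph)
  expect_identical(im@hardCalls[, mk$mask@maskedSites, drop = FALSE],
                   mk$mask@original)
  expect_true(all(im@dosage >= 0 & im@dosage <= 2, na.rm = TRUE))
  ## unmasked genotypes pass through unchanged
  un <- setdiff(seq_len(S), mk$mask@maskedSites)
  expect_equal(im@dosage[, un], as.numeric((h1 + h2)[un]))
})

test_that("degrading the emission model degrades imputation concordance", {
  conc_at_eps <- function(eps) {
    mean(sapply(1:3, function(rep) {
      p <- simulatePanel(60, 5e4, constantMap("chr1", 5e4, 1), 1e-3,
                         seed = 8800 + rep)
      keep <- mafFilter(p, 0.05)
      pp <- HaplotypePanel(haplotypes(p)[, keep, drop = FALSE],
                           positions(p)[keep])
      ref <- HaplotypePanel(haplotypes(pp)[1:50, , drop = FALSE],
                            positions(pp))
      tg <- haplotypes(pp)[51:60, , drop = FALSE]
      gm <- GenotypeMatrix(tg[seq(1, 9, 2), , drop = FALSE] +
                           tg[seq(2, 10, 2), , drop = FALSE],
                           positions(pp))
      mk <- maskRandom(gm, 0.10, seed = 8900 + rep)
      par <- HmmParams(1e4, eps)
      map <- constantMap("chr1", 5e4, 1)
      ph <- phaseCohort(mk$masked, map, par, ref = ref, nIter = 8,
                        nBurn = 3, seed = 9000 + rep)
      im <- imputeMasked(mk$masked, mk$mask, ref, map, par, ph)
      imputationConcordance(im, mk$mask, alleleFreqs(ref))$overall
    }))
  }
  good <- conc_at_eps(1e-3)
  bad <- conc_at_eps(0.4)
  expect_lte(bad, good)
})

test_that("flipping a haplotype pair changes neither genotype nor SER", {
  set.seed(10)
  S <- 15
  t1 <- rbinom(S, 1, .5); t2 <- rbinom(S, 1, .5)
  tp <- new("TruthPhase", hap1 = as.numeric(t1), hap2 = as.numeric(t2),
            resolvableMask = rep(TRUE, S), inconsistentSites = integer(0))
  e1 <- rbinom(S, 1, .5); e2 <- 1L - e1
  expect_equal(switchErrorRate(rbind(e1, e2), tp),
               switchErrorRate(rbind(e2, e1), tp))
  expect_identical(e1 + e2, (e2 + e1))
})
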