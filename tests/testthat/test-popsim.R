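test_that("the coalescent simulator is reproducible and well-formed", {
  m <- constantMap("chr1", 5e4, 1)
  p1 <- simulatePanel(12, 5e4, m, 1e-3, seed = 5)
  p2 <- simulatePanel(12, 5e4, m, 1e-3, seed = 5)
  expect_identical(haplotypes(p1), haplotypes(p2))
  expect_identical(positions(p1), positions(p2))
  p3 <- simulatePanel(12, 5e4, m, 1e-3, seed = 6)
  expect_false(identical(positions(p1), positions(p3)))
  expect_true(all(haplotypes(p1) %in% 0:1))
  expect_true(all(diff(positions(p1)) > 0))
  expect_error(simulatePanel(10, 1e5, m, 1e-3, seed = 1), "map coverage")
})

test_that("without recombination every site pair passes the four-gamete test", {
  m0 <- constantMap("chr1", 3e4, 0)
  for (seed in 1:10) {
    p <- simulatePanel(8, 3e4, m0, 2e-3, seed = seed)
    expect_false(violates_four_gamete(haplotypes(p)))
  }
})

test_that("site frequency spectrum follows the neutral 1/i shape", {
  ## n_hap = 10, 1000 replicates; per-class goodness of fit at alpha =
  ## 0.01 against E[xi_i] = theta*L/i.  Sites within a replicate share a
  ## genealogy, so class variances are taken empirically across
  ## replicates rather than assumed multinomial.
  m0 <- constantMap("chr1", 1e4, 0)
  nrep <- 1000
  counts <- matrix(0, nrep, 9)
  for (r in seq_len(nrep)) {
    p <- simulatePanel(10, 1e4, m0, 1e-3, seed = 40000 + r)
    counts[r, ] <- tabulate(colSums(haplotypes(p)), nbins = 9)
  }
  expected <- 1e-3 * 1e4 / (1:9)
  z <- (colMeans(counts) - expected) / (apply(counts, 2, sd) / sqrt(nrep))
  chi2 <- sum(z^2)
  expect_lt(chi2, qchisq(0.99, df = 9))
})

test_that("LD decays with distance when recombination is present", {
  ## mean r2 per distance tercile, averaged over replicates
  L <- 3e4
  m <- constantMap("chr1", L, 40 / L / (4 * 1e4) * 1e8)  # rho 40 per region
  bins <- matrix(0, 200, 3)
  for (r in 1:200) {
    p <- simulatePanel(20, L, m, 2e-3, seed = 50000 + r)
    H <- haplotypes(p)
    keep <- colSums(H) >= 2 & colSums(H) <= 18
    H <- H[, keep, drop = FALSE]
    pos <- positions(p)[keep]
    if (ncol(H) < 6) { bins[r, ] <- NA; next }
    r2 <- suppressWarnings(cor(H))^2
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    d <- pos[ut[, 2]] - pos[ut[, 1]]
    cl <- cut(d, c(0, L / 3, 2 * L / 3, L), labels = FALSE)
    v <- r2[ut]
    bins[r, ] <- tapply(v, factor(cl, levels = 1:3), mean, na.rm = TRUE)
  }
  mean_r2 <- colMeans(bins, na.rm = TRUE)
  expect_true(all(diff(mean_r2) < 0))
})

test_that("meiosis respects the genetic map", {
  pos <- seq(1000, 99000, by = 2000)
  parent <- rbind(rep(0L, length(pos)), rep(1L, length(pos)))

  ## 0 cM: the gamete is one intact parental haplotype
  g0 <- meiosis(parent, pos, constantMap("chr1", 1e5, 0), seed = 3)
  expect_true(all(g0 == 0L) || all(g0 == 1L))

  ## 100 cM total: crossover count is Poisson with mean 1
  m1 <- constantMap("chr1", 1e5, 1000)   # 1000 cM/Mb over 0.1 Mb = 100 cM
  nx <- vapply(1:2000, function(s)
    length(attr(meiosis(parent, pos, m1, seed = s), "crossovers")),
    numeric(1))
  se <- sqrt(1 / 2000)
  expect_lt(abs(mean(nx) - 1), 3 * se)

  ## crossovers never fall inside zero-rate intervals
  mz <- GeneticMap("chr1", c(1, 3e4, 7e4, 1e5), c(50, 0, 50))
  xo <- unlist(lapply(1:300, function(s)
    attr(meiosis(parent, pos, mz, seed = 10000 + s), "crossovers")))
  expect_true(all(xo <= 3e4 | xo >= 7e4))
})

test_that("trio cohorts have the stated structure and Mendelian consistency", {
  map <- constantMap("chr1", 3e4, 1)
  panel <- simulatePanel(220, 3e4, map, 1e-3, seed = 8)
  co <- makeTrioCohort(panel, 55, map, seed = 9)
  tr <- co@trios
  expect_equal(nrow(tr), 55)
  expect_equal(length(unique(c(tr$father, tr$mother))), 110)
  G <- genotypes(genotypes(co))
  ids <- sampleIds(genotypes(co))
  for (k in seq_len(55)) {
    f <- G[match(tr$father[k], ids), ]
    m <- G[match(tr$mother[k], ids), ]
    c_ <- G[match(tr$child[k], ids), ]
    truth <- co@childTruth[[tr$child[k]]]
    expect_identical(as.integer(colSums(truth)), c_)
    ## each child allele must be transmissible from the right parent
    expect_true(all((f == 1) | (truth[1, ] == f / 2)))
    expect_true(all((m == 1) | (truth[2, ] == m / 2)))
  }
  ## identical seed reproduces the cohort
  co2 <- makeTrioCohort(panel, 55, map, seed = 9)
  expect_identical(genotypes(genotypes(co2)), G)
  expect_error(makeTrioCohort(panel, 60, map, seed = 1), "at least")
})

test_that("thinSites applies the greedy minimum-gap rule", {
  expect_equal(thinSites(c(100, 110, 130)), c(1L, 3L))
  expect_equal(thinSites(c(10, 25, 40), 15), 1:3)   # gaps of exactly 15 kept
  expect_equal(thinSites(numeric(0)), integer(0))
  expect_equal(thinSites(c(1, 5, 9, 30, 31), 15), c(1L, 4L))
})

test_that("mafFilter keeps the 5 percent boundary and drops below it", {
  H <- matrix(0L, 100, 4)
  H[1:4, 1] <- 1L    # MAF 0.04 -> removed
  H[1:5, 2] <- 1L    # MAF 0.05 -> kept
  H[1:50, 3] <- 1L   # MAF 0.50 -> kept
  ##             4: monomorphic -> removed
  panel <- HaplotypePanel(H, c(10, 20, 30, 40))
  expect_equal(mafFilter(panel), c(2L, 3L))
  expect_warning(kept <- mafFilter(HaplotypePanel(H[, 4, drop = FALSE],
                                                  5), 0.05), "removed")
  expect_length(kept, 0)
  allHalf <- HaplotypePanel(H[, c(3, 3, 3)] , c(1, 2, 3))
  expect_equal(mafFilter(allHalf), 1:3)
})

test_that("masking removes whole columns and restores bit-exactly", {
  set.seed(4)
  G <- matrix(sample(0:2, 5 * 1000, replace = TRUE), 5, 1000)
  gm <- GenotypeMatrix(G, seq_len(1000) * 10)
  mk0 <- maskRandom(gm, 0, seed = 1)
  expect_length(mk0$mask@maskedSites, 0)
  expect_identical(genotypes(mk0$masked), genotypes(gm))

  mk <- maskRandom(gm, 0.10, seed = 2)
  expect_length(mk$mask@maskedSites, 100)
  expect_true(all(is.na(genotypes(mk$masked)[, mk$mask@maskedSites])))
  restored <- restoreMasked(mk$masked, mk$mask)
  expect_identical(genotypes(restored), genotypes(gm))

  mk2 <- maskRandom(gm, 0.10, seed = 2)
  expect_identical(mk$mask@maskedSites, mk2$mask@maskedSites)
  expect_error(maskRandom(gm, 1.5, seed = 1), "0, 1")
})

test_that("chip site selection is common-tagged with stratified rare content", {
  p <- simulatePanel(200, 1e5, constantMap("chr1", 1e5, 1), 1e-3, seed = 33)
  cs <- chipSubset(p, minMaf = 0.05, minGapBp = 1000)
  maf <- pmin(alleleFreqs(p), 1 - alleleFreqs(p))
  expect_true(all(maf[cs] >= 0.05 - 1e-12))
  expect_true(all(diff(positions(p)[cs]) >= 1000))

  cs2 <- chipSites(p, tagMinMaf = 0.05, tagGapBp = 500,
                   rareRange = c(0.005, 0.05), nRare = 40, seed = 3)
  expect_true(all(diff(cs2) > 0))
  expect_true(any(maf[cs2] < 0.05))          # rare content present
  expect_identical(cs2, chipSites(p, tagMinMaf = 0.05, tagGapBp = 500,
                                  rareRange = c(0.005, 0.05), nRare = 40,
                                  seed = 3))
})
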