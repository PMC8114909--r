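#' Resolve a child's true haplotypes from trio genotypes
#'
#' At each site the child's phase is assigned whenever Mendelian logic is
#' decisive: any configuration except all-three-heterozygous or missing.
#' Mendelian violations are recorded and excluded from the resolvable
#' mask, not treated as fatal.
#'
#' @param father,mother,child integer genotype vectors (0/1/2/NA) on a
#'   shared site axis.
#' @return A [TruthPhase-class]; `hap1` holds the paternal, `hap2` the
#'   maternal allele.
#' @examples
#' tp <- mendelianPhaseChild(2L, 0L, 1L)  # paternal 1, maternal 0
#' @export
mendelianPhaseChild <- function(father, mother, child) {
  S <- length(child)
  stopifnot(length(father) == S, length(mother) == S)
  pat <- mat <- rep(NA_real_, S)
  mask <- rep(FALSE, S)
  viol <- rep(FALSE, S)
  obs <- !(is.na(father) | is.na(mother) | is.na(child))

  hom <- obs & child != 1L
  if (any(hom)) {
    a <- child[hom] / 2
    bad <- (father[hom] == 2 & a == 0) | (father[hom] == 0 & a == 1) |
           (mother[hom] == 2 & a == 0) | (mother[hom] == 0 & a == 1)
    viol[which(hom)[bad]] <- TRUE
    ok <- hom; ok[hom] <- !bad
    pat[ok] <- mat[ok] <- child[ok] / 2
    mask[ok] <- TRUE
  }

  het <- obs & child == 1L
  fhom <- het & father != 1L
  mhom <- het & mother != 1L
  both <- fhom & mhom
  if (any(both)) {
    p <- father[both] / 2; m <- mother[both] / 2
    bad <- p + m != 1
    viol[which(both)[bad]] <- TRUE
    ok <- both; ok[both] <- !bad
    pat[ok] <- father[ok] / 2
    mat[ok] <- mother[ok] / 2
    mask[ok] <- TRUE
  }
  fonly <- fhom & !mhom
  pat[fonly] <- father[fonly] / 2
  mat[fonly] <- 1 - pat[fonly]
  mask[fonly] <- TRUE
  monly <- mhom & !fhom
  mat[monly] <- mother[monly] / 2
  pat[monly] <- 1 - mat[monly]
  mask[monly] <- TRUE
  ## remaining het sites (both parents het) stay unresolvable

  new("TruthPhase", hap1 = pat, hap2 = mat, resolvableMask = mask,
      inconsistentSites = which(viol))
}

#' Switch error rate against trio-resolved truth
#'
#' Restricted to truth-resolvable heterozygous sites at which the
#' estimate is phased and heterozygous, the SER is the number of adjacent
#' site pairs whose relative phase disagrees with truth divided by the
#' number of such sites minus one.  A global flip of the two estimated
#' haplotypes is not an error.
#'
#' @param estimated 2 x S integer matrix (the estimated haplotype pair).
#' @param truth a [TruthPhase-class].
#' @return SER in \[0, 1\], or NA when fewer than two resolvable
#'   heterozygous sites are available.
#' @export
switchErrorRate <- function(estimated, truth) {
  stopifnot(is.matrix(estimated), nrow(estimated) == 2L,
            is(truth, "TruthPhase"))
  S <- ncol(estimated)
  if (length(truth@hap1) != S)
    stop("estimate and truth must share the site axis")
  use <- truth@resolvableMask &
    !is.na(truth@hap1) & !is.na(truth@hap2) & truth@hap1 != truth@hap2 &
    !is.na(estimated[1, ]) & !is.na(estimated[2, ]) &
    estimated[1, ] != estimated[2, ]
  idx <- which(use)
  H <- length(idx)
  if (H < 2L) return(NA_real_)
  mism <- estimated[1, idx] != truth@hap1[idx]
  sum(mism[-1] != mism[-H]) / (H - 1)
}

#' Imputation concordance by minor-allele-frequency bin
#'
#' Two metrics are reported per MAF bin (MAF taken from the reference
#' panel frequencies).  `concordance` is the percentage of masked hard
#' calls equal to the original genotype.  `nonrefConcordance` is the same
#' percentage restricted to calls whose original genotype carries the
#' reference-panel minor allele; at desk scale the call-level metric is
#' buffered by trivially-correct homozygous-reference calls at low MAF,
#' so the carrier-restricted metric is the one that resolves differences
#' between frequency classes.
#'
#' @param imputed an [ImputedGenotypes-class].
#' @param mask the [MaskSet-class] holding the original values.
#' @param refFreqs per-site alternate-allele frequencies of the reference
#'   panel (length = number of sites).
#' @param bins MAF bin edges (default 0, 0.001, 0.05, 0.5 labelled
#'   rare / low-frequency / common).
#' @return list: `overall` and `nonrefOverall` (percent), `perBin`
#'   data.frame (bin, concordance, nonrefConcordance, n, nCarrier; empty
#'   bins have NA concordance and n = 0) and `perSample` (sample,
#'   concordance).
#' @export
imputationConcordance <- function(imputed, mask, refFreqs,
                                  bins = c(0, 0.001, 0.05, 0.5)) {
  stopifnot(is(imputed, "ImputedGenotypes"), is(mask, "MaskSet"))
  ms <- mask@maskedSites
  if (!length(ms)) stop("zero masked calls")
  hard <- imputed@hardCalls[, ms, drop = FALSE]
  orig <- mask@original
  ok <- !is.na(orig) & !is.na(hard)
  if (!any(ok)) stop("zero masked calls with observed originals")
  agree <- hard == orig
  f <- refFreqs[ms]
  maf <- pmin(f, 1 - f)
  ## carrier = original genotype contains the reference-panel minor allele
  minorIsAlt <- matrix(f <= 0.5, nrow(orig), ncol(orig), byrow = TRUE)
  carrier <- ok & ifelse(minorIsAlt, orig > 0, orig < 2)
  labels <- if (length(bins) == 4L) c("rare", "low-frequency", "common")
            else paste0("bin", seq_len(length(bins) - 1L))
  binOf <- cut(maf, breaks = bins, labels = labels, include.lowest = TRUE)
  perBin <- data.frame(bin = labels, concordance = NA_real_,
                       nonrefConcordance = NA_real_, n = 0L, nCarrier = 0L)
  for (b in seq_along(labels)) {
    cols <- which(binOf == labels[b])
    sel <- ok[, cols, drop = FALSE]
    car <- carrier[, cols, drop = FALSE]
    agr <- agree[, cols, drop = FALSE]
    perBin$n[b] <- sum(sel)
    perBin$nCarrier[b] <- sum(car)
    if (sum(sel) > 0)
      perBin$concordance[b] <- 100 * sum(agr[sel]) / sum(sel)
    if (sum(car) > 0)
      perBin$nonrefConcordance[b] <- 100 * sum(agr[car]) / sum(car)
  }
  perSample <- data.frame(
    sample = imputed@sampleIds,
    concordance = 100 * rowSums(agree & ok) / rowSums(ok))
  list(overall = 100 * sum(agree[ok]) / sum(ok),
       nonrefOverall = if (any(carrier)) 100 * sum(agree[carrier]) /
                         sum(carrier) else NA_real_,
       perBin = perBin, perSample = perSample)
}

#' Kruskal-Wallis comparison of metric values across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom, with rank-sum (Wilcoxon) pairwise follow-ups.
#'
#' @param groups named list of >= 2 numeric vectors (each non-empty).
#' @return list: `H`, `p.value`, `pairwise` data.frame (groupA, groupB,
#'   W, p.value).
#' @export
kruskalWallisCompare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(lengths(groups) < 1L)) stop("every group needs at least one value")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 1L)) stop("every group needs at least one value")
  kt <- kruskal.test(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pw <- NULL
  for (a in seq_len(length(groups) - 1L)) for (b in (a + 1):length(groups)) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[a]], groups[[b]]))
    pw <- rbind(pw, data.frame(groupA = nm[a], groupB = nm[b],
                               W = unname(wt$statistic),
                               p.value = wt$p.value))
  }
  list(H = unname(kt$statistic), p.value = kt$p.value, pairwise = pw)
}

#' Run the full phasing / imputation condition grid
#'
#' Phasing arm: the cohort's children are statistically phased under each
#' map, with and without the reference panel, and scored by switch error
#' against trio-resolved truth.  Imputation arm: about 10 percent of the
#' chip's variants are masked, the masked chip is phased with the panel
#' and imputed under each map, and masked-call concordance is scored by
#' MAF bin.  Kruskal-Wallis comparisons are run across maps within each
#' arm.
#'
#' @param cohort a [TrioCohort-class].
#' @param chip a [GenotypeMatrix-class] of chip-like genotypes.
#' @param ref a [HaplotypePanel-class] whose site axis covers (is a
#'   superset of) both the cohort's and the chip's positions; it is
#'   subset to each axis internally.
#' @param maps named list of [GeneticMap-class] objects (e.g. constant,
#'   external, estimated).
#' @param params an [HmmParams-class].
#' @param seed integer seed.
#' @param nIter,nBurn phasing sweeps (passed to [phaseCohort()]).
#' @param maskFraction fraction of chip variants to mask (default 0.10).
#' @param bins MAF bin edges for concordance.
#' @return An [EvalReport-class].
#' @export
experimentGrid <- function(cohort, chip, ref, maps, params = HmmParams(),
                           seed = 1, nIter = 20, nBurn = 10,
                           maskFraction = 0.10,
                           bins = c(0, 0.001, 0.05, 0.5)) {
  stopifnot(is(cohort, "TrioCohort"), is(chip, "GenotypeMatrix"),
            is(ref, "HaplotypePanel"), is.list(maps), length(maps) >= 1L,
            !is.null(names(maps)))
  G <- genotypes(cohort)
  ids <- sampleIds(G)
  tr <- cohort@trios
  childG <- GenotypeMatrix(genotypes(G)[match(tr$child, ids), , drop = FALSE],
                           positions(G), tr$child, chromName(G))
  truths <- lapply(seq_len(nrow(tr)), function(k)
    mendelianPhaseChild(genotypes(G)[match(tr$father[k], ids), ],
                        genotypes(G)[match(tr$mother[k], ids), ],
                        genotypes(G)[match(tr$child[k], ids), ]))
  names(truths) <- tr$child

  ## reference panel restricted to the cohort's site axis
  cohortRefIdx <- match(positions(childG), positions(ref))
  if (anyNA(cohortRefIdx))
    stop("cohort sites must all be present in the reference panel")
  cohortRef <- HaplotypePanel(
    haplotypes(ref)[, cohortRefIdx, drop = FALSE],
    positions(childG), chromName(ref))

  phasing <- NULL
  for (mname in names(maps)) {
    for (panel in c("none", "ref")) {
      ph <- phaseCohort(childG, maps[[mname]], params,
                        ref = if (panel == "ref") cohortRef else NULL,
                        nIter = nIter, nBurn = nBurn,
                        seed = .derive_seed(seed, paste0("ph", mname, panel)))
      ser <- vapply(seq_along(tr$child), function(k)
        switchErrorRate(rbind(ph@hap1[k, ], ph@hap2[k, ]),
                        truths[[tr$child[k]]]), numeric(1))
      phasing <- rbind(phasing,
                       data.frame(map = mname, panel = panel,
                                  sample = tr$child, ser = ser))
    }
  }

  ## imputation arm
  mk <- maskRandom(chip, maskFraction, .derive_seed(seed, "mask"))
  chipRefIdx <- match(positions(chip), positions(ref))
  if (anyNA(chipRefIdx))
    stop("chip sites must all be present in the reference panel")
  chipRef <- HaplotypePanel(haplotypes(ref)[, chipRefIdx, drop = FALSE],
                            positions(chip), chromName(chip))
  refF <- alleleFreqs(chipRef)
  imputation <- NULL
  perSampleConc <- list()
  for (mname in names(maps)) {
    ph <- phaseCohort(mk$masked, maps[[mname]], params, ref = chipRef,
                      nIter = nIter, nBurn = nBurn,
                      seed = .derive_seed(seed, paste0("imp", mname)))
    im <- imputeMasked(mk$masked, mk$mask, chipRef, maps[[mname]], params, ph)
    cc <- imputationConcordance(im, mk$mask, refF, bins)
    pb <- cc$perBin
    pb$overall <- cc$overall
    imputation <- rbind(imputation, cbind(data.frame(map = mname), pb))
    perSampleConc[[mname]] <- cc$perSample$concordance
  }

  tests <- NULL
  if (length(maps) >= 2L) {
    for (panel in c("none", "ref")) {
      gr <- split(phasing$ser[phasing$panel == panel],
                  phasing$map[phasing$panel == panel])
      gr <- lapply(gr, function(x) x[!is.na(x)])
      if (all(lengths(gr) >= 1L)) {
        kw <- kruskalWallisCompare(gr)
        tests <- rbind(tests, data.frame(
          arm = "phasing", comparison = paste0("maps|panel=", panel),
          statistic = kw$H, p.value = kw$p.value))
      }
    }
    kw <- kruskalWallisCompare(perSampleConc)
    tests <- rbind(tests, data.frame(
      arm = "imputation", comparison = "maps",
      statistic = kw$H, p.value = kw$p.value))
  }
  if (is.null(tests))
    tests <- data.frame(arm = character(), comparison = character(),
                        statistic = numeric(), p.value = numeric())

  new("EvalReport", phasing = phasing, imputation = imputation,
      tests = tests)
}
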