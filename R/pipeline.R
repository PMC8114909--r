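#' Simulate the full study inputs: map, panels, trios and chip
#'
#' Builds everything the downstream comparisons consume from one seed: a
#' hotspot-structured generating map; a coalescent haplotype panel under
#' that map; a reference panel (first `refHaps` haplotypes); a trio
#' cohort produced by map-driven meiosis on an array-density evaluation
#' site axis (thin 15 bp, MAF filter, then `evalGapBp` spacing); and a
#' chip-like genotype matrix of separate individuals on [chipSites()].
#' The reference panel is returned on the full thinned axis, a superset
#' of both the evaluation and chip axes, so one panel serves phasing and
#' imputation.
#'
#' @param seed integer root seed (per-stage seeds are derived from it).
#' @param regionLength region length in bp.
#' @param thetaBp scaled mutation rate per bp.
#' @param ne diploid effective population size.
#' @param refHaps reference-panel haplotypes.
#' @param nTrios trios in the cohort; parents use `4 * nTrios` panel
#'   haplotypes disjoint from the reference.
#' @param nChip chip individuals (2 further haplotypes each).
#' @param backgroundRate,hotspotRate,nHotspots,hotspotWidth generating-map
#'   shape (see [hotspotMap()]).
#' @param thinGap,minMaf,evalGapBp evaluation-axis filters: physical
#'   thinning, MAF floor, and array-density spacing.
#' @param chipTagMinMaf,chipTagGapBp,chipRareRange,chipRareSplit,chipNRare
#'   chip composition (see [chipSites()]).
#' @param chrom chromosome label.
#' @return list with elements `generatingMap`, `panel` (raw),
#'   `ref` (thinned axis), `cohort`, `chip`, `estPanel` (the trio
#'   parents' haplotypes on the raw axis, the map-estimation input) and
#'   `evalPanel`.
#' @export
simulateStudy <- function(seed = 1, regionLength = 4e5, thetaBp = 1e-3,
                          ne = 10000, refHaps = 500, nTrios = 16,
                          nChip = 40, backgroundRate = 0.05,
                          hotspotRate = 200, nHotspots = 8,
                          hotspotWidth = 1500, thinGap = 15, minMaf = 0.05,
                          evalGapBp = 800, chipTagMinMaf = 0.05,
                          chipTagGapBp = 300,
                          chipRareRange = c(0.0015, 0.05),
                          chipRareSplit = 0.004, chipNRare = 300,
                          chrom = "chr1") {
  gmap <- hotspotMap(chrom, regionLength, backgroundRate, hotspotRate,
                     nHotspots, hotspotWidth,
                     seed = .derive_seed(seed, "genmap"))
  need <- refHaps + 4 * nTrios + 2 * nChip
  panel <- simulatePanel(need, regionLength, gmap, thetaBp,
                         .derive_seed(seed, "panel"), ne = ne,
                         chrom = chrom)
  thin <- .sub_panel(panel, cols = thinSites(positions(panel), thinGap))
  ref <- .sub_panel(thin, rows = seq_len(refHaps))

  ## array-density evaluation axis for the trio cohort
  evalP <- .sub_panel(thin, cols = mafFilter(thin, minMaf))
  if (evalGapBp > thinGap)
    evalP <- .sub_panel(evalP, cols = thinSites(positions(evalP), evalGapBp))
  trioP <- .sub_panel(evalP, rows = refHaps + seq_len(4 * nTrios))
  cohort <- makeTrioCohort(trioP, nTrios, gmap,
                           seed = .derive_seed(seed, "trios"))

  ## chip individuals on the full-spectrum thinned axis
  cs <- chipSites(thin, chipTagMinMaf, chipTagGapBp, chipRareRange,
                  chipRareSplit, chipNRare,
                  seed = .derive_seed(seed, "chip"))
  chipH <- haplotypes(thin)[refHaps + 4 * nTrios + seq_len(2 * nChip), ,
                            drop = FALSE]
  chip <- GenotypeMatrix(
    chipH[seq(1, 2 * nChip, 2), cs, drop = FALSE] +
      chipH[seq(2, 2 * nChip, 2), cs, drop = FALSE],
    positions(thin)[cs], paste0("CHIP", seq_len(nChip)), chrom)

  estPanel <- .sub_panel(panel, rows = refHaps + seq_len(4 * nTrios))
  list(generatingMap = gmap, panel = panel, ref = ref, cohort = cohort,
       chip = chip, estPanel = estPanel, evalPanel = evalP)
}

#' Build and validate a pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end run, validates all of
#' them against stage preconditions before any compute starts, and fixes
#' the single root seed from which per-stage seeds are derived.  The
#' defaults are a compact demonstration scale; the study-condition
#' defaults of [simulateStudy()] are larger.
#'
#' @param ... overrides of the defaults (see the function definition for
#'   the full list: simulation shape, filters, estimation windows, chip
#'   composition, HMM and sweep settings, MAF bins, seed).
#' @return validated configuration list (class `runConfig`).
#' @export
runConfig <- function(...) {
  cfg <- modifyList(list(
    chrom = "chr1", regionLength = 2.5e5, thetaBp = 1e-3, ne = 10000,
    refHaps = 150, nTrios = 16, nChip = 12,
    backgroundRate = 0.05, hotspotRate = 200, nHotspots = 6,
    hotspotWidth = 1500,
    thinGap = 15, minMaf = 0.05, evalGapBp = 800,
    segmentSnps = 10000, overhangSnps = 1000,
    windowBp = 50000, stepBp = 25000, maxPairSpan = 50000,
    lookupReps = 12000, trainWindows = 210, thetaLocus = 0.2,
    chipTagMinMaf = 0.05, chipTagGapBp = 300,
    chipRareRange = c(0.0015, 0.05), chipRareSplit = 0.004,
    chipNRare = 150, maskFraction = 0.10,
    eps = 1e-3, nIter = 16, nBurn = 8,
    bins = c(0, 0.004, 0.05, 0.5),
    compareWindowBp = 25000, seed = 1), list(...))
  with(cfg, {
    stopifnot(regionLength > 0, thetaBp > 0, ne > 0,
              refHaps >= 2, nTrios >= 1, nChip >= 1,
              thinGap >= 0, minMaf >= 0, minMaf < 0.5, evalGapBp >= 0,
              segmentSnps > 2 * overhangSnps,
              windowBp > 0, stepBp > 0, maxPairSpan > 0,
              lookupReps > 0, trainWindows >= 200,
              chipTagMinMaf >= 0, chipTagGapBp > 0, chipNRare >= 0,
              eps > 0, eps < 0.5, nIter > nBurn, nBurn >= 0,
              length(bins) >= 2, all(diff(bins) > 0),
              compareWindowBp > 0, length(seed) == 1)
    if (maskFraction < 0 || maskFraction > 1)
      stop("maskFraction must lie in [0, 1]")
  })
  structure(cfg, class = "runConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline and write its artifact directory
#'
#' simulate -> estimate map (from the trio parents' haplotypes) ->
#' compare maps (estimated vs generating vs constant) -> phasing /
#' imputation condition grid -> evaluation report.  Every artifact is a
#' plain-text table, map file or JSON stamped with the configuration and
#' seed; rerunning with the same configuration yields a byte-identical
#' directory tree.
#'
#' @param config a [runConfig()] list.
#' @param outDir output directory (created if needed).
#' @return the [EvalReport-class], invisibly, with attribute `dir`;
#'   side effect: artifact files (generating_map.txt, estimated_map.txt,
#'   constant_map.txt, map_comparison.tsv, phasing_ser.tsv,
#'   imputation_concordance.tsv, group_tests.tsv, summary.json,
#'   provenance.json).
#' @export
runPipeline <- function(config = runConfig(), outDir) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cf <- config
  seed <- cf$seed

  study <- .stage("simulate",
    simulateStudy(seed = .derive_seed(seed, "study"),
                  regionLength = cf$regionLength, thetaBp = cf$thetaBp,
                  ne = cf$ne, refHaps = cf$refHaps, nTrios = cf$nTrios,
                  nChip = cf$nChip, backgroundRate = cf$backgroundRate,
                  hotspotRate = cf$hotspotRate, nHotspots = cf$nHotspots,
                  hotspotWidth = cf$hotspotWidth, thinGap = cf$thinGap,
                  minMaf = cf$minMaf, evalGapBp = cf$evalGapBp,
                  chipTagMinMaf = cf$chipTagMinMaf,
                  chipTagGapBp = cf$chipTagGapBp,
                  chipRareRange = cf$chipRareRange,
                  chipRareSplit = cf$chipRareSplit,
                  chipNRare = cf$chipNRare, chrom = cf$chrom))

  estMap <- .stage("estimate-map",
    estimateMap(study$estPanel, cf$ne, config = list(
      thinGap = cf$thinGap, minMaf = cf$minMaf,
      segmentSnps = cf$segmentSnps, overhangSnps = cf$overhangSnps,
      windowBp = cf$windowBp, stepBp = cf$stepBp,
      maxPairSpan = cf$maxPairSpan, thetaLocus = cf$thetaLocus,
      lookupReps = cf$lookupReps, trainWindows = cf$trainWindows,
      thetaBp = cf$thetaBp, seed = .derive_seed(seed, "estimate"))))

  constMap <- constantMap(cf$chrom, cf$regionLength, 1)
  genMap <- study$generatingMap

  comparison <- .stage("compare-maps", {
    ce <- compareMaps(estMap, genMap, cf$compareWindowBp)
    cc <- compareMaps(estMap, constMap, cf$compareWindowBp)
    data.frame(pair = c("estimated_vs_generating", "estimated_vs_constant"),
               spearman = c(ce$spearman, cc$spearman),
               meanA = c(ce$meanA, cc$meanA),
               meanB = c(ce$meanB, cc$meanB),
               ratio = c(ce$ratio, cc$ratio))
  })

  report <- .stage("experiment-grid",
    experimentGrid(study$cohort, study$chip, study$ref,
                   maps = list(constant = constMap, generating = genMap,
                               estimated = estMap),
                   params = HmmParams(cf$ne, cf$eps),
                   seed = .derive_seed(seed, "grid"),
                   nIter = cf$nIter, nBurn = cf$nBurn,
                   maskFraction = cf$maskFraction, bins = cf$bins))

  .stage("write-artifacts", {
    writeGeneticMap(genMap, file.path(outDir, "generating_map.txt"))
    writeGeneticMap(estMap, file.path(outDir, "estimated_map.txt"))
    writeGeneticMap(constMap, file.path(outDir, "constant_map.txt"))
    wt <- function(d, f) write.table(
      d, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(comparison, "map_comparison.tsv")
    wt(report@phasing, "phasing_ser.tsv")
    wt(report@imputation, "imputation_concordance.tsv")
    wt(report@tests, "group_tests.tsv")
    serTab <- stats::aggregate(ser ~ map + panel, data = report@phasing,
                               FUN = mean, na.rm = TRUE)
    summary <- list(
      map = list(estimatedMeanRate = totalCm(estMap) /
                   (diff(range(positions(estMap))) / 1e6),
                 generatingMeanRate = totalCm(genMap) /
                   (diff(range(positions(genMap))) / 1e6),
                 spearmanEstVsGenerating = comparison$spearman[1]),
      phasingSer = setNames(as.list(serTab$ser),
                            paste(serTab$map, serTab$panel, sep = "_")),
      imputationConcordance = setNames(
        as.list(report@imputation$concordance),
        paste(report@imputation$map, report@imputation$bin, sep = "_")),
      imputationNonrefConcordance = setNames(
        as.list(report@imputation$nonrefConcordance),
        paste(report@imputation$map, report@imputation$bin, sep = "_")))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    prov <- list(package = as.character(packageVersion("recombMap")),
                 config = unclass(config))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  attr(report, "dir") <- outDir
  invisible(report)
}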