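## Central S4 data containers.  Each class carries the invariants the rest
## of the pipeline relies on in its validity method, so that objects are
## checked at construction and after every transformation that rebuilds
## them with new().

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GeneticMap: positions with interval rates and cumulative genetic distance
#'
#' A genetic map for one chromosome: strictly increasing 1-based physical
#' positions (bp), a non-negative recombination rate in cM/Mb for each
#' interval `[positions[i], positions[i+1])`, and the cumulative genetic
#' distance in cM at each position (`cumulativeCm[1] == 0`).
#'
#' @slot chrom chromosome label.
#' @slot positions numeric, strictly increasing physical positions in bp.
#' @slot intervalRates numeric, cM/Mb per interval (length
#'   `length(positions) - 1`).
#' @slot cumulativeCm numeric, cM at each position, non-decreasing,
#'   starting at 0.
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(chrom = "character", positions = "numeric",
                 intervalRates = "numeric", cumulativeCm = "numeric"),
  validity = function(object) {
    p <- object@positions; r <- object@intervalRates; cm <- object@cumulativeCm
    if (length(object@chrom) != 1L) return("chrom must be a single label")
    if (length(p) < 2L) return("a map needs at least two positions")
    if (any(!is.finite(p))) return("positions must be finite")
    if (any(diff(p) <= 0)) return("positions must be strictly increasing")
    if (length(r) != length(p) - 1L)
      return("intervalRates must have length(positions) - 1 entries")
    if (any(!is.finite(r)) || any(r < 0))
      return("interval rates must be finite and >= 0")
    if (length(cm) != length(p))
      return("cumulativeCm must align with positions")
    if (abs(cm[1]) > 1e-12) return("cumulativeCm must start at 0")
    if (any(diff(cm) < -1e-12)) return("cumulativeCm must be non-decreasing")
    expect <- r * diff(p) / 1e6
    got <- diff(cm)
    tol <- 1e-6 * pmax(abs(expect), 1e-12)
    if (any(abs(got - expect) > tol))
      return("cumulativeCm increments disagree with intervalRates")
    TRUE
  })

#' RhoTrack: per-window population-scaled recombination-rate estimates
#'
#' Windowed estimates of the population-scaled recombination rate
#' rho = 4*Ne*r, expressed per bp, with a sampling variance and the number
#' of SNPs that informed each window.  Windows are half-open
#' `[start, end)`; in sliding mode they may overlap and are flagged so.
#'
#' @slot windowStart,windowEnd numeric, bp.
#' @slot rhoPerBp numeric, rho per bp per window (NA = missing estimate).
#' @slot variance numeric, sampling variance of each estimate.
#' @slot nSnps integer, SNPs per window.
#' @slot sliding logical(1), whether windows are allowed to overlap.
#' @exportClass RhoTrack
setClass("RhoTrack",
  representation(windowStart = "numeric", windowEnd = "numeric",
                 rhoPerBp = "numeric", variance = "numeric",
                 nSnps = "integer", sliding = "logical"),
  validity = function(object) {
    n <- length(object@windowStart)
    if (length(object@windowEnd) != n || length(object@rhoPerBp) != n ||
        length(object@variance) != n || length(object@nSnps) != n)
      return("all window vectors must have equal length")
    if (n == 0L) return("empty track")
    if (any(object@windowEnd <= object@windowStart))
      return("windows must satisfy start < end")
    if (any(object@rhoPerBp < 0, na.rm = TRUE)) return("rho must be >= 0")
    if (any(object@variance < 0, na.rm = TRUE)) return("variance must be >= 0")
    if (length(object@sliding) != 1L) return("sliding must be logical(1)")
    if (!object@sliding && n > 1L) {
      o <- order(object@windowStart)
      if (any(object@windowStart[o][-1] < object@windowEnd[o][-n]))
        return("windows overlap but sliding = FALSE")
    }
    TRUE
  })

#' HaplotypePanel: binary haplotype-by-site matrix
#'
#' @slot haplotypes integer matrix (n_hap x n_sites) with entries in {0, 1}.
#' @slot positions numeric, strictly increasing physical positions (bp).
#' @slot chrom chromosome label.
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(haplotypes = "matrix", positions = "numeric",
                 chrom = "character"),
  validity = function(object) {
    h <- object@haplotypes
    if (nrow(h) < 2L) return("a panel needs at least two haplotypes")
    if (ncol(h) != length(object@positions))
      return("positions must align with haplotype columns")
    if (length(object@positions) &&
        any(diff(object@positions) <= 0))
      return("positions must be strictly increasing")
    if (length(h) && !all(h %in% c(0L, 1L)))
      return("haplotype alleles must be 0/1")
    TRUE
  })

#' GenotypeMatrix: diploid genotypes with possible missingness
#'
#' @slot genotypes integer matrix (n_ind x n_sites), values 0/1/2 or NA.
#' @slot positions numeric, strictly increasing bp.
#' @slot chrom chromosome label.
#' @slot sampleIds character, one per row.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(genotypes = "matrix", positions = "numeric",
                 chrom = "character", sampleIds = "character"),
  validity = function(object) {
    g <- object@genotypes
    if (ncol(g) != length(object@positions))
      return("positions must align with genotype columns")
    if (nrow(g) != length(object@sampleIds))
      return("sampleIds must align with genotype rows")
    if (anyDuplicated(object@sampleIds)) return("sampleIds must be unique")
    if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
      return("positions must be strictly increasing")
    vals <- g[!is.na(g)]
    if (length(vals) && !all(vals %in% 0:2))
      return("genotypes must be 0, 1, 2 or NA")
    TRUE
  })

#' TrioCohort: father/mother/child genotypes with true child haplotypes
#'
#' @slot genotypes [GenotypeMatrix] over all trio members.
#' @slot trios data.frame with columns father, mother, child (sample IDs).
#' @slot childTruth named list (one per child) of 2 x n_sites integer
#'   matrices; row 1 is the paternally, row 2 the maternally transmitted
#'   haplotype.
#' @exportClass TrioCohort
setClass("TrioCohort",
  representation(genotypes = "GenotypeMatrix", trios = "data.frame",
                 childTruth = "list"),
  validity = function(object) {
    ids <- object@genotypes@sampleIds
    tr <- object@trios
    need <- c("father", "mother", "child")
    if (!all(need %in% names(tr))) return("trios needs father/mother/child")
    all_ids <- unlist(tr[need], use.names = FALSE)
    if (!all(all_ids %in% ids)) return("trio IDs must resolve to samples")
    if (!all(tr$child %in% names(object@childTruth)))
      return("childTruth must cover every child")
    S <- ncol(object@genotypes@genotypes)
    for (ch in tr$child) {
      m <- object@childTruth[[ch]]
      if (!is.matrix(m) || nrow(m) != 2L || ncol(m) != S)
        return("childTruth entries must be 2 x n_sites matrices")
      g <- object@genotypes@genotypes[match(ch, ids), ]
      ok <- is.na(g) | colSums(m) == g
      if (!all(ok)) return("childTruth inconsistent with child genotypes")
    }
    TRUE
  })

#' MaskSet: masked variant columns with their original values
#'
#' @slot maskedSites integer site (column) indices that were set missing.
#' @slot original integer matrix (n_ind x length(maskedSites)) holding the
#'   pre-masking genotype values, restorable bit-exactly.
#' @exportClass MaskSet
setClass("MaskSet",
  representation(maskedSites = "integer", original = "matrix"),
  validity = function(object) {
    if (ncol(object@original) != length(object@maskedSites))
      return("original must have one column per masked site")
    if (anyDuplicated(object@maskedSites)) return("masked sites must be unique")
    TRUE
  })

#' TwoLocusLookup: Monte-Carlo two-locus configuration likelihoods
#'
#' Configuration probabilities of two-locus derived-allele haplotype counts
#' under the coalescent, tabulated by Monte-Carlo simulation on a grid of
#' between-locus rho values.  Configurations are canonicalised over allele
#' relabelling at each locus and locus exchange.
#'
#' @slot nHap sample size the table was built for.
#' @slot rhoGrid increasing rho values.
#' @slot thetaLocus per-locus scaled mutation rate used in simulation.
#' @slot configs character keys "freqClassA:freqClassB:ldClass" (canonical binned form).
#' @slot probs numeric matrix (n_config x n_grid); columns sum to 1.
#' @slot nReps Monte-Carlo replicates per grid point.
#' @slot nKept integer, accepted (biallelic-at-both-loci) replicates per
#'   grid point.
#' @exportClass TwoLocusLookup
setClass("TwoLocusLookup",
  representation(nHap = "integer", rhoGrid = "numeric", thetaLocus = "numeric",
                 configs = "character", probs = "matrix", nReps = "integer",
                 nKept = "integer"),
  validity = function(object) {
    if (any(diff(object@rhoGrid) <= 0)) return("rhoGrid must be increasing")
    if (nrow(object@probs) != length(object@configs))
      return("probs rows must match configs")
    if (ncol(object@probs) != length(object@rhoGrid))
      return("probs columns must match rhoGrid")
    cs <- colSums(object@probs)
    if (any(abs(cs - 1) > 1e-9))
      return("configuration probabilities must sum to 1 per grid rho")
    TRUE
  })

#' HmmParams: parameters of the haplotype-copying HMM
#'
#' @slot ne diploid effective population size; with the genetic map it sets
#'   the switch probability between copying templates.
#' @slot eps per-site copying-error (emission mismatch) probability.
#' @exportClass HmmParams
setClass("HmmParams",
  representation(ne = "numeric", eps = "numeric"),
  validity = function(object) {
    if (length(object@ne) != 1L || !is.finite(object@ne) || object@ne <= 0)
      return("ne must be a single positive number")
    if (length(object@eps) != 1L || object@eps <= 0 || object@eps >= 0.5)
      return("eps must lie strictly between 0 and 0.5")
    TRUE
  })

#' PhasedCohort: ordered haplotype pairs with per-het phase certainty
#'
#' @slot hap1,hap2 integer matrices (n_ind x n_sites); at every non-missing
#'   genotype the pair sums to it.
#' @slot certainty numeric matrix; posterior phase agreement in \[0.5, 1\] at
#'   heterozygous sites, NA elsewhere.
#' @slot positions numeric bp; @slot chrom label; @slot sampleIds character.
#' @exportClass PhasedCohort
setClass("PhasedCohort",
  representation(hap1 = "matrix", hap2 = "matrix", certainty = "matrix",
                 positions = "numeric", chrom = "character",
                 sampleIds = "character"),
  validity = function(object) {
    d <- dim(object@hap1)
    if (!identical(d, dim(object@hap2)) || !identical(d, dim(object@certainty)))
      return("hap1, hap2 and certainty must share dimensions")
    if (d[2] != length(object@positions))
      return("positions must align with sites")
    if (d[1] != length(object@sampleIds))
      return("sampleIds must align with rows")
    cc <- object@certainty[!is.na(object@certainty)]
    if (length(cc) && (any(cc < 0.5 - 1e-9) || any(cc > 1 + 1e-9)))
      return("certainties must lie in [0.5, 1]")
    TRUE
  })

#' ImputedGenotypes: dosages and hard calls after imputation
#'
#' @slot dosage numeric matrix (n_ind x n_sites) in \[0, 2\].
#' @slot hardCalls integer matrix, rounded posterior-mode genotypes.
#' @slot maskedSites integer, the site columns that were imputed.
#' @slot positions numeric bp; @slot sampleIds character.
#' @exportClass ImputedGenotypes
setClass("ImputedGenotypes",
  representation(dosage = "matrix", hardCalls = "matrix",
                 maskedSites = "integer", positions = "numeric",
                 sampleIds = "character"),
  validity = function(object) {
    if (!identical(dim(object@dosage), dim(object@hardCalls)))
      return("dosage and hardCalls must share dimensions")
    dd <- object@dosage[!is.na(object@dosage)]
    if (length(dd) && (any(dd < -1e-9) || any(dd > 2 + 1e-9)))
      return("dosages must lie in [0, 2]")
    TRUE
  })

#' TruthPhase: trio-resolved true haplotypes of one child
#'
#' @slot hap1,hap2 integer vectors; paternal and maternal alleles, NA where
#'   trio logic cannot resolve the phase.
#' @slot resolvableMask logical, TRUE where phase is determined (excludes
#'   triple-heterozygous and missing sites).
#' @slot inconsistentSites integer, Mendelian-violation site indices.
#' @exportClass TruthPhase
setClass("TruthPhase",
  representation(hap1 = "numeric", hap2 = "numeric",
                 resolvableMask = "logical", inconsistentSites = "integer"),
  validity = function(object) {
    n <- length(object@hap1)
    if (length(object@hap2) != n || length(object@resolvableMask) != n)
      return("hap1, hap2 and resolvableMask must share length")
    if (any(!is.na(object@hap1[!object@resolvableMask])))
      return("unresolvable sites must have NA haplotype entries")
    TRUE
  })

#' EvalReport: switch-error and concordance tables for a condition grid
#'
#' @slot phasing data.frame: map, panel, sample, ser (NA = fewer than two
#'   resolvable heterozygous sites).
#' @slot imputation data.frame: map, bin, concordance (percent), n (masked
#'   calls in the bin).
#' @slot tests data.frame: arm, comparison, statistic, p.value.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(phasing = "data.frame", imputation = "data.frame",
                 tests = "data.frame"),
  validity = function(object) {
    ph <- object@phasing
    if (nrow(ph) && (any(ph$ser < 0, na.rm = TRUE) ||
                     any(ph$ser > 1, na.rm = TRUE)))
      return("SER must lie in [0, 1]")
    im <- object@imputation
    if (nrow(im) && (any(im$concordance < 0, na.rm = TRUE) ||
                     any(im$concordance > 100, na.rm = TRUE)))
      return("concordance must lie in [0, 100]")
    TRUE
  })
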