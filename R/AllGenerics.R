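## Accessor generics and show methods.  Slots are never touched directly by
## user code; these accessors are the supported surface.

#' @rdname GeneticMap-class
#' @param object,x an object.
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname GeneticMap-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname GeneticMap-class
#' @export
setGeneric("intervalRates", function(x) standardGeneric("intervalRates"))

#' @rdname GeneticMap-class
#' @export
setGeneric("cumulativeCm", function(x) standardGeneric("cumulativeCm"))

#' @rdname GeneticMap-class
#' @export
setGeneric("totalCm", function(x) standardGeneric("totalCm"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHap", function(x) standardGeneric("nHap"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname RhoTrack-class
#' @export
setGeneric("rhoPerBp", function(x) standardGeneric("rhoPerBp"))

#' @rdname RhoTrack-class
#' @export
setGeneric("rhoVariance", function(x) standardGeneric("rhoVariance"))

#' @rdname RhoTrack-class
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' @exportMethod chromName
setMethod("chromName", "GeneticMap", function(x) x@chrom)
setMethod("chromName", "HaplotypePanel", function(x) x@chrom)
setMethod("chromName", "GenotypeMatrix", function(x) x@chrom)

#' @exportMethod positions
setMethod("positions", "GeneticMap", function(x) x@positions)
setMethod("positions", "HaplotypePanel", function(x) x@positions)
setMethod("positions", "GenotypeMatrix", function(x) x@positions)
setMethod("positions", "PhasedCohort", function(x) x@positions)
setMethod("positions", "ImputedGenotypes", function(x) x@positions)

#' @exportMethod intervalRates
setMethod("intervalRates", "GeneticMap", function(x) x@intervalRates)

#' @exportMethod cumulativeCm
setMethod("cumulativeCm", "GeneticMap", function(x) x@cumulativeCm)

#' @exportMethod totalCm
setMethod("totalCm", "GeneticMap",
          function(x) x@cumulativeCm[length(x@cumulativeCm)])

#' @exportMethod haplotypes
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @exportMethod nHap
setMethod("nHap", "HaplotypePanel", function(x) nrow(x@haplotypes))

#' @exportMethod nSites
setMethod("nSites", "HaplotypePanel", function(x) ncol(x@haplotypes))
setMethod("nSites", "GenotypeMatrix", function(x) ncol(x@genotypes))

#' @exportMethod genotypes
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)
setMethod("genotypes", "TrioCohort", function(x) x@genotypes)

#' @exportMethod sampleIds
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)
setMethod("sampleIds", "PhasedCohort", function(x) x@sampleIds)
setMethod("sampleIds", "ImputedGenotypes", function(x) x@sampleIds)

#' @exportMethod rhoPerBp
setMethod("rhoPerBp", "RhoTrack", function(x) x@rhoPerBp)

#' @exportMethod rhoVariance
setMethod("rhoVariance", "RhoTrack", function(x) x@variance)

#' @exportMethod windows
setMethod("windows", "RhoTrack", function(x)
  data.frame(start = x@windowStart, end = x@windowEnd,
             rhoPerBp = x@rhoPerBp, variance = x@variance,
             nSnps = x@nSnps))

setMethod("show", "GeneticMap", function(object) {
  p <- object@positions
  cat(sprintf("GeneticMap on %s: %d positions, %.0f-%.0f bp, %.4g cM total (mean %.4g cM/Mb)\n",
              object@chrom, length(p), p[1], p[length(p)],
              totalCm(object),
              totalCm(object) / ((p[length(p)] - p[1]) / 1e6)))
})

setMethod("show", "RhoTrack", function(object) {
  cat(sprintf("RhoTrack: %d windows (%s), median rho/bp %.3g, %d missing\n",
              length(object@windowStart),
              if (object@sliding) "sliding" else "non-overlapping",
              median(object@rhoPerBp, na.rm = TRUE),
              sum(is.na(object@rhoPerBp))))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel on %s: %d haplotypes x %d sites\n",
              object@chrom, nrow(object@haplotypes), ncol(object@haplotypes)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix on %s: %d samples x %d sites (%.2f%% missing)\n",
              object@chrom, nrow(object@genotypes), ncol(object@genotypes),
              100 * mean(is.na(object@genotypes))))
})

setMethod("show", "TrioCohort", function(object) {
  cat(sprintf("TrioCohort: %d trios, %d sites\n",
              nrow(object@trios), ncol(object@genotypes@genotypes)))
})

setMethod("show", "TwoLocusLookup", function(object) {
  cat(sprintf("TwoLocusLookup: n_hap %d, %d grid rho values, %d configurations\n",
              object@nHap, length(object@rhoGrid), length(object@configs)))
})

setMethod("show", "PhasedCohort", function(object) {
  cat(sprintf("PhasedCohort: %d samples x %d sites\n",
              nrow(object@hap1), ncol(object@hap1)))
})

setMethod("show", "ImputedGenotypes", function(object) {
  cat(sprintf("ImputedGenotypes: %d samples x %d sites, %d imputed columns\n",
              nrow(object@dosage), ncol(object@dosage),
              length(object@maskedSites)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d phasing rows, %d imputation rows, %d tests\n",
              nrow(object@phasing), nrow(object@imputation),
              nrow(object@tests)))
})
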