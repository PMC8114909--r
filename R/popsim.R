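#' Construct a haplotype panel
#'
#' @param haplotypes matrix (n_hap x n_sites) of 0/1 alleles.
#' @param positions strictly increasing bp positions, one per column.
#' @param chrom chromosome label.
#' @return A [HaplotypePanel-class].
#' @export
HaplotypePanel <- function(haplotypes, positions, chrom = "chr1") {
  storage.mode(haplotypes) <- "integer"
  new("HaplotypePanel", haplotypes = haplotypes,
      positions = as.numeric(positions), chrom = as.character(chrom))
}

#' Construct a genotype matrix
#'
#' @param genotypes matrix (n_ind x n_sites), values 0/1/2/NA.
#' @param positions strictly increasing bp positions.
#' @param sampleIds character row labels (default S1, S2, ...).
#' @param chrom chromosome label.
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(genotypes, positions,
                           sampleIds = paste0("S", seq_len(nrow(genotypes))),
                           chrom = "chr1") {
  storage.mode(genotypes) <- "integer"
  new("GenotypeMatrix", genotypes = genotypes,
      positions = as.numeric(positions), chrom = as.character(chrom),
      sampleIds = as.character(sampleIds))
}

#' Simulate a haplotype panel under the coalescent with recombination
#'
#' Exact Hudson-style ancestral-recombination-graph simulation over a
#' continuous region.  Recombination intensity between physical positions
#' is taken from the genetic map (scaled by `4 * ne` to the population
#' rate rho), and infinite-sites mutations fall on branches at rate
#' `theta / 2` per bp, so the LD decay of the sample follows the input
#' map.  Continuous mutation positions are snapped to distinct integer bp.
#'
#' @param nHap number of haplotypes (>= 2).
#' @param regionLength region length in bp; the map must cover it.
#' @param map a [GeneticMap-class] providing the recombination landscape.
#' @param theta scaled mutation rate (4*Ne*mu) per bp.
#' @param seed integer seed; the simulation is deterministic given
#'   `(seed, parameters)`.
#' @param ne diploid effective population size used to scale the map's cM
#'   to rho.
#' @param chrom chromosome label of the output panel.
#' @return A [HaplotypePanel-class] of segregating sites.
#' @examples
#' p <- simulatePanel(10, 1e5, constantMap("chr1", 1e5, 1), 1e-3, seed = 1)
#' nHap(p)
#' @export
simulatePanel <- function(nHap, regionLength, map, theta, seed,
                          ne = 10000, chrom = chromName(map)) {
  stopifnot(is(map, "GeneticMap"))
  if (nHap < 2) stop("nHap must be >= 2")
  if (theta <= 0) stop("theta must be > 0")
  pmap <- positions(map)
  if (pmap[length(pmap)] < regionLength)
    stop("region longer than map coverage: map ends at ",
         pmap[length(pmap)], " < ", regionLength)
  ## cumulative rho as a function of 0-based physical coordinate
  map_pos <- pmax(pmap - 1, 0)
  map_rho <- 4 * ne * cumulativeCm(map) / 100
  if (map_pos[1] > 0) {        # no recombination before the map start
    map_pos <- c(0, map_pos)
    map_rho <- c(0, map_rho)
  }
  keep <- map_pos <= regionLength
  if (!all(keep)) {            # truncate the map at the region end
    cut_rho <- approx(map_pos, map_rho, xout = regionLength, rule = 2)$y
    map_pos <- c(map_pos[keep], regionLength)
    map_rho <- c(map_rho[keep], cut_rho)
  }
  sim <- .arg_simulate(as.integer(nHap), as.numeric(regionLength),
                       map_pos, map_rho, theta,
                       as.numeric(.derive_seed(seed, "argsim")))
  pos <- .integer_positions(sim$positions, regionLength)
  HaplotypePanel(sim$haplotypes[, pos$keep, drop = FALSE], pos$pos, chrom)
}

## snap continuous positions (ascending) to distinct 1-based integer bp;
## in the (rare) event the region is locally saturated, excess sites are
## dropped rather than displaced
.integer_positions <- function(cont, L) {
  pos <- floor(cont) + 1
  pos[pos > L] <- L
  n <- length(pos)
  keep <- rep(TRUE, n)
  if (n > 1) {
    for (i in 2:n) {
      if (pos[i] <= pos[i - 1]) {
        cand <- pos[i - 1] + 1
        if (cand > L) keep[i] <- FALSE else pos[i] <- cand
      }
    }
  }
  list(pos = pos[keep], keep = which(keep))
}

#' Transmit a gamete by meiosis with map-driven crossovers
#'
#' Haldane (no-interference) meiosis: the crossover count is Poisson with
#' mean equal to the map's total genetic length in Morgans, crossover
#' positions are uniform on the cM scale (hence concentrated where the
#' rate is high and never inside zero-rate intervals), and the gamete
#' alternates between the two parental haplotypes at each crossover.
#'
#' @param parent 2 x n_sites integer matrix (the parent's haplotype pair).
#' @param sitePos site bp positions (columns of `parent`).
#' @param map a [GeneticMap-class] covering the sites.
#' @param seed integer seed.
#' @return integer vector gamete with attributes `crossovers` (bp) and
#'   `startHap` (1 or 2).
#' @export
meiosis <- function(parent, sitePos, map, seed) {
  stopifnot(is.matrix(parent), nrow(parent) == 2L,
            ncol(parent) == length(sitePos))
  M <- totalCm(map) / 100
  .local_seed(seed, {
    start <- sample.int(2L, 1L)
    nx <- rpois(1L, M)
    xover <- numeric(0)
    if (nx > 0) {
      ucm <- runif(nx, 0, totalCm(map))
      xover <- sort(.cm_to_pos(map, ucm))
    }
    src <- (start - 1L + findInterval(sitePos, xover)) %% 2L + 1L
    gam <- parent[cbind(src, seq_along(sitePos))]
    attr(gam, "crossovers") <- xover
    attr(gam, "startHap") <- start
    gam
  })
}

## inverse of the cumulative-cM function; flat (zero-rate) stretches are
## never hit by a uniform draw on the cM scale, so the inverse places a
## value strictly inside the rising interval that contains it
.cm_to_pos <- function(map, ucm) {
  cm <- cumulativeCm(map)
  pp <- positions(map)
  n <- length(cm)
  idx <- findInterval(ucm, cm)          # last knot with cm <= u
  idx[idx >= n] <- n - 1L
  idx[idx < 1L] <- 1L
  dcm <- cm[idx + 1L] - cm[idx]
  frac <- ifelse(dcm > 0, (ucm - cm[idx]) / dcm, 0)
  pp[idx] + frac * (pp[idx + 1L] - pp[idx])
}

#' Assemble a cohort of parent-offspring trios
#'
#' Parents are assembled from distinct panel haplotypes (drawn without
#' replacement); each child haplotype is a meiotic crossover mosaic of one
#' parent's pair; genotypes are the unphased allele sums, and the child's
#' true transmitted haplotype pair is retained for evaluation.
#'
#' @param panel a [HaplotypePanel-class] with at least `4 * nTrios`
#'   haplotypes.
#' @param nTrios number of trios (default 55, i.e. 110 independent
#'   parents).
#' @param map a [GeneticMap-class] driving the meiotic crossovers.
#' @param seed integer seed.
#' @return A [TrioCohort-class]; sample IDs are F<k>, M<k>, C<k>.
#' @export
makeTrioCohort <- function(panel, nTrios = 55, map, seed) {
  stopifnot(is(panel, "HaplotypePanel"))
  H <- haplotypes(panel)
  if (nrow(H) < 4 * nTrios)
    stop("panel has ", nrow(H), " haplotypes; need at least ", 4 * nTrios)
  pos <- positions(panel)
  idx <- .local_seed(.derive_seed(seed, "parents"),
                     sample.int(nrow(H), 4 * nTrios))
  S <- ncol(H)
  gm <- matrix(NA_integer_, nrow = 3 * nTrios, ncol = S)
  ids <- character(3 * nTrios)
  truth <- vector("list", nTrios)
  trios <- data.frame(father = character(nTrios), mother = character(nTrios),
                      child = character(nTrios))
  for (k in seq_len(nTrios)) {
    fh <- H[idx[4 * k - 3:2], , drop = FALSE]
    mh <- H[idx[4 * k - 1:0], , drop = FALSE]
    pat <- meiosis(fh, pos, map, .derive_seed(seed, paste0("pat", k)))
    mat <- meiosis(mh, pos, map, .derive_seed(seed, paste0("mat", k)))
    r <- 3 * (k - 1)
    gm[r + 1, ] <- colSums(fh)
    gm[r + 2, ] <- colSums(mh)
    gm[r + 3, ] <- pat + mat
    ids[r + 1:3] <- paste0(c("F", "M", "C"), k)
    truth[[k]] <- rbind(as.integer(pat), as.integer(mat))
    trios[k, ] <- ids[r + 1:3]
  }
  names(truth) <- trios$child
  new("TrioCohort",
      genotypes = GenotypeMatrix(gm, pos, ids, chromName(panel)),
      trios = trios, childTruth = truth)
}

#' Greedy site thinning by physical distance
#'
#' Left-to-right scan keeping a site iff it lies at least `minGap` bp from
#' the last kept site, so that no two kept sites are within `minGap` of
#' each other.
#'
#' @param positions increasing bp positions.
#' @param minGap minimum spacing in bp (default 15).
#' @return integer indices of kept sites.
#' @examples
#' thinSites(c(100, 110, 130))  # keeps sites 1 and 3
#' @export
thinSites <- function(positions, minGap = 15) {
  n <- length(positions)
  if (n == 0L) return(integer(0))
  if (any(diff(positions) <= 0)) stop("positions must be increasing")
  keep <- integer(n)
  keep[1] <- 1L
  m <- 1L
  last <- positions[1]
  for (i in seq_len(n)[-1]) {
    if (positions[i] - last >= minGap) {
      m <- m + 1L
      keep[m] <- i
      last <- positions[i]
    }
  }
  keep[seq_len(m)]
}

#' Derived-allele frequencies of a panel or genotype matrix
#'
#' @param x a [HaplotypePanel-class], [GenotypeMatrix-class] or 0/1 matrix.
#' @return numeric vector of per-site derived/alternate allele frequencies
#'   (missing genotypes excluded from the denominator).
#' @export
alleleFreqs <- function(x) {
  if (is(x, "HaplotypePanel")) return(colMeans(haplotypes(x)))
  g <- if (is(x, "GenotypeMatrix")) genotypes(x) else x
  colMeans(g, na.rm = TRUE) / 2
}

#' Minor-allele-frequency filter
#'
#' Keeps sites whose minor allele frequency is at least `minMaf`; sites
#' strictly below the threshold (including monomorphic sites) are removed.
#'
#' @param x a [HaplotypePanel-class], [GenotypeMatrix-class] or allele
#'   matrix.
#' @param minMaf threshold as a fraction (default 0.05; a site at exactly
#'   5 percent is kept).
#' @return integer indices of kept sites (possibly empty, with a warning).
#' @export
mafFilter <- function(x, minMaf = 0.05) {
  f <- alleleFreqs(x)
  maf <- pmin(f, 1 - f)
  keep <- which(maf >= minMaf - 1e-12)
  if (!length(keep)) warning("all sites removed by the MAF filter")
  keep
}

#' Chip-like common-variant site subset
#'
#' Emulates a sparse genotyping array: keeps common variants
#' (MAF >= `minMaf`) thinned to at least `minGapBp` apart.
#'
#' @param panel a [HaplotypePanel-class] whose frequencies define MAF.
#' @param minMaf common-variant threshold (default 0.01).
#' @param minGapBp minimum spacing of retained sites (default 1000 bp).
#' @return integer indices of chip sites (relative to the panel's axis).
#' @export
chipSubset <- function(panel, minMaf = 0.01, minGapBp = 1000) {
  common <- mafFilter(panel, minMaf)
  if (!length(common)) return(integer(0))
  common[thinSites(positions(panel)[common], minGapBp)]
}

#' Randomly mask whole variant columns
#'
#' Sets exactly `round(fraction * nSites)` whole variant columns to
#' missing, chosen uniformly without replacement, storing the original
#' values for later evaluation.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param fraction fraction of sites to mask, in \[0, 1\] (default 0.10).
#' @param seed integer seed.
#' @return list with elements `masked` (the [GenotypeMatrix-class] with
#'   masked columns set NA) and `mask` (a [MaskSet-class]).
#' @export
maskRandom <- function(gm, fraction = 0.10, seed) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  S <- nSites(gm)
  nMask <- round(fraction * S)
  sites <- if (nMask > 0)
    sort(.local_seed(seed, sample.int(S, nMask))) else integer(0)
  g <- genotypes(gm)
  orig <- g[, sites, drop = FALSE]
  g[, sites] <- NA_integer_
  list(masked = GenotypeMatrix(g, positions(gm), sampleIds(gm),
                               chromName(gm)),
       mask = new("MaskSet", maskedSites = as.integer(sites),
                  original = orig))
}

#' Restore masked columns
#'
#' Inverse of [maskRandom()]: reinstates the stored original values
#' bit-exactly.
#'
#' @param gm the masked [GenotypeMatrix-class].
#' @param mask the corresponding [MaskSet-class].
#' @return The restored [GenotypeMatrix-class].
#' @export
restoreMasked <- function(gm, mask) {
  stopifnot(is(gm, "GenotypeMatrix"), is(mask, "MaskSet"))
  g <- genotypes(gm)
  g[, mask@maskedSites] <- mask@original
  GenotypeMatrix(g, positions(gm), sampleIds(gm), chromName(gm))
}

## row/column subset of a panel (internal convenience)
.sub_panel <- function(p, rows = NULL, cols = NULL) {
  H <- haplotypes(p)
  if (is.null(rows)) rows <- seq_len(nrow(H))
  if (is.null(cols)) cols <- seq_len(ncol(H))
  HaplotypePanel(H[rows, cols, drop = FALSE], positions(p)[cols],
                 chromName(p))
}

#' Chip-like site selection: common tags plus rare exome-style content
#'
#' Emulates a CoreExome-class genotyping array: within each `tagGapBp`
#' window the single most informative common variant (largest MAF at or
#' above `tagMinMaf`) is kept as a GWAS tag, and `nRare` additional sites
#' are drawn as exome-like rare content, stratified evenly across
#' `[rareRange[1], rareSplit)` and `[rareSplit, rareRange[2])` so that the
#' rare tail is represented rather than swallowed by the frequency
#' spectrum.
#'
#' @param panel a [HaplotypePanel-class] whose frequencies define MAF.
#' @param tagMinMaf common-tag MAF floor (default 0.05).
#' @param tagGapBp tag window size in bp (default 300).
#' @param rareRange MAF range of the rare content (default 0.0015-0.05).
#' @param rareSplit stratification boundary (default 0.004).
#' @param nRare number of rare-content sites (split evenly between
#'   strata; fewer if a stratum has fewer sites).
#' @param seed integer seed for the rare-content draw.
#' @return sorted integer site indices on the panel's axis.
#' @seealso [chipSubset()] for the plain common-variant thinned subset.
#' @export
chipSites <- function(panel, tagMinMaf = 0.05, tagGapBp = 300,
                      rareRange = c(0.0015, 0.05), rareSplit = 0.004,
                      nRare = 300, seed = 1) {
  f <- alleleFreqs(panel)
  maf <- pmin(f, 1 - f)
  pos <- positions(panel)
  win <- floor(pos / tagGapBp)
  cand <- which(maf >= tagMinMaf)
  tags <- if (length(cand))
    as.integer(tapply(cand, win[cand],
                      function(ii) ii[which.max(maf[ii])])) else integer(0)
  ra <- which(maf >= rareRange[1] & maf < rareSplit)
  rb <- which(maf >= rareSplit & maf < rareRange[2])
  rare <- .local_seed(.derive_seed(seed, "chiprare"),
                      c(sample(ra, min(ceiling(nRare / 2), length(ra))),
                        sample(rb, min(floor(nRare / 2), length(rb)))))
  sort(union(tags, rare))
}
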