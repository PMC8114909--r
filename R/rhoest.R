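## Windowed estimation of the population-scaled recombination rate rho.
## Two routes are computed per window and then averaged: a pairwise
## composite likelihood against a Monte-Carlo two-locus lookup (the
## classical LD-based estimator family, at constant rate per window) and a
## summary-statistic regression trained on simulated windows (the
## machine-learning window-estimator family).

.default_rho_grid <- c(0, 0.5, 1, 2, 5, 10, 20, 50, 100)

## Canonical key of a two-locus haplotype-count configuration, invariant
## under allele relabelling at each locus and locus exchange.  Exact
## configurations are far too numerous for Monte-Carlo tabulation at
## n_hap ~ 100, so configurations are keyed by (minor-allele frequency
## class at each locus, normalised position of n11 within its feasible
## range).  The boundary classes (n11 at either end of the range) are
## kept exact: a configuration violates the four-gamete test iff n11 is
## strictly interior, so at rho = 0 all mass sits in boundary classes.
.freq_class <- function(minorCount, n) {
  f <- minorCount / n
  ifelse(minorCount <= 1L, 1L,
  ifelse(minorCount == 2L, 2L,
  ifelse(minorCount <= 4L, 3L,
         4L + findInterval(f, c(0.075, 0.125, 0.2, 0.3)))))
}

.config_key <- function(n00, n01, n10, n11) {
  n <- n00 + n01 + n10 + n11
  cA <- n10 + n11
  cB <- n01 + n11
  ## orient each locus to its minor allele (ties resolved toward the
  ## orientation with smaller n11)
  flipA <- cA > n / 2 | (cA == n / 2 & (cB - n11) < n11)
  n11 <- ifelse(flipA, cB - n11, n11)
  cA <- ifelse(flipA, n - cA, cA)
  flipB <- cB > n / 2 | (cB == n / 2 & (cA - n11) < n11)
  n11 <- ifelse(flipB, cA - n11, n11)
  cB <- ifelse(flipB, n - cB, cB)
  ## order loci by minor count (n11 is invariant under locus exchange)
  lo_c <- pmin(cA, cB); hi_c <- pmax(cA, cB)
  lo <- pmax(0, cA + cB - n)
  hi <- pmin(cA, cB)
  tb <- ifelse(n11 <= lo, 0L,
        ifelse(n11 >= hi, 8L,
               1L + findInterval((n11 - lo) / (hi - lo),
                                 seq(1 / 7, 6 / 7, by = 1 / 7))))
  paste(.freq_class(lo_c, n), .freq_class(hi_c, n), tb, sep = ":")
}

## TRUE when a key (or raw configuration) violates the four-gamete test
.key_violates_4g <- function(key) {
  tb <- as.integer(vapply(strsplit(key, ":"), `[`, "", 3L))
  tb > 0L & tb < 8L
}

#' Build a Monte-Carlo two-locus likelihood lookup
#'
#' For each grid rho, simulates `nReps` two-locus coalescent samples with
#' scaled recombination rho between the loci and per-locus mutation rate
#' `thetaLocus`, retains only replicates that are biallelic at both loci
#' (exactly one infinite-sites mutation per locus), and tabulates the
#' canonicalised haplotype-count configurations with add-one smoothing
#' over the union of configurations observed anywhere on the grid.
#'
#' @param nHap haplotype sample size the table is for (>= 4).
#' @param rhoGrid increasing rho values (default 0, 0.5, 1, 2, 5, 10, 20,
#'   50, 100).
#' @param thetaLocus per-locus scaled mutation rate used in the simulation
#'   (default 0.2; the conditional configuration distribution is only
#'   weakly sensitive to it).
#' @param nReps Monte-Carlo replicates per grid point.
#' @param seed integer seed.
#' @return A [TwoLocusLookup-class].
#' @export
buildLookup <- function(nHap, rhoGrid = .default_rho_grid, thetaLocus = 0.2,
                        nReps = 40000, seed = 1) {
  if (nHap < 4) stop("nHap must be >= 4")
  if (!length(rhoGrid)) stop("rhoGrid must be non-empty")
  keys <- vector("list", length(rhoGrid))
  kept <- integer(length(rhoGrid))
  for (g in seq_along(rhoGrid)) {
    cfg <- .two_locus_sim(as.integer(nHap), rhoGrid[g], thetaLocus,
                          as.integer(nReps),
                          as.numeric(.derive_seed(seed, paste0("lk", g))))
    if (nrow(cfg) == 0L)
      stop("no biallelic two-locus outcome in ", nReps,
           " replicates at rho = ", rhoGrid[g],
           "; increase nReps or thetaLocus")
    keys[[g]] <- .config_key(cfg[, 1], cfg[, 2], cfg[, 3], cfg[, 4])
    kept[g] <- nrow(cfg)
  }
  universe <- sort(unique(unlist(keys)))
  probs <- matrix(0, nrow = length(universe), ncol = length(rhoGrid),
                  dimnames = list(universe, NULL))
  for (g in seq_along(rhoGrid)) {
    tab <- table(factor(keys[[g]], levels = universe))
    probs[, g] <- (as.numeric(tab) + 1) / (kept[g] + length(universe))
  }
  new("TwoLocusLookup", nHap = as.integer(nHap), rhoGrid = as.numeric(rhoGrid),
      thetaLocus = thetaLocus, configs = universe, probs = probs,
      nReps = as.integer(nReps), nKept = kept)
}

## pairwise configurations of a 0/1 haplotype matrix: canonical keys and
## physical distances for all site pairs within maxPairSpan
.pair_configs <- function(H, pos, maxPairSpan) {
  S <- ncol(H)
  n <- nrow(H)
  C11 <- crossprod(H)               # counts of haplotype (1,1) per pair
  ones <- colSums(H)
  ut <- which(upper.tri(C11), arr.ind = TRUE)
  d <- pos[ut[, 2]] - pos[ut[, 1]]
  keep <- d <= maxPairSpan
  ut <- ut[keep, , drop = FALSE]
  d <- d[keep]
  n11 <- C11[ut]
  n10 <- ones[ut[, 1]] - n11
  n01 <- ones[ut[, 2]] - n11
  n00 <- n - n11 - n10 - n01
  list(keys = .config_key(n00, n01, n10, n11), dist = d,
       i = ut[, 1], j = ut[, 2])
}

#' Composite-likelihood estimate of rho for one window
#'
#' Sums two-locus log-likelihoods from the lookup over all site pairs
#' within `maxPairSpan`, with the between-pair rho equal to the candidate
#' per-bp rho times the pair distance (log-likelihood interpolated
#' log-linearly on the lookup grid), and returns the grid argmax with a
#' profile-curvature variance approximation.  Ties break toward smaller
#' rho.
#'
#' @param panel a [HaplotypePanel-class] (the window's sites).
#' @param lookup a [TwoLocusLookup-class] built for the panel's sample
#'   size.
#' @param maxPairSpan maximum pair distance in bp (default 50 kb).
#' @param candRhoBp candidate per-bp rho grid (ascending, starting at 0).
#' @param jackknifeBlocks number of contiguous site blocks for the
#'   leave-one-block-out variance (site pairs are strongly dependent, so
#'   the naive profile curvature badly understates the sampling variance;
#'   the block jackknife is used whenever at least 4 blocks are possible,
#'   the curvature otherwise).
#' @return list with `rhoPerBp` (NA when fewer than 2 usable sites),
#'   `variance`, `nSnps`, `logLik` (per candidate) and `candRhoBp`.
#' @export
compositeRho <- function(panel, lookup, maxPairSpan = 50000,
                         candRhoBp = NULL, jackknifeBlocks = 8) {
  stopifnot(is(panel, "HaplotypePanel"), is(lookup, "TwoLocusLookup"))
  if (nHap(panel) != lookup@nHap)
    stop("panel has ", nHap(panel), " haplotypes but lookup was built for ",
         lookup@nHap)
  if (is.null(candRhoBp))
    candRhoBp <- c(0, exp(seq(log(1e-6), log(3e-2), length.out = 48)))
  H <- haplotypes(panel)
  seg <- which(colSums(H) > 0 & colSums(H) < nrow(H))
  if (length(seg) < 2L)
    return(list(rhoPerBp = NA_real_, variance = NA_real_,
                nSnps = length(seg), logLik = NULL, candRhoBp = candRhoBp))
  H <- H[, seg, drop = FALSE]
  pos <- positions(panel)[seg]
  pc <- .pair_configs(H, pos, maxPairSpan)
  if (!length(pc$dist))
    return(list(rhoPerBp = NA_real_, variance = NA_real_,
                nSnps = ncol(H), logLik = NULL, candRhoBp = candRhoBp))
  idx <- match(pc$keys, lookup@configs)
  idx[is.na(idx)] <- 0L
  floorLog <- log(1 / (min(lookup@nKept) + length(lookup@configs)))
  ll <- .composite_scan(as.integer(idx), as.numeric(pc$dist),
                        log(lookup@probs), lookup@rhoGrid,
                        as.numeric(candRhoBp), floorLog)
  best <- which.max(ll)          # first maximum = smallest rho on ties
  variance <- .jackknife_var(pc, idx, ncol(H), lookup, candRhoBp,
                             floorLog, jackknifeBlocks)
  if (is.na(variance))
    variance <- .profile_curvature_var(candRhoBp, ll, best)
  list(rhoPerBp = candRhoBp[best], variance = variance, nSnps = ncol(H),
       logLik = ll, candRhoBp = candRhoBp)
}

## leave-one-site-block-out jackknife variance of the composite argmax
.jackknife_var <- function(pc, idx, S, lookup, candRhoBp, floorLog,
                           nBlocks) {
  B <- min(nBlocks, floor(S / 2))
  if (B < 4) return(NA_real_)
  blockOf <- ceiling(seq_len(S) / (S / B))
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    keep <- blockOf[pc$i] != b & blockOf[pc$j] != b
    if (sum(keep) < 1) next
    llb <- .composite_scan(as.integer(idx[keep]),
                           as.numeric(pc$dist[keep]),
                           log(lookup@probs), lookup@rhoGrid,
                           as.numeric(candRhoBp), floorLog)
    est[b] <- candRhoBp[which.max(llb)]
  }
  est <- est[!is.na(est)]
  if (length(est) < 4) return(NA_real_)
  (length(est) - 1) / length(est) * sum((est - mean(est))^2)
}

## variance from the curvature of the profile log-likelihood at the
## argmax (quadratic approximation with uneven grid spacing); at a grid
## boundary the curvature of the nearest interior point is used
.profile_curvature_var <- function(x, ll, best) {
  n <- length(x)
  i <- min(max(best, 2L), n - 1L)
  h1 <- x[i] - x[i - 1]
  h2 <- x[i + 1] - x[i]
  d2 <- 2 * (ll[i - 1] * h2 - ll[i] * (h1 + h2) + ll[i + 1] * h1) /
    (h1 * h2 * (h1 + h2))
  if (!is.finite(d2) || d2 >= 0) return(NA_real_)
  -1 / d2
}

#' Split a panel's SNP axis into segments with overhangs
#'
#' Consecutive segments whose cores tile the SNP index axis exactly once;
#' each segment additionally carries up to `overhangSnps` flanking SNPs on
#' each side so that estimates near core edges see their context, and
#' stitched results are taken from cores only.
#'
#' @param panel a [HaplotypePanel-class] (or anything with sites).
#' @param segmentSnps core size in SNPs (default 10000).
#' @param overhangSnps overhang on each side (default 1000); must satisfy
#'   `segmentSnps > 2 * overhangSnps`.
#' @return data.frame with 1-based inclusive SNP indices coreStart,
#'   coreEnd, segStart, segEnd.
#' @export
segmentPanel <- function(panel, segmentSnps = 10000, overhangSnps = 1000) {
  if (segmentSnps <= 2 * overhangSnps)
    stop("segmentSnps must exceed 2 * overhangSnps")
  n <- if (is(panel, "HaplotypePanel")) nSites(panel) else as.integer(panel)
  starts <- seq(1L, n, by = segmentSnps)
  ends <- pmin(starts + segmentSnps - 1L, n)
  data.frame(coreStart = starts, coreEnd = ends,
             segStart = pmax(1L, starts - as.integer(overhangSnps)),
             segEnd = pmin(n, ends + as.integer(overhangSnps)))
}

## ---- summary-statistic (regression) estimator ----------------------------

.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-window summary statistics for the regression estimator
#'
#' Segregating sites, distinct haplotype count, mean pairwise r-squared,
#' mean absolute D-prime, Tajima's D and the window span in bp.  Windows
#' with fewer than two segregating sites report 0 for the LD statistics.
#'
#' @param panel a [HaplotypePanel-class] restricted to the window.
#' @param spanBp window span in bp (defaults to the position range).
#' @return one-row data.frame of features, all finite.
#' @export
windowFeatures <- function(panel, spanBp = NULL) {
  H <- haplotypes(panel)
  n <- nrow(H)
  seg <- which(colSums(H) > 0 & colSums(H) < n)
  if (is.null(spanBp)) {
    p <- positions(panel)
    spanBp <- if (length(p) > 1) diff(range(p)) else 0
  }
  S <- length(seg)
  if (S == 0L)
    return(data.frame(S = 0, nDistinct = 1, meanR2 = 0, meanAbsDprime = 0,
                      tajimaD = 0, spanBp = spanBp))
  H <- H[, seg, drop = FALSE]
  nDistinct <- nrow(unique(H))
  k <- colSums(H)
  pi_tot <- sum(k * (n - k)) / choose(n, 2)
  cst <- .tajima_constants(n)
  tajD <- if (S >= 2) {
    den <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    if (den > 0) (pi_tot - S / cst$a1) / den else 0
  } else 0
  if (S >= 2) {
    f <- k / n
    C11 <- crossprod(H) / n
    D <- C11 - outer(f, f)
    dmax <- ifelse(D >= 0,
                   pmin(outer(f, 1 - f), outer(1 - f, f)),
                   pmin(outer(f, f), outer(1 - f, 1 - f)))
    ut <- upper.tri(D)
    dn <- D[ut] / dmax[ut]
    dn[!is.finite(dn)] <- 0
    r2 <- D[ut]^2 / (outer(f * (1 - f), f * (1 - f))[ut])
    r2[!is.finite(r2)] <- 0
    meanR2 <- mean(r2)
    meanAbsDp <- mean(pmin(abs(dn), 1))
  } else {
    meanR2 <- 0; meanAbsDp <- 0
  }
  data.frame(S = S, nDistinct = nDistinct, meanR2 = meanR2,
             meanAbsDprime = meanAbsDp, tajimaD = tajD, spanBp = spanBp)
}

#' Simulate training windows for the summary regression estimator
#'
#' Windows are simulated under constant per-window rho values: a point
#' mass at 0 plus a log-uniform spread over `(0.5, rhoMax]`, covering the
#' range the estimator will be asked about.
#'
#' @param nWindows number of training windows (>= 200 recommended).
#' @param nHap haplotypes per window.
#' @param windowBp window span.
#' @param thetaBp scaled mutation rate per bp.
#' @param rhoMax largest training rho (per window).
#' @param ne effective population size used to express rho as a map.
#' @param seed integer seed.
#' @return data.frame of features plus the true per-window `rho`.
#' @export
simulateTrainingWindows <- function(nWindows = 240, nHap = 100,
                                    windowBp = 50000, thetaBp = 0.001,
                                    rhoMax = 100, ne = 10000, seed = 1) {
  rhos <- .local_seed(.derive_seed(seed, "trainrho"), {
    u <- runif(nWindows)
    ifelse(u < 0.15, 0, exp(runif(nWindows, log(0.5), log(rhoMax))))
  })
  rows <- vector("list", nWindows)
  for (w in seq_len(nWindows)) {
    rate <- rhos[w] / windowBp / (4 * ne) * 1e8
    mp <- constantMap("train", windowBp, rate)
    p <- simulatePanel(nHap, windowBp, mp, thetaBp,
                       .derive_seed(seed, paste0("trainw", w)), ne = ne)
    rows[[w]] <- windowFeatures(p, spanBp = windowBp)
  }
  out <- do.call(rbind, rows)
  out$rho <- rhos
  out
}

#' Train the summary-statistic rho regressor
#'
#' Random-forest regression of true window rho on the window features;
#' deterministic given the seed.
#'
#' @param training data.frame from [simulateTrainingWindows()] (features
#'   plus `rho`); at least 200 rows.
#' @param seed integer seed.
#' @param numTrees forest size.
#' @return fitted model (class `summaryRhoModel`).
#' @export
trainSummaryModel <- function(training, seed = 1, numTrees = 500) {
  if (nrow(training) < 200)
    stop("need at least 200 training windows spanning the rho range")
  feats <- setdiff(names(training), "rho")
  fit <- ranger::ranger(
    dependent.variable.name = "rho",
    data = training[, c(feats, "rho")],
    num.trees = numTrees, seed = as.integer(seed), num.threads = 1)
  structure(list(fit = fit, features = feats,
                 rhoMax = max(training$rho),
                 support = lapply(training[feats], range)),
            class = "summaryRhoModel")
}

#' Predict window rho from summary features
#'
#' Predictions are clipped to `[0, max training rho]`; targets with any
#' feature outside the training support are still predicted but flagged
#' via the `extrapolated` attribute.
#'
#' @param model a model from [trainSummaryModel()].
#' @param features one or more rows of features as from
#'   [windowFeatures()].
#' @param variance also return the between-tree variance of the ensemble
#'   prediction as attribute `variance`.
#' @return numeric predictions with attributes `extrapolated` and
#'   (optionally) `variance`.
#' @export
predictSummaryRho <- function(model, features, variance = TRUE) {
  stopifnot(inherits(model, "summaryRhoModel"))
  X <- features[, model$features, drop = FALSE]
  pr <- predict(model$fit, data = X, num.threads = 1,
                predict.all = variance)
  if (variance) {
    all_tr <- pr$predictions
    est <- rowMeans(all_tr)
    vr <- apply(all_tr, 1, var)  # ensemble spread as uncertainty proxy
  } else {
    est <- pr$predictions
    vr <- NULL
  }
  extrap <- rep(FALSE, nrow(X))
  for (f in model$features) {
    rg <- model$support[[f]]
    extrap <- extrap | X[[f]] < rg[1] | X[[f]] > rg[2]
  }
  out <- pmin(pmax(est, 0), model$rhoMax)
  attr(out, "extrapolated") <- extrap
  if (variance) attr(out, "variance") <- vr
  out
}

#' One-call summary-statistic rho estimator
#'
#' Convenience wrapper: fits the regressor on the supplied training
#' windows and predicts the target window's rho.
#'
#' @param training data.frame of training features plus `rho`.
#' @param target one-row data.frame of features for the window of
#'   interest.
#' @param seed training seed.
#' @return predicted rho (scalar) with an `extrapolated` attribute.
#' @export
summaryRhoEstimator <- function(training, target, seed = 1) {
  model <- trainSummaryModel(training, seed = seed)
  predictSummaryRho(model, target)
}

#' Average two rho tracks window by window
#'
#' Per-window arithmetic mean of two estimates on the same window scheme;
#' a window missing in one source takes the other's value.  Under
#' independence the combined variance is `(varA + varB) / 4`.
#'
#' @param a,b [RhoTrack-class] objects sharing window boundaries.
#' @return combined [RhoTrack-class].
#' @export
combineEstimates <- function(a, b) {
  stopifnot(is(a, "RhoTrack"), is(b, "RhoTrack"))
  if (length(a@windowStart) != length(b@windowStart) ||
      any(a@windowStart != b@windowStart) ||
      any(a@windowEnd != b@windowEnd))
    stop("disjoint window schemes; resample onto a common grid first")
  ra <- a@rhoPerBp; rb <- b@rhoPerBp
  rho <- ifelse(is.na(ra), rb, ifelse(is.na(rb), ra, (ra + rb) / 2))
  va <- a@variance; vb <- b@variance
  vr <- ifelse(is.na(ra), vb, ifelse(is.na(rb), va, (va + vb) / 4))
  ns <- pmax(a@nSnps, b@nSnps, na.rm = TRUE)
  RhoTrack(a@windowStart, a@windowEnd, rho, vr, ns, sliding = a@sliding)
}

## average sliding-window estimates onto non-overlapping step-sized bins
.bin_sliding <- function(track, stepBp) {
  stopifnot(is(track, "RhoTrack"))
  ws <- track@windowStart; we <- track@windowEnd
  lo <- min(ws); hi <- max(we)
  first <- floor((lo - 1) / stepBp) * stepBp + 1
  bs <- first + stepBp * (seq_len(ceiling((hi - first) / stepBp)) - 1)
  be <- bs + stepBp
  rho <- vr <- rep(NA_real_, length(bs))
  ns <- rep(NA_integer_, length(bs))
  for (i in seq_along(bs)) {
    ov <- which(ws < be[i] & we > bs[i] & !is.na(track@rhoPerBp))
    if (length(ov)) {
      rho[i] <- mean(track@rhoPerBp[ov])
      vr[i] <- sum(track@variance[ov], na.rm = TRUE) / length(ov)^2
      ns[i] <- as.integer(round(mean(track@nSnps[ov], na.rm = TRUE)))
    }
  }
  RhoTrack(bs, be, rho, vr, ns, sliding = FALSE)
}

#' Estimate a genetic map from a haplotype panel
#'
#' End-to-end map construction: site thinning (15 bp) and MAF filtering
#' (5 percent), segmentation of the SNP axis (10,000-SNP cores with
#' 1000-SNP overhangs), per-window composite-likelihood rho estimation on
#' a 50 kb / 25 kb sliding grid, a summary-regression estimate on the
#' same windows, averaging of the two tracks on 25 kb bins, and
#' conversion to cM/Mb through the effective population size.
#'
#' @param panel a [HaplotypePanel-class].
#' @param ne diploid effective population size (default 10,000).
#' @param config named list overriding defaults: thinGap, minMaf,
#'   segmentSnps, overhangSnps, windowBp, stepBp, maxPairSpan, thetaLocus,
#'   lookupReps, trainWindows, thetaBp, seed; plus optional prebuilt
#'   `lookup` ([TwoLocusLookup-class]) and `model`
#'   ([trainSummaryModel()] fit) to reuse across calls.
#' @return A [GeneticMap-class]; attribute `provenance` records the
#'   configuration and seeds, attribute `tracks` the composite, summary
#'   and combined [RhoTrack-class] objects.
#' @export
estimateMap <- function(panel, ne = 10000, config = list()) {
  stopifnot(is(panel, "HaplotypePanel"))
  .check_ne(ne)
  cfg <- modifyList(list(
    thinGap = 15, minMaf = 0.05, segmentSnps = 10000, overhangSnps = 1000,
    windowBp = 50000, stepBp = 25000, maxPairSpan = 50000,
    thetaLocus = 0.2, lookupReps = 20000, trainWindows = 240,
    thetaBp = 0.001, seed = 1, lookup = NULL, model = NULL), config)

  ## site filters: 15 bp thinning, then MAF >= 5 percent
  keepThin <- thinSites(positions(panel), cfg$thinGap)
  thinned <- HaplotypePanel(haplotypes(panel)[, keepThin, drop = FALSE],
                            positions(panel)[keepThin], chromName(panel))
  keepMaf <- mafFilter(thinned, cfg$minMaf)
  fp <- HaplotypePanel(haplotypes(thinned)[, keepMaf, drop = FALSE],
                       positions(thinned)[keepMaf], chromName(panel))

  lookup <- cfg[["lookup"]]      # exact: cfg$lookup would match lookupReps
  if (is.null(lookup))
    lookup <- buildLookup(nHap(fp), thetaLocus = cfg$thetaLocus,
                          nReps = cfg$lookupReps,
                          seed = .derive_seed(cfg$seed, "lookup"))
  model <- cfg[["model"]]
  if (is.null(model)) {
    training <- simulateTrainingWindows(
      nWindows = cfg$trainWindows, nHap = nHap(fp),
      windowBp = cfg$windowBp, thetaBp = cfg$thetaBp, ne = ne,
      seed = .derive_seed(cfg$seed, "train"))
    model <- trainSummaryModel(training, seed = .derive_seed(cfg$seed, "rf"))
  }

  segs <- segmentPanel(fp, cfg$segmentSnps, cfg$overhangSnps)
  pos <- positions(fp)
  ws_all <- we_all <- numeric(0)
  rhoC <- varC <- rhoS <- varS <- numeric(0)
  nS <- integer(0)
  for (s in seq_len(nrow(segs))) {
    segIdx <- segs$segStart[s]:segs$segEnd[s]
    corePos <- pos[segs$coreStart[s]:segs$coreEnd[s]]
    wFirst <- floor((corePos[1] - 1) / cfg$stepBp) * cfg$stepBp + 1
    nW <- ceiling((corePos[length(corePos)] - wFirst) / cfg$stepBp)
    wStart <- wFirst + cfg$stepBp * (seq_len(max(nW, 1)) - 1)
    wEnd <- wStart + cfg$windowBp
    subH <- haplotypes(fp)[, segIdx, drop = FALSE]
    subP <- pos[segIdx]
    for (w in seq_along(wStart)) {
      inw <- which(subP >= wStart[w] & subP < wEnd[w])
      ws_all <- c(ws_all, wStart[w]); we_all <- c(we_all, wEnd[w])
      if (length(inw) >= 2L) {
        wp <- HaplotypePanel(subH[, inw, drop = FALSE], subP[inw],
                             chromName(fp))
        cr <- compositeRho(wp, lookup, maxPairSpan = cfg$maxPairSpan)
        fe <- windowFeatures(wp, spanBp = cfg$windowBp)
        sr <- predictSummaryRho(model, fe)
        rhoC <- c(rhoC, cr$rhoPerBp)
        varC <- c(varC, cr$variance)
        rhoS <- c(rhoS, as.numeric(sr) / cfg$windowBp)
        varS <- c(varS, attr(sr, "variance") / cfg$windowBp^2)
        nS <- c(nS, length(inw))
      } else {
        rhoC <- c(rhoC, NA_real_); varC <- c(varC, NA_real_)
        rhoS <- c(rhoS, NA_real_); varS <- c(varS, NA_real_)
        nS <- c(nS, length(inw))
      }
    }
  }
  compTrack <- RhoTrack(ws_all, we_all, rhoC, varC, nS, sliding = TRUE)
  sumTrack <- RhoTrack(ws_all, we_all, rhoS, varS, nS, sliding = TRUE)
  compBin <- .bin_sliding(compTrack, cfg$stepBp)
  sumBin <- .bin_sliding(sumTrack, cfg$stepBp)
  combined <- combineEstimates(compBin, sumBin)
  map <- rhoToMap(combined, ne, chrom = chromName(panel))
  attr(map, "tracks") <- list(composite = compBin, summary = sumBin,
                              combined = combined,
                              compositeSliding = compTrack,
                              summarySliding = sumTrack)
  attr(map, "provenance") <- list(
    package = as.character(packageVersion("recombMap")),
    ne = ne,
    config = cfg[setdiff(names(cfg), c("lookup", "model"))],
    nSitesInput = nSites(panel), nSitesFiltered = nSites(fp))
  map
}
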