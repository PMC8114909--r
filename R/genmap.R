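#' Construct a genetic map from interval rates
#'
#' @param chrom chromosome label.
#' @param positions strictly increasing physical positions (bp, 1-based).
#' @param intervalRates cM/Mb for each interval
#'   `[positions[i], positions[i+1])`; one fewer than `positions`.
#' @return A [GeneticMap-class] object with cumulative cM accumulated from
#'   the rates.
#' @examples
#' GeneticMap("chr20", c(1, 1e6, 2e6), c(1, 2))
#' @export
GeneticMap <- function(chrom, positions, intervalRates) {
  positions <- as.numeric(positions)
  intervalRates <- as.numeric(intervalRates)
  cm <- c(0, cumsum(intervalRates * diff(positions) / 1e6))
  new("GeneticMap", chrom = as.character(chrom), positions = positions,
      intervalRates = intervalRates, cumulativeCm = cm)
}

#' Construct a windowed track of population-scaled recombination rates
#'
#' @param windowStart,windowEnd half-open window bounds `[start, end)` in bp.
#' @param rhoPerBp rho (= 4*Ne*r) per bp per window; NA marks a missing
#'   estimate.
#' @param variance sampling variance of each estimate.
#' @param nSnps number of SNPs informing each window.
#' @param sliding whether windows are allowed to overlap.
#' @return A [RhoTrack-class] object.
#' @export
RhoTrack <- function(windowStart, windowEnd, rhoPerBp,
                     variance = rep(NA_real_, length(rhoPerBp)),
                     nSnps = rep(NA_integer_, length(rhoPerBp)),
                     sliding = FALSE) {
  new("RhoTrack", windowStart = as.numeric(windowStart),
      windowEnd = as.numeric(windowEnd), rhoPerBp = as.numeric(rhoPerBp),
      variance = as.numeric(variance), nSnps = as.integer(nSnps),
      sliding = isTRUE(sliding))
}

#' Read a genetic map in 3-column HapMap text format
#'
#' Expects a header line followed by whitespace-delimited rows of
#' `position  rate(cM/Mb)  cumulative cM`; an optional leading chromosome
#' column is tolerated.  The rate on the last row (the rate beyond the last
#' position) is ignored, as is conventional for this format.
#'
#' @param path file path.
#' @return A [GeneticMap-class].
#' @seealso [writeGeneticMap()]
#' @export
readGeneticMap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("map file needs a header and at least two data rows: ", path)
  body <- strsplit(trimws(lines[-1]), "\\s+")
  nf <- lengths(body)
  if (any(nf < 3L))
    stop("malformed map row (fewer than 3 fields) at line ",
         which(nf < 3L)[1] + 1L)
  has_chrom <- all(nf >= 4L) | any(is.na(suppressWarnings(
    as.numeric(vapply(body, `[`, "", 1L)))))
  chrom <- "unknown"
  if (has_chrom) {
    chrom <- body[[1]][1]
    body <- lapply(body, `[`, -1L)
  }
  pos <- suppressWarnings(as.numeric(vapply(body, `[`, "", 1L)))
  rate <- suppressWarnings(as.numeric(vapply(body, `[`, "", 2L)))
  cm <- suppressWarnings(as.numeric(vapply(body, `[`, "", 3L)))
  if (anyNA(pos) || anyNA(rate) || anyNA(cm))
    stop("non-numeric map entry at line ",
         which(is.na(pos) | is.na(rate) | is.na(cm))[1] + 1L)
  bad <- which(diff(pos) <= 0)
  if (length(bad))
    stop("positions not strictly increasing at line ", bad[1] + 2L,
         " of ", path)
  if (any(rate[-length(rate)] < 0))
    stop("negative recombination rate at line ",
         which(rate < 0)[1] + 1L, " of ", path)
  ## anchor cumulative cM at 0 and rebuild rates from cM increments so the
  ## object is internally consistent even if the file's rate column was
  ## rounded more aggressively than its cM column
  cm <- cm - cm[1]
  ir <- diff(cm) / (diff(pos) / 1e6)
  ir[ir < 0 & ir > -1e-9] <- 0
  new("GeneticMap", chrom = chrom, positions = pos,
      intervalRates = ir, cumulativeCm = cm)
}

#' Write a genetic map in 3-column HapMap text format
#'
#' @param map a [GeneticMap-class].
#' @param path output file.
#' @param chromColumn write the chromosome as a leading column.
#' @return `path`, invisibly.
#' @export
writeGeneticMap <- function(map, path, chromColumn = FALSE) {
  stopifnot(is(map, "GeneticMap"))
  p <- positions(map)
  r <- c(intervalRates(map), 0)
  cm <- cumulativeCm(map)
  hdr <- "position COMBINED_rate(cM/Mb) Genetic_Map(cM)"
  rows <- sprintf("%.0f %.*g %.*g", p, 15L, r, 15L, cm)
  if (chromColumn) {
    hdr <- paste("chr", hdr)
    rows <- paste(chromName(map), rows)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Uniform-rate genetic map
#'
#' The constant-rate control condition: a single rate over the whole
#' region, e.g. the conventional 1 cM/Mb background.
#'
#' @param chrom chromosome label.
#' @param lengthBp region length in bp; the map covers the 1-based
#'   half-open span `[1, lengthBp + 1)`, i.e. exactly `lengthBp` bases.
#' @param rate cM/Mb, >= 0.
#' @return A [GeneticMap-class] with one uniform interval.
#' @examples
#' totalCm(constantMap("chr20", 1e6, 1))  # 1 cM
#' @export
constantMap <- function(chrom, lengthBp, rate = 1) {
  if (!is.finite(lengthBp) || lengthBp <= 0)
    stop("lengthBp must be positive")
  if (rate < 0) stop("rate must be >= 0")
  GeneticMap(chrom, c(1, lengthBp + 1), rate)
}

#' Synthetic hotspot-structured genetic map
#'
#' Generates a map with a low uniform background punctuated by narrow
#' hotspots, the canonical fine-scale structure of human recombination.
#' Hotspot centres are uniform over the region; intensities are drawn
#' log-uniformly between `hotspotRate/3` and `hotspotRate`.
#'
#' @param chrom label; @param lengthBp region length.
#' @param backgroundRate cM/Mb outside hotspots.
#' @param hotspotRate peak hotspot intensity (cM/Mb).
#' @param nHotspots number of hotspots.
#' @param hotspotWidth hotspot width in bp.
#' @param seed integer seed.
#' @return A [GeneticMap-class].
#' @export
hotspotMap <- function(chrom, lengthBp, backgroundRate = 0.5,
                       hotspotRate = 60, nHotspots = 10,
                       hotspotWidth = 2000, seed = 1) {
  stopifnot(lengthBp > 0, backgroundRate >= 0, hotspotRate >= 0)
  draws <- .local_seed(seed, {
    centres <- sort(runif(nHotspots, hotspotWidth, lengthBp - hotspotWidth))
    if (nHotspots > 1) {  # enforce non-overlap by dropping crowded hotspots
      centres <- centres[c(TRUE, diff(centres) > hotspotWidth * 2)]
    }
    list(centres = centres,
         rates = exp(runif(length(centres), log(hotspotRate / 3),
                           log(hotspotRate))))
  })
  centres <- draws$centres
  rates <- draws$rates
  brk <- sort(unique(c(1, lengthBp + 1,
                       pmax(1, centres - hotspotWidth / 2),
                       pmin(lengthBp, centres + hotspotWidth / 2))))
  mid <- (head(brk, -1) + tail(brk, -1)) / 2
  r <- rep(backgroundRate, length(mid))
  for (i in seq_along(centres)) {
    inhot <- mid >= centres[i] - hotspotWidth / 2 &
             mid < centres[i] + hotspotWidth / 2
    r[inhot] <- rates[i]
  }
  GeneticMap(chrom, brk, r)
}

#' Convert a rho track to a per-generation genetic map
#'
#' rho = 4 * Ne * r with r the per-generation recombination probability per
#' bp, so each window's rate in cM/Mb is `rhoPerBp / (4 * Ne) * 1e8`.
#' Windows with missing estimates are bridged by linear interpolation of
#' cumulative cM (equivalently, the mean rate of the flanking coverage).
#'
#' @param track a [RhoTrack-class] with non-overlapping windows.
#' @param ne diploid effective population size (> 0).
#' @param chrom chromosome label for the resulting map.
#' @return A [GeneticMap-class] over the track's span.
#' @seealso [mapToRho()] for the exact inverse.
#' @examples
#' tr <- RhoTrack(1, 1e6 + 1, 4e-4)
#' intervalRates(rhoToMap(tr, 10000))  # 1 cM/Mb
#' @export
rhoToMap <- function(track, ne = 10000, chrom = "chr1") {
  stopifnot(is(track, "RhoTrack"))
  .check_ne(ne)
  if (track@sliding)
    stop("rhoToMap needs non-overlapping windows; aggregate sliding estimates first")
  o <- order(track@windowStart)
  ws <- track@windowStart[o]; we <- track@windowEnd[o]
  rho <- track@rhoPerBp[o]
  rate <- rho / (4 * ne) * 1e8   # cM/Mb
  ## build breakpoints; gaps between windows and NA windows get NA rate,
  ## then fill by linear interpolation of cumulative cM across the gap
  brk <- ws[1]; rates <- numeric(0)
  for (i in seq_along(ws)) {
    if (ws[i] > brk[length(brk)]) {       # gap before window i
      rates <- c(rates, NA_real_)
      brk <- c(brk, ws[i])
    }
    rates <- c(rates, rate[i])
    brk <- c(brk, we[i])
  }
  rates <- .fill_na_rates(rates, diff(brk))
  GeneticMap(chrom, brk, rates)
}

## linear interpolation of cumulative cM across NA stretches == replacing
## the NA run by the mean rate of its flanking defined intervals, length
## weighted; terminal NA runs copy the nearest defined rate
.fill_na_rates <- function(rates, widths) {
  if (!anyNA(rates)) return(rates)
  ok <- which(!is.na(rates))
  if (!length(ok)) stop("no defined rates in track")
  for (i in which(is.na(rates))) {
    lo <- ok[ok < i]; hi <- ok[ok > i]
    lo <- if (length(lo)) rates[max(lo)] else NA_real_
    hi <- if (length(hi)) rates[min(hi)] else NA_real_
    rates[i] <- mean(c(lo, hi), na.rm = TRUE)
  }
  rates
}

#' Convert a genetic map back to a windowed rho track
#'
#' Exact inverse of [rhoToMap()]: each map interval becomes a window with
#' `rhoPerBp = rate / 1e8 * 4 * Ne`.
#'
#' @param map a [GeneticMap-class].
#' @param ne diploid effective population size.
#' @return A [RhoTrack-class] with one window per map interval.
#' @export
mapToRho <- function(map, ne = 10000) {
  stopifnot(is(map, "GeneticMap"))
  .check_ne(ne)
  p <- positions(map)
  RhoTrack(head(p, -1), tail(p, -1),
           intervalRates(map) / 1e8 * 4 * ne)
}

.check_ne <- function(ne) {
  if (!is.numeric(ne) || length(ne) != 1L || !is.finite(ne) || ne <= 0)
    stop("ne must be a single positive number")
  invisible(ne)
}

#' Windowed mean recombination rates of a map
#'
#' Aggregates a map onto a fixed grid of half-open windows
#' `[start, start + window)` anchored at bp 1.  Each window's rate is the
#' length-weighted mean of the map intervals overlapping it; windows with
#' no map coverage get NA.
#'
#' @param map a [GeneticMap-class].
#' @param window window size in bp (> 0).
#' @return data.frame with columns start, end, rate (cM/Mb), coveredBp.
#' @export
windowRates <- function(map, window) {
  stopifnot(is(map, "GeneticMap"))
  if (!is.finite(window) || window <= 0) stop("window must be > 0")
  p <- positions(map)
  r <- intervalRates(map)
  first <- floor((p[1] - 1) / window) * window + 1
  starts <- first + window * (seq_len(ceiling((p[length(p)] - first) /
                                                window)) - 1)
  ends <- starts + window
  cm_at <- function(x) interpolateCm(map, x)
  covL <- pmin(ends, p[length(p)]) - pmax(starts, p[1])
  covL[covL < 0] <- 0
  cm_in <- cm_at(pmin(ends, p[length(p)])) - cm_at(pmax(starts, p[1]))
  rate <- ifelse(covL > 0, cm_in / (covL / 1e6), NA_real_)
  data.frame(start = starts, end = ends, rate = rate, coveredBp = covL)
}

#' Compare two genetic maps on a common window grid
#'
#' Windows both maps with [windowRates()], restricts to windows covered by
#' both (comparison at similar physical positions), and reports the
#' Spearman rank correlation of windowed rates (ties mid-ranked), the
#' length-weighted mean rate of each map over the shared windows, and
#' their ratio.
#'
#' @param a,b [GeneticMap-class] objects covering a shared region.
#' @param window comparison scale in bp (e.g. 10 kb, 50 kb, 5 Mb).
#' @return list with elements `spearman`, `meanA`, `meanB`, `ratio`
#'   (meanA / meanB) and `table` (the per-window rates).
#' @export
compareMaps <- function(a, b, window = 50000) {
  wa <- windowRates(a, window)
  wb <- windowRates(b, window)
  shared <- merge(wa, wb, by = c("start", "end"), suffixes = c("A", "B"))
  shared <- shared[!is.na(shared$rateA) & !is.na(shared$rateB), ]
  if (nrow(shared) < 3L)
    stop("fewer than 3 shared windows; correlation undefined")
  wgtA <- shared$coveredBpA; wgtB <- shared$coveredBpB
  meanA <- sum(shared$rateA * wgtA) / sum(wgtA)
  meanB <- sum(shared$rateB * wgtB) / sum(wgtB)
  list(spearman = cor(shared$rateA, shared$rateB, method = "spearman"),
       meanA = meanA, meanB = meanB,
       ratio = meanA / meanB,
       table = shared[, c("start", "end", "rateA", "rateB")])
}

#' Cumulative genetic distance at arbitrary positions
#'
#' Linear interpolation of cumulative cM inside the map; positions outside
#' the map clamp to the terminal cumulative values (no extrapolation).
#'
#' @param map a [GeneticMap-class].
#' @param pos numeric vector of physical positions (bp).
#' @return numeric vector of cM values, non-decreasing in `pos`.
#' @export
interpolateCm <- function(map, pos) {
  stopifnot(is(map, "GeneticMap"))
  approx(positions(map), cumulativeCm(map), xout = pos, rule = 2,
         ties = "ordered")$y
}
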