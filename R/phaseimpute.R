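#' Parameters of the haplotype-copying HMM
#'
#' @param ne diploid effective population size; together with the genetic
#'   map it sets the template-switch probability
#'   `s_j = 1 - exp(-4 * ne * d_j / K)` for Morgan distance `d_j` between
#'   adjacent sites and K copying templates.
#' @param eps per-site copying-error (emission mismatch) probability.
#' @return An [HmmParams-class].
#' @export
HmmParams <- function(ne = 10000, eps = 1e-3) {
  new("HmmParams", ne = as.numeric(ne), eps = as.numeric(eps))
}

## per-interval switch probabilities for K templates
.switch_probs <- function(map, sitePos, ne, K) {
  cm <- interpolateCm(map, sitePos)
  d <- diff(cm) / 100                      # Morgans
  1 - exp(-4 * ne * d / K)
}

## emission matrix (K templates x S sites) for a 0/1/NA target
.ls_emissions <- function(target, templates, eps) {
  K <- nrow(templates); S <- ncol(templates)
  e <- matrix(1, K, S)
  obs <- which(!is.na(target))
  if (length(obs)) {
    tt <- matrix(target[obs], K, length(obs), byrow = TRUE)
    e[, obs] <- ifelse(templates[, obs, drop = FALSE] == tt, 1 - eps, eps)
  }
  e
}

## scaled forward pass; returns alpha (K x S, columns sum to 1) and logLik
.ls_forward <- function(emis, s) {
  K <- nrow(emis); S <- ncol(emis)
  alpha <- matrix(0, K, S)
  a <- emis[, 1] / K
  c1 <- sum(a)
  if (c1 <= 0) stop("zero forward probability at site 1")
  alpha[, 1] <- a / c1
  ll <- log(c1)
  if (S > 1) for (j in 2:S) {
    m <- (1 - s[j - 1]) * alpha[, j - 1] + s[j - 1] / K
    a <- emis[, j] * m
    cj <- sum(a)
    if (cj <= 0) stop("zero forward probability at site ", j)
    alpha[, j] <- a / cj
    ll <- ll + log(cj)
  }
  list(alpha = alpha, logLik = ll)
}

#' Forward-backward pass of the haplotype-copying HMM
#'
#' The hidden state at each site is the reference haplotype being copied;
#' between adjacent sites the chain switches with probability
#' `s_j = 1 - exp(-4 * Ne * d_j / K)` (Morgan distance `d_j` from the
#' genetic map), landing uniformly on the K templates; emissions match
#' the copied allele with probability `1 - eps`; missing target sites
#' emit uniformly.  Arithmetic is scaled so that underflow cannot occur
#' silently.
#'
#' @param target integer vector of 0/1 alleles with NA for missing.
#' @param refs a [HaplotypePanel-class] (or K x S 0/1 matrix) of copying
#'   templates on the same site axis.
#' @param map a [GeneticMap-class].
#' @param params an [HmmParams-class].
#' @param sitePos site positions (taken from `refs` when it is a panel).
#' @return list: `posterior` (K x S, columns sum to 1), `postAllele1`
#'   (per-site posterior probability of allele 1), `logLik`.
#' @export
lsForwardBackward <- function(target, refs, map, params,
                              sitePos = NULL) {
  stopifnot(is(params, "HmmParams"))
  if (is(refs, "HaplotypePanel")) {
    sitePos <- positions(refs)
    templates <- haplotypes(refs)
  } else {
    templates <- refs
    if (is.null(sitePos)) stop("sitePos required when refs is a matrix")
  }
  if (length(target) != ncol(templates))
    stop("target and templates must share the site axis")
  K <- nrow(templates); S <- ncol(templates)
  s <- if (S > 1) .switch_probs(map, sitePos, params@ne, K) else numeric(0)
  emis <- .ls_emissions(target, templates, params@eps)
  fw <- .ls_forward(emis, s)
  ## scaled backward pass
  beta <- matrix(0, K, S)
  beta[, S] <- 1
  if (S > 1) for (j in (S - 1):1) {
    eb <- emis[, j + 1] * beta[, j + 1]
    v <- (1 - s[j]) * eb + s[j] * mean(eb)
    beta[, j] <- v / sum(v * fw$alpha[, j]) * 1  # scale against alpha
  }
  post <- fw$alpha * beta
  post <- sweep(post, 2, colSums(post), "/")
  list(posterior = post,
       postAllele1 = colSums(post * templates),
       logLik = fw$logLik)
}

#' Phase a cohort by iterative conditional haplotype sampling
#'
#' Phases are initialised randomly at heterozygous sites; each sweep
#' re-samples every individual's haplotype pair from the copying model
#' conditioned on the current haplotypes of the other individuals plus
#' the reference panel (when given): a copying path is sampled for each
#' current haplotype, then the phase at each heterozygous site is
#' re-drawn from the two copied template alleles.  After burn-in the
#' per-heterozygote consensus phase (majority across retained sweeps,
#' sweeps oriented by the first heterozygous site) is returned with its
#' agreement fraction as certainty.
#'
#' @param gm a [GenotypeMatrix-class] of the individuals to phase.
#' @param map a [GeneticMap-class].
#' @param params an [HmmParams-class].
#' @param ref optional [HaplotypePanel-class] of reference templates on
#'   the same site axis.
#' @param nIter total sweeps (default 20); @param nBurn burn-in sweeps
#'   (default 10), `nIter > nBurn >= 0`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A [PhasedCohort-class].
#' @export
phaseCohort <- function(gm, map, params = HmmParams(), ref = NULL,
                        nIter = 20, nBurn = 10, seed = 1) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!(nIter > nBurn && nBurn >= 0)) stop("need nIter > nBurn >= 0")
  G <- genotypes(gm)
  N <- nrow(G); S <- ncol(G)
  pos <- positions(gm)
  refH <- NULL
  if (!is.null(ref)) {
    stopifnot(is(ref, "HaplotypePanel"))
    .assert_same_sites(pos, positions(ref), "cohort and reference panel")
    refH <- haplotypes(ref)
  }
  nTemplates <- 2 * (N - 1) + if (is.null(refH)) 0 else nrow(refH)
  if (nTemplates < 1) {
    warning("no copying templates (single individual, no reference); ",
            "returning an uninformed random phase")
    return(.random_phase(gm, seed))
  }

  .local_seed(.derive_seed(seed, "phase"), {
    h1 <- h2 <- matrix(NA_integer_, N, S)
    for (i in seq_len(N)) {
      g <- G[i, ]
      hom <- !is.na(g) & g != 1L
      h1[i, hom] <- h2[i, hom] <- as.integer(g[hom] / 2L)
      het <- which(!is.na(g) & g == 1L)
      if (length(het)) {
        a <- rbinom(length(het), 1L, 0.5)
        h1[i, het] <- a
        h2[i, het] <- 1L - a
      }
    }
    hetList <- lapply(seq_len(N), function(i)
      which(!is.na(G[i, ]) & G[i, ] == 1L))
    votes <- matrix(0, N, S)     # votes for oriented h1 == 1 at het sites
    nVotes <- 0L
    orient <- vector("list", N)  # per-individual orientation reference

    path2 <- matrix(NA_integer_, N, S)   # chain-2 copying paths
    for (it in seq_len(nIter)) {
      for (i in seq_len(N)) {
        others <- setdiff(seq_len(N), i)
        templates <- rbind(h1[others, , drop = FALSE],
                           h2[others, , drop = FALSE])
        if (!is.null(refH)) templates <- rbind(templates, refH)
        ## template alleles may be NA (missing genotypes); emit uniformly
        K <- nrow(templates)
        s <- if (S > 1) .switch_probs(map, pos, params@ne, K) else numeric(0)
        tpl <- templates
        tpl[is.na(tpl)] <- -1L   # never matches -> uniform emission
        ## chain 1 conditioned on chain 2's current template path with the
        ## per-site phase marginalised out (good mixing: whole-segment
        ## phase flips are reachable in one path update)
        al2 <- if (all(is.na(path2[i, ]))) rep(-1L, S)
               else tpl[cbind(pmin(path2[i, ], K), seq_len(S))]
        p1 <- .ls_chain_path(tpl, G[i, ], al2, s, params@eps, runif(S))
        al1 <- tpl[cbind(p1, seq_len(S))]
        p2 <- .ls_chain_path(tpl, G[i, ], al1, s, params@eps, runif(S))
        path2[i, ] <- p2
        het <- hetList[[i]]
        if (length(het)) {
          a1 <- al1[het]
          a2 <- tpl[cbind(p2[het], het)]
          e <- params@eps
          w1 <- ifelse(a1 == 1L, 1 - e, ifelse(a1 == 0L, e, 0.5)) *
                ifelse(a2 == 0L, 1 - e, ifelse(a2 == 1L, e, 0.5))
          w0 <- ifelse(a1 == 0L, 1 - e, ifelse(a1 == 1L, e, 0.5)) *
                ifelse(a2 == 1L, 1 - e, ifelse(a2 == 0L, e, 0.5))
          draw <- rbinom(length(het), 1L, w1 / (w1 + w0))
          h1[i, het] <- draw
          h2[i, het] <- 1L - draw
        }
      }
      if (it > nBurn) {
        nVotes <- nVotes + 1L
        for (i in seq_len(N)) {
          het <- hetList[[i]]
          if (!length(het)) next
          cur <- h1[i, het]
          ## orient against the first retained sweep (majority agreement)
          ## so that chain label switching cannot corrupt the votes
          if (is.null(orient[[i]])) orient[[i]] <- cur
          flip <- mean(cur == orient[[i]]) < 0.5
          votes[i, het] <- votes[i, het] + if (flip) 1L - cur else cur
        }
      }
    }

    out1 <- h1; out2 <- h2
    cert <- matrix(NA_real_, N, S)
    for (i in seq_len(N)) {
      het <- hetList[[i]]
      if (!length(het)) next
      freq <- votes[i, het] / nVotes
      call1 <- as.integer(freq >= 0.5)
      out1[i, het] <- call1
      out2[i, het] <- 1L - call1
      cert[i, het] <- pmax(freq, 1 - freq)
    }
    new("PhasedCohort", hap1 = out1, hap2 = out2, certainty = cert,
        positions = pos, chrom = chromName(gm), sampleIds = sampleIds(gm))
  })
}

.random_phase <- function(gm, seed) {
  G <- genotypes(gm)
  N <- nrow(G); S <- ncol(G)
  .local_seed(.derive_seed(seed, "randphase"), {
    h1 <- h2 <- matrix(NA_integer_, N, S)
    cert <- matrix(NA_real_, N, S)
    for (i in seq_len(N)) {
      g <- G[i, ]
      hom <- !is.na(g) & g != 1L
      h1[i, hom] <- h2[i, hom] <- as.integer(g[hom] / 2L)
      het <- which(!is.na(g) & g == 1L)
      if (length(het)) {
        a <- rbinom(length(het), 1L, 0.5)
        h1[i, het] <- a
        h2[i, het] <- 1L - a
        cert[i, het] <- 0.5
      }
    }
    new("PhasedCohort", hap1 = h1, hap2 = h2, certainty = cert,
        positions = positions(gm), chrom = chromName(gm),
        sampleIds = sampleIds(gm))
  })
}

#' Impute masked genotypes from a reference panel
#'
#' Each pre-phased target haplotype is run through the copying HMM
#' against the reference panel; the dosage at a masked site is the sum
#' over the two haplotypes of the posterior-weighted reference alleles,
#' and the hard call is the rounded dosage.  Unmasked genotypes pass
#' through unchanged.
#'
#' @param masked the masked [GenotypeMatrix-class] (masked columns NA).
#' @param mask the [MaskSet-class] from [maskRandom()].
#' @param ref a [HaplotypePanel-class] covering all sites.
#' @param map a [GeneticMap-class].
#' @param params an [HmmParams-class].
#' @param phased a [PhasedCohort-class] for the masked matrix (haplotypes
#'   NA at masked sites).
#' @return An [ImputedGenotypes-class].
#' @export
imputeMasked <- function(masked, mask, ref, map, params = HmmParams(),
                         phased) {
  stopifnot(is(masked, "GenotypeMatrix"), is(mask, "MaskSet"),
            is(ref, "HaplotypePanel"), is(phased, "PhasedCohort"))
  .assert_same_sites(positions(masked), positions(ref),
                     "target and reference panel")
  .assert_same_sites(positions(masked), positions(phased),
                     "target and phased input")
  G <- genotypes(masked)
  N <- nrow(G); S <- ncol(G)
  ms <- mask@maskedSites
  dosage <- matrix(NA_real_, N, S)
  ok <- !is.na(G)
  dosage[ok] <- G[ok]
  refH <- haplotypes(ref)
  pos <- positions(masked)
  for (i in seq_len(N)) {
    t1 <- phased@hap1[i, ]; t1[ms] <- NA_integer_
    t2 <- phased@hap2[i, ]; t2[ms] <- NA_integer_
    fb1 <- lsForwardBackward(t1, refH, map, params, sitePos = pos)
    fb2 <- lsForwardBackward(t2, refH, map, params, sitePos = pos)
    dosage[i, ms] <- fb1$postAllele1[ms] + fb2$postAllele1[ms]
  }
  hard <- round(dosage)
  storage.mode(hard) <- "integer"
  new("ImputedGenotypes", dosage = dosage, hardCalls = hard,
      maskedSites = as.integer(ms), positions = pos,
      sampleIds = sampleIds(masked))
}

#' Cumulative expected template-switch intensity along a map
#'
#' The summed switch intensity `sum_j 4 * Ne * d_j / K` (the negative log
#' of the stay probabilities) between consecutive sites.  It depends on
#' the map only through the total genetic distance spanned, so any two
#' maps of equal total cM conserve it exactly.
#'
#' @param map a [GeneticMap-class]; @param sitePos site positions;
#' @param ne effective population size; @param K number of templates.
#' @return scalar intensity.
#' @export
switchIntensity <- function(map, sitePos, ne, K) {
  s <- .switch_probs(map, sitePos, ne, K)
  sum(-log(1 - s))
}
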