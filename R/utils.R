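## Seed plumbing.  Every randomised operation takes an explicit integer
## seed; .local_seed runs code under that seed without disturbing the
## caller's RNG state, and .derive_seed spawns reproducible per-stage
## sub-seeds (kept below 2^31) from one root seed.

.local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% 1000003
  as.integer(((abs(seed) %% 65011) * 48271 + h * 16807 + 12345) %%
               2147483647) + 1L
}

#' @noRd
.assert_same_sites <- function(posA, posB, what = "objects") {
  if (length(posA) != length(posB) || any(posA != posB))
    stop(what, " must share the same site axis")
  invisible(TRUE)
}
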