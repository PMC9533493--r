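# Shared fixture builders; everything is generated in code at test time.

# small composition with controlled occupancies: part j is present in the
# first present[j] of n samples
toyOccupancyTable <- function(present, n = 10) {
  p <- length(present)
  m <- matrix(0, n, p, dimnames = list(paste0("S", 1:n), paste0("P", 1:p)))
  for (j in seq_len(p)) m[seq_len(present[j]), j] <- 1
  compositionTable(m)
}

# strictly positive random composition
randomComposition <- function(n = 12, p = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p)), n, p,
              dimnames = list(paste0("S", 1:n), paste0("P", 1:p)))
  compositionTable(m)
}

# small simulated population shared by the heavier tests (memoised per
# session so several test files can reuse it)
.popCache <- new.env(parent = emptyenv())
smallPop <- function(n = 120, nSnps = 600, seed = 11, ...) {
  key <- paste(n, nSnps, seed, deparse(list(...)), collapse = "_")
  if (!is.null(.popCache[[key]])) return(.popCache[[key]])
  spec <- simSpec(nAnimals = n, nSnps = nSnps, seed = seed, ...)
  pop <- simulatePopulation(spec)
  pop$spec <- spec
  .popCache[[key]] <- pop
  pop
}

quickConfig <- function(seed = 5, nIter = 6000, burnIn = 1500, thin = 3) {
  mcmcConfig(nIter = nIter, burnIn = burnIn, thin = thin, seed = seed)
}
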