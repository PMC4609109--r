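# Shared fixtures built in code. Small datasets are cached per test run
# so several test files can reuse the same simulation.

.fixtureCache <- new.env(parent = emptyenv())

fixtureDataset <- function(nGenes = 1000, seed = 11, ...) {
  key <- paste(nGenes, seed, deparse(list(...)), collapse = "|")
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- simulateDataset(nGenes = nGenes, seed = seed,
                                            ...)
  .fixtureCache[[key]]
}

fixtureProfiles <- function(...) {
  ds <- fixtureDataset(...)
  averageReplicates(globalNormalize(experiment(ds)))
}

# Noise-free dataset for exact algebraic identities.
noiselessDataset <- function(nGenes = 300, seed = 5, epistasisCoef = 0) {
  simulateDataset(nGenes = nGenes, seed = seed, noiseSd = 0,
                  epistasisCoef = epistasisCoef)
}

# A tiny hand-made ProfileSet.
toyProfiles <- function(values) {
  methods::new("ProfileSet", values = values)
}

# Brute-force running-sum enumeration, independent of the package's
# closed-form extremum search: walks every rank position.
bruteForceES <- function(scores, geneset, exponent = 1) {
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  member <- ranked %in% geneset
  w <- unname(abs(scores[ord])^exponent)
  NR <- sum(w[member])
  if (NR == 0) {
    w[member] <- 1
    NR <- sum(w[member])
  }
  K <- sum(member)
  N <- length(ranked)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (member[i]) w[i] / NR else -1 / (N - K)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exact binomial upper-tail by direct summation of choose() terms.
exactBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}
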