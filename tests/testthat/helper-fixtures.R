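# Shared small fixtures, built in code.

# tiny deterministic count table with named taxa/samples
toyTable <- function(nTaxa = 6, nSamples = 8, lambda = 4, seed = 100) {
  set.seed(seed)
  m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa, nSamples,
              dimnames = list(sprintf("t%02d", seq_len(nTaxa)),
                              sprintf("s%02d", seq_len(nSamples))))
  m
}

# one-site generator config small enough for fast tests
smallConfig <- function(seed = 42, n = 24, nTaxa = 80, burdenEffect = 1,
                        ...) {
  metacomConfig(nHosts = n, sites = c(gut = n), nTaxa = nTaxa,
                determinism = 0.7, burdenEffect = burdenEffect,
                nResponders = 4, librarySizeMean = 3000, seed = seed, ...)
}

# three-site config used by pipeline tests
miniPipelineConfig <- function(seed = 7) {
  metacomConfig(nHosts = 14, sites = c(stomach = 12, cloaca = 12, faeces = 8),
                nTaxa = 50, nResponders = 3, librarySizeMean = 2000,
                seed = seed)
}
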