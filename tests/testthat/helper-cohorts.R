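# Shared fixtures, generated in code and cached per test run.

# Hand-built store: 4 loci x 5 samples with known codes.
tinyStore <- function() {
  codes <- rbind(c(0, 0, 1, 2, 0),
                 c(2, 2, 2, 1, 2),
                 c(0, -1, 1, 0, 0),
                 c(0, 0, 0, 0, 0))
  loci <- data.frame(chr = c("1", "1", "2", "19"),
                     pos = c(100L, 200L, 300L, 400L),
                     ref = c("A", "C", "G", "T"), alt = c("T", "G", "A", "C"),
                     gene = c("GA", "GB", "GC", "APOE"))
  samples <- data.frame(sample_id = paste0("s", 1:5),
                        cohort = c("X", "X", "X", "Y", "Y"),
                        status = c("case", "control", "case", "control", "case"),
                        age = c(70, 85, 66, 90, 74),
                        stringsAsFactors = FALSE)
  GenotypeStore(codes, loci, samples)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# Small default-spec cohort (all planted effects present).
smallCohort <- function() cachedFixture("small", function()
  generateCohort(synthSpec(nSamples = 800, nSnps = 400, seed = 3)))

# Micro cohort + micro net config for engine-level tests.
microCohort <- function() cachedFixture("micro", function()
  generateCohort(synthSpec(nSamples = 300, nSnps = 150, nCohorts = 4, seed = 11)))

microNet <- function(seed = 1) netConfig(hidden = c(6, 3), maxEpochs = 60, seed = seed)

poolOf <- function(cohort, seed = 1) {
  balancedPool(cohort$samples, filterCohorts(cohort$samples), seed = seed)
}

plantedKey <- function(cohort, name) {
  pl <- cohort$manifest$planted
  pl$key[match(name, pl$name)]
}
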