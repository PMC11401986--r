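# Shared fixtures. The two heavy batches (the standard 23-sample study
# preset and an independent training batch) are simulated once per test run
# and cached, since several test files exercise them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Quick in-memory genotype table without touching the IO layer.
toy_table <- function(gtypes, individual = "a", ...) {
  data.frame(individual = individual, gtype = gtypes, ...)
}

# Small end-to-end batch for module-level tests.
small_batch <- function(n_samples = 6L, n_snps = 2000L, seed = 11L, ...) {
  simulate_batch(sim_config(n_samples = n_samples, n_snps = n_snps,
                            seed = seed, ...),
                 tempfile("smallbatch"))
}

load_batch <- function(batch) {
  assemble_table(read_samplesheet(batch$samplesheet),
                 read_manifest(batch$manifest),
                 read_cluster(batch$cluster))
}

# Standard study preset: 23 haploid samples, two families, 20,000 SNPs,
# ADI 0.10, ADO 0.20 (inert in haploid mode), fixed seed.
study_batch <- function() cached("study_batch", function() {
  simulate_batch(sim_config(seed = 101L), tempfile("studybatch"))
})

study_table <- function() cached("study_table", function() {
  calculate_ma(filter_informative(load_batch(study_batch())))
})

# Independent labelled batch used only to train the first layer.
training_model <- function() cached("training_model", function() {
  b <- simulate_batch(sim_config(n_samples = 10L, seed = 202L),
                      tempfile("trainbatch"))
  t <- calculate_ma(filter_informative(load_batch(b)))
  train_rf(t[t$gtype != "NC", ], truth_labels(t, b$truth)[t$gtype != "NC"],
           seed = 7L)
})

# Study batch scored with a model whose first layer saw none of its data.
study_scored <- function() cached("study_scored", function() {
  t <- study_table()
  model <- rfgda(t, rf = training_model(), seed = 7L)
  score_genotypes(t, model)
})
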