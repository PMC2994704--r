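# Shared small synthetic corpus + trained model, built once per test run.
# Kept deliberately small (4 families x 6 members, one superclass) so the
# transfer/evaluation unit tests stay fast; the acceptance tests build
# their own full-size corpora.

fixture_env <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (!is.null(fixture_env$fx)) return(fixture_env$fx)
  params <- simulation_params(n_families = 4, members_per_family = 6,
                              superclasses = 2, seed = 301)
  corpus <- simulate_corpus(params)
  cache <- new_feature_cache()
  ds <- assemble_pair_dataset(corpus$refs, corpus$pfms, 2,
                              taxonomy = corpus$taxonomy, seed = 301,
                              mosta_alpha = 0.05, cache = cache)
  grid <- expand.grid(cost = c(0.5, 2, 8), epsilon = 0.01,
                      gamma = c(0.03125, 0.125))
  model <- train_superclass_model(ds, grid, runs = 2, folds = 5, seed = 301)
  fixture_env$fx <- list(corpus = corpus, dataset = ds, model = model,
                         cache = cache)
  fixture_env$fx
}

# a tiny hand-built TF pair with known PFMs, for direct feature tests
toy_tf <- function(accession, sequence, dbd = c(11, 30), taxon = "S1",
                   superclass = 2L, pfm_id = NULL) {
  tf_record(accession, taxon, superclass, sequence, dbd, pfm_id = pfm_id)
}
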