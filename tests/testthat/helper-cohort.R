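# Shared synthetic-cohort builders. Tile sizes here are deliberately small
# so the suite stays fast; the class-separating morphology defaults are the
# generator's own.

test_profiles <- function(width = 320, height = 320, mpp = 0.5, seed = 1L) {
  list(
    cortex = slide_spec(width, height, mpp,
                        counts = c(CB = 6, NFT = 4, TA = 2, TF = 18, non_tau = 6),
                        nuclei = 15, seed = seed),
    putamen = slide_spec(width, height, mpp,
                         counts = c(CB = 5, NFT = 3, TA = 3, TF = 20, non_tau = 6),
                         nuclei = 15, seed = seed),
    STN_GP = slide_spec(width, height, mpp,
                        counts = c(CB = 4, NFT = 2, TA = 0, TF = 30, non_tau = 6),
                        nuclei = 15, seed = seed),
    dentate = slide_spec(width, height, mpp,
                         counts = c(CB = 3, NFT = 4, TA = 0, TF = 20, non_tau = 6),
                         nuclei = 15, seed = seed)
  )
}

# Lazily built and cached labelled feature tables (shared across tests).
.cohort_cache <- new.env(parent = emptyenv())

cached_features <- function(name, n_donors, seed) {
  if (!exists(name, envir = .cohort_cache)) {
    coh <- generate_cohort(test_profiles(), n_donors = n_donors, seed = seed)
    h <- harvest_cohort(coh)
    h <- h[!is.na(h$class), , drop = FALSE]
    h$screen <- ifelse(h$class == "non_tau", "non_tau", "tau")
    assign(name, h, envir = .cohort_cache)
  }
  get(name, envir = .cohort_cache)
}

train_features <- function() cached_features("train", n_donors = 10, seed = 101)
heldout_features <- function() cached_features("heldout", n_donors = 3, seed = 707)

# A fast fixed forest configuration for tests that do not exercise tuning.
fast_config <- function() {
  list(n_features_to_select = 40, n_estimators = 200, max_features = 0.6,
       max_depth = Inf, min_samples_split = 2, min_samples_leaf = 1,
       sampling_strategy = "auto", max_samples = Inf)
}
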