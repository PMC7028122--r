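# shared fixtures, built in code and cached across test files

.tabvis_cache <- new.env(parent = emptyenv())

# standard synthetic cohort used by the analysis-level tests
cached_cohort <- function() {
  if (is.null(.tabvis_cache$cohort))
    .tabvis_cache$cohort <- generate_cohort(n_search = 50, n_faces = 30,
                                            seed = 101)
  .tabvis_cache$cohort
}

cached_evaluation <- function() {
  if (is.null(.tabvis_cache$evaluation))
    .tabvis_cache$evaluation <- evaluate_cohort(cached_cohort(),
                                                n_boot = 2000, seed = 7)
  .tabvis_cache$evaluation
}

# a reproducible random landmark face
random_face <- function(seed, id = paste0("f", seed), sd = 10) {
  set.seed(seed)
  landmark_face(matrix(rnorm(254, sd = sd), ncol = 2), id = id)
}
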