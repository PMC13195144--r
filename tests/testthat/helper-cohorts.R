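# Memoized reference cohorts: the acceptance criteria and several module
# tests reuse the same phantom cohorts, so connectomes are built once per
# (seed, effect) and cached for the duration of the test run.
.petconn_test_cache <- new.env(parent = emptyenv())

ref_cohort <- function(seed, n_controls = 20, n_patients = 10,
                       effect = TRUE) {
  key <- sprintf("coh_%d_%d_%d_%d", seed, n_controls, n_patients, effect)
  if (!is.null(.petconn_test_cache[[key]])) {
    return(.petconn_test_cache[[key]])
  }
  spec <- cohort_spec(
    n_controls, n_patients,
    effect = if (effect) {
      effect_spec("Heart Right", mean_shift = 1.5, variance_inflation = 1.5)
    } else {
      effect_spec(character(0))
    },
    seed = seed
  )
  coh <- generate_cohort(spec)
  conns <- lapply(coh$subjects,
                  function(s) reduce_to_roi(build_connectome(s)))
  out <- list(subjects = coh$subjects, groups = coh$groups, conns = conns,
              y = as.integer(coh$groups == "patient"))
  assign(key, out, envir = .petconn_test_cache)
  out
}

# edges of a symmetric matrix ranked by decreasing value, as node pairs
top_edges <- function(M, k) {
  ut <- which(upper.tri(M), arr.ind = TRUE)
  o <- order(M[ut], decreasing = TRUE)[seq_len(k)]
  cbind(rownames(M)[ut[o, 1]], rownames(M)[ut[o, 2]])
}
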