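# Shared synthetic fixtures, built in code at test time.

quinary_spectra <- local({
  S <- NULL
  function() {
    if (is.null(S)) S <<- default_pure_spectra()
    S
  }
})

# Noiseless, artifact-free dataset on the 25-sample training design
clean_quinary <- function() {
  generate_dataset(generate_design(), quinary_spectra())
}

# Training-design dataset with a planted concentration-independent baseline
# artifact (rank `rank`) and optional noise
artifact_quinary <- function(seed = 7L, noise_sd = 0, rank = 2L,
                             scale = 0.05) {
  generate_dataset(generate_design(), quinary_spectra(),
                   artifact_config(noise_sd = noise_sd,
                                   baseline_rank = rank,
                                   baseline_scale = scale, seed = seed))
}

# Paired calibration/validation study with the same artifact structure in
# both sets
artifact_study <- function(seed = 7L, noise_sd = 0, rank = 2L,
                           scale = 0.05) {
  simulate_study(artifact_config(noise_sd = noise_sd, baseline_rank = rank,
                                 baseline_scale = scale, seed = seed),
                 S = quinary_spectra())
}

# A small full-rank random calibration problem for oracle comparisons
random_system <- function(n, k, p, seed = 1L) {
  set.seed(seed)
  C <- matrix(runif(n * k, 1, 10), n, k)
  S <- matrix(runif(k * p), k, p)
  list(C = C, S = S, A = C %*% S)
}
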