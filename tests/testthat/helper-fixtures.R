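# Shared fixtures: a small toy brain and cached simulated cohorts.
# Everything is generated in code at test time; sizes are kept small so the
# whole suite runs quickly on one CPU.

toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_toy_brain(n_pairs = 4, n_subcortical = 2,
                                subdivisions = 2)
    cache
  }
})

# 642-vertex model for geometry-resolution-sensitive checks
toy_model_fine <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_toy_brain(n_pairs = 8, n_subcortical = 3,
                                subdivisions = 3)
    cache
  }
})

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_subjects = 4, sessions = "baseline",
                           conditions = c("rest", "task", "empty"),
                           events_per_recording = 3000, seed = 11)
      cache <<- c(simulate_cohort(cfg, toy_model()), list(config = cfg))
    }
    cache
  }
})

# brute-force nearest-vertex oracle, deliberately independent of the
# vectorized implementation
brute_nearest <- function(p, vertices) {
  d <- sqrt(colSums((t(vertices) - p)^2))
  i <- which(d == min(d))[1]
  list(index = i, dist = d[i])
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  ca * diag(3) + sa * rbind(c(0, -a[3], a[2]),
                            c(a[3], 0, -a[1]),
                            c(-a[2], a[1], 0)) +
    (1 - ca) * outer(a, a)
}
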