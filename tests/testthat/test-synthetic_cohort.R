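test_that("identical seeds give identical event tables", {
  model <- toy_model()
  cfg <- cohort_config(n_subjects = 2, sessions = "baseline",
                       conditions = c("rest", "empty"),
                       events_per_recording = 500, seed = 99)
  a <- simulate_cohort(cfg, model)
  b <- simulate_cohort(cfg, model)
  expect_identical(a$events, b$events)
  expect_identical(a$subjects, b$subjects)
  cfg2 <- cfg; cfg2$seed <- 100
  c_ <- simulate_cohort(cfg2, model)
  expect_false(identical(a$events, c_$events))
})

test_that("per-subject streams are stable under cohort size changes", {
  model <- toy_model()
  mk <- function(n) cohort_config(n_subjects = n, sessions = "baseline",
                                  conditions = "rest",
                                  events_per_recording = 300, seed = 5)
  small <- simulate_cohort(mk(2), model)
  large <- simulate_cohort(mk(4), model)
  s1 <- function(x) x$events[x$events$subject_id == "S001", ]
  expect_identical(s1(small), s1(large))
})

test_that("zero-noise isotropic config puts count fractions at volume fractions", {
  model <- toy_model()
  cfg <- cohort_config(n_subjects = 3, sessions = "baseline",
                       conditions = "rest", events_per_recording = 60000,
                       subject_effect_sd = 0, session_noise_sd = 0,
                       dark_fraction = 0, seed = 4)
  sim <- simulate_cohort(cfg, model)
  d <- compute_density(count_events(sim$events, model$regions))
  # multinomial probabilities equal volume fractions, so rho -> 1
  expect_true(all(abs(d$rho - 1) < 0.15))
  expect_lt(mean(abs(d$rho - 1)), 0.05)
})

test_that("generated brain events respect exclusion and tangency invariants", {
  model <- toy_model()
  sim <- small_cohort()
  ev <- sim$events
  expect_true(all(validate_events(ev, model)))
  brain <- ev[!ev$is_dark, ]
  r <- sqrt(brain$x_mm^2 + brain$y_mm^2 + brain$z_mm^2)
  expect_true(all(r >= model$exclusion_radius))
  dir <- as.matrix(brain[, c("dx", "dy", "dz")])
  loc <- as.matrix(brain[, c("x_mm", "y_mm", "z_mm")])
  expect_lt(max(abs(rowSums(dir * loc) / r)), 1e-6)
  expect_equal(sqrt(rowSums(dir^2)), rep(1, nrow(dir)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("symptom labels follow the severity cut-off (inclusive boundary)", {
  expect_true(assign_labels(15, 15))
  expect_false(assign_labels(14.9, 15))
  expect_true(assign_labels(63, 63))
  expect_identical(assign_labels(c(0, 62.9, 63, 100), 63),
                   c(FALSE, FALSE, TRUE, TRUE))
  model <- toy_model()
  cfg <- cohort_config(n_subjects = 30, sessions = "baseline",
                       conditions = "rest", events_per_recording = 200,
                       symptom_specs = list(list(name = "insomnia",
                                                 regions = c(1L, 5L),
                                                 delta = 0.4,
                                                 prevalence = 0.5,
                                                 cutoff = 15)),
                       seed = 8)
  sim <- simulate_cohort(cfg, model)
  expect_identical(sim$subjects$label_insomnia,
                   assign_labels(sim$subjects$severity_insomnia, 15))
  expect_identical(sim$subjects$cohort,
                   ifelse(sim$subjects$label_insomnia, "symptomatic",
                          "control"))
})

test_that("a planted symptom effect shifts the affected region's density", {
  model <- toy_model()
  delta <- 0.5
  cfg <- cohort_config(n_subjects = 60, sessions = "baseline",
                       conditions = "rest", events_per_recording = 4000,
                       subject_effect_sd = 0.1, session_noise_sd = 0.05,
                       dark_fraction = 0,
                       symptom_specs = list(list(name = "s", regions = 3L,
                                                 delta = delta,
                                                 prevalence = 0.5,
                                                 cutoff = 15)),
                       seed = 12)
  sim <- simulate_cohort(cfg, model)
  d <- compute_density(count_events(sim$events, model$regions))
  d3 <- d[d$region_id == 3L, ]
  lab <- sim$subjects$label_s[match(d3$subject_id, sim$subjects$subject_id)]
  ratio <- mean(d3$rho[lab]) / mean(d3$rho[!lab])
  # the log-rate shift inflates the region's share by about exp(delta),
  # shrunk by renormalization over the other regions; Monte-Carlo band
  expect_gt(ratio, exp(delta) * 0.75)
  expect_lt(ratio, exp(delta) * 1.15)
})

test_that("empty-room and resting densities correlate across subjects", {
  model <- toy_model()
  cfg <- cohort_config(n_subjects = 20, sessions = "baseline",
                       conditions = c("rest", "empty"),
                       events_per_recording = 3000,
                       subject_effect_sd = 0.05, session_noise_sd = 0.05,
                       dark_fraction = 0.35, seed = 31)
  sim <- simulate_cohort(cfg, model)
  d <- compute_density(count_events(sim$events, model$regions))
  rest <- d[d$condition == "rest", ]
  empty <- d[d$condition == "empty", ]
  corr <- eq3_correlations(rest, empty)
  expect_true(all(corr$corr >= -1 & corr$corr <= 1, na.rm = TRUE))
  # dark contamination is shared between same-day rest and empty recordings
  expect_gt(mean(corr$corr, na.rm = TRUE), 0.2)
})

test_that("marginal count expectation matches the softmax rate model", {
  model <- toy_model()
  cfg <- cohort_config(n_subjects = 1, sessions = "baseline",
                       conditions = "rest", events_per_recording = 200000,
                       subject_effect_sd = 0.3, session_noise_sd = 0,
                       dark_fraction = 0, seed = 77)
  sim <- simulate_cohort(cfg, model)
  lograte <- log(model$regions$volume_mm3) + sim$latent$subject_effects[1, ]
  p <- exp(lograte - max(lograte)); p <- p / sum(p)
  obs <- table(factor(sim$events$region_id,
                      levels = model$regions$region_id))
  expected <- cfg$events_per_recording * p
  expect_true(all(abs(obs - expected) < 5 * sqrt(expected * (1 - p)) + 5))
})

test_that("cohort config round-trips through JSON", {
  cfg <- cohort_config(n_subjects = 7, events_per_recording = 123,
                       symptom_specs = list(list(name = "x", regions = c(2L, 4L),
                                                 delta = -0.3,
                                                 prevalence = 0.4,
                                                 cutoff = 63)),
                       seed = 2)
  tf <- tempfile(fileext = ".json")
  write_cohort_config(cfg, tf)
  back <- read_cohort_config(tf)
  expect_equal(back$n_subjects, 7)
  expect_equal(back$symptom_specs[[1]]$regions, c(2L, 4L))
  expect_equal(back$symptom_specs[[1]]$delta, -0.3)
  expect_equal(back$seed, 2)
})
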