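# Synthetic cohort generator: emulates solver output — per-region
# multinomial current counts with subject-stable activation, session noise,
# symptom-linked regional shifts, and contaminant ("dark") currents whose
# geometric features differ from brain currents.

#' Cohort simulation configuration
#'
#' Returns the configuration list consumed by [simulate_cohort()]. The
#' generative model: per recording, region counts are multinomial with
#' probabilities proportional to `volume * exp(subject effect +
#' symptom effect + session noise)` (all effects on the log scale); a
#' `dark_fraction` share of each brain recording is replaced by contaminant
#' events drawn from a separate dark-count rate profile shared, per subject,
#' between same-day recordings — which is what makes empty-room densities
#' correlate with resting densities across subjects and gives the Eq.-style
#' correlation correction something to estimate.
#'
#' @param n_subjects number of subjects.
#' @param sessions character subset of `c("baseline", "followup")`.
#' @param conditions character subset of `c("rest", "task", "empty")`,
#'   recorded in every session.
#' @param events_per_recording solver-yield stand-in per brain recording.
#' @param subject_effect_sd between-subject SD of log regional activation
#'   (stable across sessions; the signal that test-retest reliability sees).
#' @param session_noise_sd per-recording SD of log regional activation.
#' @param dark_fraction proportion of contaminant events mixed into brain
#'   recordings, in `[0, 1)`.
#' @param dark_profile_sd SD of the cohort-level dark-count log-rate profile.
#' @param dark_subject_sd SD of the per-subject, per-day dark log-rate
#'   wobble (shared by same-day recordings, redrawn at follow-up).
#' @param direction_noise_sd angular SD (radians) of brain-current
#'   directions about the tangent-plane projection of the local interface
#'   normal; contaminant directions are isotropic in the tangent plane.
#' @param task_rotation_deg rotation (degrees) of the preferred direction
#'   during task recordings — the state difference that feature f1 carries.
#' @param empty_yield events per empty-room recording as a fraction of
#'   `events_per_recording` (default 1: with nothing to outcompete them,
#'   falsely validated currents fill the empty-room yield).
#' @param symptom_specs list of symptom specifications, each a list with
#'   `name`, `regions` (affected region_ids), `delta` (signed log-activation
#'   shift in positives), `prevalence` in (0, 1), and `cutoff` (severity
#'   score at and above which the label is positive).
#' @param score_cutoffs named numeric vector of survey cut-offs; defaults to
#'   `c(ISI = 15, BSI = 63)`.
#' @param recording_ms nominal recording length, ms (event timestamps only).
#' @param seed master seed; all per-subject/per-recording streams are
#'   derived from it via [derive_seed()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24,
                          sessions = c("baseline", "followup"),
                          conditions = c("rest", "task", "empty"),
                          events_per_recording = 20000,
                          subject_effect_sd = 0.30,
                          session_noise_sd = 0.15,
                          dark_fraction = 0.20,
                          dark_profile_sd = 0.5,
                          dark_subject_sd = 0.3,
                          direction_noise_sd = 0.6,
                          task_rotation_deg = 60,
                          empty_yield = NULL,
                          symptom_specs = list(),
                          score_cutoffs = c(ISI = 15, BSI = 63),
                          recording_ms = 560000,
                          seed = 1) {
  stopifnot(n_subjects >= 1, events_per_recording > 0,
            dark_fraction >= 0, dark_fraction < 1,
            all(sessions %in% c("baseline", "followup")),
            all(conditions %in% c("rest", "task", "empty")))
  for (spec in symptom_specs) {
    stopifnot(!is.null(spec$name), !is.null(spec$regions),
              is.numeric(spec$delta),
              spec$prevalence > 0, spec$prevalence < 1,
              is.numeric(spec$cutoff))
  }
  structure(list(
    n_subjects = n_subjects, sessions = sessions, conditions = conditions,
    events_per_recording = events_per_recording,
    subject_effect_sd = subject_effect_sd,
    session_noise_sd = session_noise_sd,
    dark_fraction = dark_fraction, dark_profile_sd = dark_profile_sd,
    dark_subject_sd = dark_subject_sd,
    direction_noise_sd = direction_noise_sd,
    task_rotation_deg = task_rotation_deg,
    empty_yield = empty_yield %||% 1,
    symptom_specs = symptom_specs, score_cutoffs = score_cutoffs,
    recording_ms = recording_ms, seed = seed), class = "cohort_config")
}

#' Binary symptom labels from severity scores
#'
#' A score at or above the cut-off is labelled positive (the boundary is
#' inclusive; configurable by shifting the cut-off).
#'
#' @param severities numeric vector of finite severity scores.
#' @param cutoff numeric cut-off (e.g. 15 for the ISI, 63 for the BSI).
#' @return Logical vector: `TRUE` = clinically positive.
#' @export
assign_labels <- function(severities, cutoff) {
  stopifnot(all(is.finite(severities)), is.finite(cutoff))
  severities >= cutoff
}

softmax <- function(loga) {
  w <- exp(loga - max(loga))
  w / sum(w)
}

#' Simulate a synthetic cohort of current events
#'
#' Generates per-recording event tables from the multinomial rate model
#' described in [cohort_config()]. Brain events are placed inside their
#' region's sector outside the central exclusion sphere, with tangent-plane
#' directions concentrated near the local gray/white-interface normal;
#' contaminant events carry geometrically atypical locations (broad radial
#' spread) and isotropic tangent directions, and are flagged in the
#' ground-truth column `is_dark` (excluded from analysis inputs). Identical
#' seeds produce identical tables.
#'
#' @param config a [cohort_config()].
#' @param model a [build_toy_brain()] model (must carry toy sampling
#'   geometry).
#' @return A list with `events` (data.frame: `subject_id, session,
#'   condition, time_ms, x_mm, y_mm, z_mm, dx, dy, dz, region_id, is_dark`),
#'   `subjects` (severities, labels, cohort tag), and `latent` (the
#'   subject-effect matrix and dark profile, for oracle checks).
#' @export
simulate_cohort <- function(config, model) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "brain_model"))
  geom <- attr(model, "toy_geometry")
  if (is.null(geom))
    stop("model carries no sampling geometry; build it with build_toy_brain()")
  regions <- model$regions
  nR <- nrow(regions)
  for (spec in config$symptom_specs)
    if (!all(spec$regions %in% regions$region_id))
      stop("symptom spec '", spec$name, "' names regions absent from the parcellation")

  master <- config$seed
  dark_shift <- with_seed(derive_seed(master, "dark_profile"),
                          stats::rnorm(nR, 0, config$dark_profile_sd))

  subj_ids <- sprintf("S%03d", seq_len(config$n_subjects))
  subj_eff <- matrix(0, config$n_subjects, nR,
                     dimnames = list(subj_ids, regions$region_id))
  subjects <- data.frame(subject_id = subj_ids, stringsAsFactors = FALSE)
  symptom_effect <- matrix(0, config$n_subjects, nR)
  for (i in seq_len(config$n_subjects)) {
    subj_eff[i, ] <- with_seed(derive_seed(master, paste0(subj_ids[i], "/effect")),
                               stats::rnorm(nR, 0, config$subject_effect_sd))
  }
  for (spec in config$symptom_specs) {
    sev <- numeric(config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      sev[i] <- with_seed(
        derive_seed(master, paste0(subj_ids[i], "/symptom/", spec$name)), {
          pos <- stats::runif(1) < spec$prevalence
          if (pos) stats::runif(1, spec$cutoff, 2 * spec$cutoff)
          else stats::runif(1, 0, spec$cutoff * (1 - 1e-9))
        })
    }
    lab <- assign_labels(sev, spec$cutoff)
    subjects[[paste0("severity_", spec$name)]] <- sev
    subjects[[paste0("label_", spec$name)]] <- lab
    cols <- match(spec$regions, regions$region_id)
    symptom_effect[lab, cols] <- symptom_effect[lab, cols] + spec$delta
  }
  any_pos <- if (length(config$symptom_specs))
    Reduce(`|`, lapply(config$symptom_specs,
                       function(s) subjects[[paste0("label_", s$name)]]))
  else rep(FALSE, config$n_subjects)
  subjects$cohort <- ifelse(any_pos, "symptomatic", "control")

  base_log_vol <- log(regions$volume_mm3)
  chunks <- list()
  for (i in seq_len(config$n_subjects)) {
    for (ses in config$sessions) {
      dark_wobble <- with_seed(
        derive_seed(master, paste(subj_ids[i], ses, "darkwobble", sep = "/")),
        stats::rnorm(nR, 0, config$dark_subject_sd))
      dark_prob <- softmax(base_log_vol + dark_shift + dark_wobble)
      for (cond in config$conditions) {
        key <- paste(subj_ids[i], ses, cond, sep = "/")
        chunks[[key]] <- with_seed(derive_seed(master, key), {
          if (cond == "empty") {
            n_dark <- round(config$events_per_recording * config$empty_yield)
            simulate_recording(model, geom, config, subj_ids[i], ses, cond,
                               n_brain = 0, brain_prob = NULL,
                               n_dark = n_dark, dark_prob = dark_prob)
          } else {
            n_dark <- round(config$events_per_recording * config$dark_fraction)
            n_brain <- config$events_per_recording - n_dark
            noise <- stats::rnorm(nR, 0, config$session_noise_sd)
            brain_prob <- softmax(base_log_vol + subj_eff[i, ] +
                                    symptom_effect[i, ] + noise)
            simulate_recording(model, geom, config, subj_ids[i], ses, cond,
                               n_brain = n_brain, brain_prob = brain_prob,
                               n_dark = n_dark, dark_prob = dark_prob)
          }
        })
      }
    }
  }
  events <- do.call(rbind, c(chunks, list(make.row.names = FALSE)))
  rownames(events) <- NULL
  list(events = events, subjects = subjects,
       latent = list(subject_effects = subj_eff, dark_shift = dark_shift,
                     symptom_effects = symptom_effect))
}

# one recording: counts -> locations -> directions (runs inside a set stream)
simulate_recording <- function(model, geom, config, subject_id, session,
                               condition, n_brain, brain_prob, n_dark,
                               dark_prob) {
  regions <- model$regions
  nR <- nrow(regions)
  counts_brain <- if (n_brain > 0)
    as.integer(stats::rmultinom(1, n_brain, brain_prob)) else integer(nR)
  counts_dark <- if (n_dark > 0)
    as.integer(stats::rmultinom(1, n_dark, dark_prob)) else integer(nR)
  reg_idx <- c(rep(seq_len(nR), counts_brain), rep(seq_len(nR), counts_dark))
  is_dark <- c(rep(FALSE, sum(counts_brain)), rep(TRUE, sum(counts_dark)))
  n <- length(reg_idx)
  if (n == 0) {
    return(data.frame(subject_id = character(), session = character(),
                      condition = character(), time_ms = numeric(),
                      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      region_id = integer(), is_dark = logical()))
  }

  # sector angular bounds per event
  tissue <- regions$tissue[reg_idx]
  sector_of <- integer(n)
  ctxwm <- tissue != "subcortical"
  sector_of[ctxwm] <- ifelse(tissue[ctxwm] == "cortex", reg_idx[ctxwm],
                             reg_idx[ctxwm] - geom$n_pairs)
  az <- numeric(n)
  az[ctxwm] <- stats::runif(sum(ctxwm),
                            geom$az_breaks[sector_of[ctxwm]],
                            geom$az_breaks[sector_of[ctxwm] + 1])
  if (any(!ctxwm)) {
    sb <- subcort_breaks(geom)
    k <- reg_idx[!ctxwm] - 2 * geom$n_pairs
    az[!ctxwm] <- stats::runif(sum(!ctxwm), sb[k], sb[k + 1])
  }
  ct <- stats::runif(n, -1, 1)
  st <- sqrt(1 - ct^2)
  u <- cbind(st * cos(az), st * sin(az), ct)

  # radial placement: brain events inside their region's radial band; dark
  # events spread over the whole sampled depth range (broad f3 signature)
  rg <- geom$r_gw(u)
  lo <- numeric(n); hi <- numeric(n)
  lo[tissue == "cortex"] <- rg[tissue == "cortex"]
  hi[tissue == "cortex"] <- geom$r_pial(u[tissue == "cortex", , drop = FALSE])
  lo[tissue == "white_rim"] <- rg[tissue == "white_rim"] - geom$rim_mm
  hi[tissue == "white_rim"] <- rg[tissue == "white_rim"]
  lo[tissue == "subcortical"] <- geom$subcort_band[1]
  hi[tissue == "subcortical"] <- geom$subcort_band[2]
  lo[is_dark] <- geom$subcort_band[1]
  hi[is_dark] <- geom$r_pial(u[is_dark, , drop = FALSE])
  r <- stats::runif(n, lo, hi)
  loc <- u * r

  # tangent-plane basis at each location (tangent to the head sphere)
  ref <- cbind(rep(1, n), 0, 0)
  swap <- abs(u[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  e1 <- cbind(u[, 2] * ref[, 3] - u[, 3] * ref[, 2],
              u[, 3] * ref[, 1] - u[, 1] * ref[, 3],
              u[, 1] * ref[, 2] - u[, 2] * ref[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])

  # brain currents: direction concentrated near the tangent-plane projection
  # of the local interface normal; dark currents: isotropic in the plane
  nip <- nearest_interface_point(loc, model)
  a0 <- atan2(rowSums(nip$normal * e2), rowSums(nip$normal * e1))
  ang <- a0 + stats::rnorm(n, 0, config$direction_noise_sd)
  if (condition == "task")
    ang <- ang + config$task_rotation_deg * pi / 180
  ang[is_dark] <- stats::runif(sum(is_dark), -pi, pi)
  dir <- e1 * cos(ang) + e2 * sin(ang)

  data.frame(subject_id = subject_id, session = session, condition = condition,
             time_ms = round(stats::runif(n, 0, config$recording_ms)),
             x_mm = loc[, 1], y_mm = loc[, 2], z_mm = loc[, 3],
             dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
             region_id = regions$region_id[reg_idx], is_dark = is_dark,
             stringsAsFactors = FALSE)
}

#' Write / read a cohort configuration as JSON
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @return `read_cohort_config()` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$symptom_specs <- lapply(
    if (is.data.frame(raw$symptom_specs))
      split(raw$symptom_specs, seq_len(nrow(raw$symptom_specs)))
    else raw$symptom_specs,
    function(s) { s <- as.list(s); s$regions <- unlist(s$regions); s })
  do.call(cohort_config, raw[setdiff(names(raw), character())])
}
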