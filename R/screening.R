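# Empty-room dark-count correction: per-region, per-subject random-forest
# inclusion/exclusion of individual currents, plus the legacy correlation
# correction applied at the density level.

#' Training-set specification for the per-region screen
#'
#' Each class is subsampled without replacement to at most `cap_per_class`
#' currents; when the smaller class has fewer than the cap, the larger class
#' is further limited to `floor(balance_ratio * smaller)` — approximately
#' equal class sizes remove a key failure mode of random-forest
#' classification. A region/subject screen whose classes fall below
#' `min_class_size` is marked unsuccessful rather than trained.
#'
#' @param cap_per_class maximum training currents per class (default 5000).
#' @param balance_ratio larger/smaller class size limit (default 1.10).
#' @param min_class_size smallest usable class (default 200).
#' @param min_accuracy per-class full-population accuracy (percent) below
#'   which the screen is declared unsuccessful (default 55).
#' @return A list of class `training_spec`.
#' @export
training_spec <- function(cap_per_class = 5000, balance_ratio = 1.10,
                          min_class_size = 200, min_accuracy = 55) {
  stopifnot(cap_per_class > 0, balance_ratio >= 1, min_class_size >= 1)
  structure(list(cap_per_class = cap_per_class, balance_ratio = balance_ratio,
                 min_class_size = min_class_size, min_accuracy = min_accuracy),
            class = "training_spec")
}

#' Build balanced training subsets for the two current populations
#'
#' @param n_a,n_b class population sizes, or data.frames/matrices whose rows
#'   are the populations (row indices are then sampled).
#' @param spec a [training_spec()].
#' @param seed integer seed for the subsampling stream.
#' @return A list with `idx_a`, `idx_b`: sorted row indices of the sampled
#'   training subsets.
#' @export
build_training_sets <- function(n_a, n_b, spec = training_spec(), seed = 1) {
  size_a <- if (length(n_a) == 1 && is.numeric(n_a)) n_a else nrow(n_a)
  size_b <- if (length(n_b) == 1 && is.numeric(n_b)) n_b else nrow(n_b)
  stopifnot(size_a > 0, size_b > 0)
  take_a <- min(size_a, spec$cap_per_class)
  take_b <- min(size_b, spec$cap_per_class)
  smaller <- min(size_a, size_b)
  if (smaller < spec$cap_per_class) {
    lim <- floor(spec$balance_ratio * smaller)
    take_a <- min(take_a, lim)
    take_b <- min(take_b, lim)
  }
  with_seed(seed, {
    idx_a <- sort(sample.int(size_a, take_a))
    idx_b <- sort(sample.int(size_b, take_b))
    list(idx_a = idx_a, idx_b = idx_b)
  })
}

#' Train a per-region random-forest screen
#'
#' Fits a random forest on the four geometric features (100 trees, majority
#' vote) to the training subsets, then evaluates per-class percentage
#' accuracy on the *full* populations (training + test, the optimistic
#' protocol) as well as out-of-bag accuracy on the training subsets.
#' Feature contributions are mean-impurity-decrease shares normalized to
#' sum to 1.
#'
#' @param feat_a,feat_b data.frames with columns `f1..f4` for the two full
#'   populations (class A is the brain-condition class retained downstream).
#' @param spec a [training_spec()].
#' @param seed integer seed (subsampling + forest).
#' @param ntree number of trees.
#' @return A list of class `current_screen`: `forest`, `acc_a`, `acc_b`
#'   (percent, full populations), `oob_acc_a`, `oob_acc_b`, `contrib`
#'   (named length-4 shares), `success`, `n_a`, `n_b`.
#' @export
train_screen <- function(feat_a, feat_b, spec = training_spec(), seed = 1,
                         ntree = 100) {
  feat_a <- as.data.frame(feat_a)[, c("f1", "f2", "f3", "f4")]
  feat_b <- as.data.frame(feat_b)[, c("f1", "f2", "f3", "f4")]
  res <- list(forest = NULL, acc_a = NA_real_, acc_b = NA_real_,
              oob_acc_a = NA_real_, oob_acc_b = NA_real_,
              contrib = stats::setNames(rep(NA_real_, 4), paste0("f", 1:4)),
              success = FALSE, n_a = nrow(feat_a), n_b = nrow(feat_b))
  class(res) <- "current_screen"
  if (nrow(feat_a) < spec$min_class_size || nrow(feat_b) < spec$min_class_size)
    return(res)
  if (all(apply(rbind(feat_a, feat_b), 2, function(x) length(unique(x)) == 1)))
    return(res)  # degenerate: zero variance in every feature
  tr <- build_training_sets(nrow(feat_a), nrow(feat_b), spec, seed = seed)
  x <- rbind(feat_a[tr$idx_a, ], feat_b[tr$idx_b, ])
  y <- factor(rep(c("A", "B"), c(length(tr$idx_a), length(tr$idx_b))),
              levels = c("A", "B"))
  forest <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = ntree, importance = FALSE))
  imp <- randomForest::importance(forest, type = 2)[, 1]
  res$forest <- forest
  res$train_idx_a <- tr$idx_a
  res$train_idx_b <- tr$idx_b
  res$contrib <- imp / sum(imp)
  pa <- stats::predict(forest, feat_a)
  pb <- stats::predict(forest, feat_b)
  res$acc_a <- 100 * mean(pa == "A")
  res$acc_b <- 100 * mean(pb == "B")
  oob <- forest$confusion
  res$oob_acc_a <- 100 * oob["A", "A"] / sum(oob["A", c("A", "B")])
  res$oob_acc_b <- 100 * oob["B", "B"] / sum(oob["B", c("A", "B")])
  res$success <- res$acc_a >= spec$min_accuracy && res$acc_b >= spec$min_accuracy
  res
}

#' Apply a trained screen to a population of currents
#'
#' An event is dropped when the forest's empty-class (class B) vote share
#' exceeds 0.5; ties retain the event. Events that were part of the class-A
#' training subset are judged by their out-of-bag votes (identified via
#' `train_rows_a`), so a memorized training point cannot vote itself
#' brain-like. With no trained classifier the events pass through unchanged
#' with a warning flag.
#'
#' @param features data.frame with columns `f1..f4`, one row per event.
#' @param screen a `current_screen` from [train_screen()].
#' @param train_rows_a optional: for each row of `features`, its row index
#'   in the class-A population the screen was trained on (NA if the event
#'   is not from that population).
#' @return A list with `keep` (logical per event), `n_kept`, `n_dropped`,
#'   `passthrough` (TRUE when no classifier was available).
#' @export
apply_screen <- function(features, screen, train_rows_a = NULL) {
  n <- nrow(features)
  if (is.null(screen$forest) || !isTRUE(screen$success)) {
    return(list(keep = rep(TRUE, n), n_kept = n, n_dropped = 0L,
                passthrough = TRUE))
  }
  votes <- stats::predict(screen$forest,
                          as.data.frame(features)[, c("f1", "f2", "f3", "f4")],
                          type = "vote")
  vote_b <- votes[, "B"]
  if (!is.null(train_rows_a)) {
    in_train <- match(train_rows_a, screen$train_idx_a)
    oob_b <- screen$forest$votes[seq_along(screen$train_idx_a), "B"]
    use <- !is.na(in_train) & !is.na(oob_b[pmax(in_train, 1)])
    vote_b[use] <- oob_b[in_train[use]]
  }
  keep <- vote_b <= 0.5
  list(keep = keep, n_kept = sum(keep), n_dropped = sum(!keep),
       passthrough = FALSE)
}

#' Screen a cohort's events per subject and region
#'
#' For every subject and every cortical / white-rim region, trains a
#' random-forest classifier contrasting the subject's `rest` currents in
#' that region against the contrast condition (`empty` for the dark-count
#' screen, `task` for the state-vs-state comparison), then — for the
#' `rest_vs_empty` contrast — removes rest (and task) currents the model
#' deems empty-room-like. Regions whose screen is unsuccessful pass their
#' events through unfiltered and are flagged, so downstream stages can
#' restrict to screen-successful region/subject pairs.
#'
#' @param events events data.frame (see [read_events()]).
#' @param model a [brain_model()].
#' @param contrast `"rest_vs_empty"` or `"rest_vs_task"`.
#' @param spec a [training_spec()].
#' @param seed master seed; per-subject/region forests use derived streams.
#' @param features optional precomputed [compute_features()] rows aligned
#'   with `events` (computed when missing).
#' @param apply_to conditions whose events are filtered (default
#'   `c("rest", "task")` for the empty contrast; the contrast condition
#'   itself is never filtered).
#' @return A list with `report` (one row per subject x region: sizes,
#'   accuracies, contributions, success), `keep` (logical per input event)
#'   and `filtered_events`.
#' @export
screen_cohort <- function(events, model, contrast = c("rest_vs_empty",
                                                      "rest_vs_task"),
                          spec = training_spec(), seed = 1, features = NULL,
                          apply_to = c("rest", "task")) {
  contrast <- match.arg(contrast)
  cond_b <- if (contrast == "rest_vs_empty") "empty" else "task"
  if (is.null(features)) features <- compute_features(events, model)
  stopifnot(nrow(features) == nrow(events))
  screened_regions <- model$regions$region_id[
    model$regions$tissue %in% c("cortex", "white_rim")]
  keep <- rep(TRUE, nrow(events))
  rows <- list()
  for (sid in unique(events$subject_id)) {
    for (rid in screened_regions) {
      in_reg <- events$subject_id == sid & events$region_id == rid
      ia <- which(in_reg & events$condition == "rest")
      ib <- which(in_reg & events$condition == cond_b)
      scr <- train_screen(features[ia, , drop = FALSE],
                          features[ib, , drop = FALSE], spec,
                          seed = derive_seed(seed, paste(sid, rid, contrast,
                                                         sep = "/")))
      if (contrast == "rest_vs_empty" && scr$success) {
        it <- which(in_reg & events$condition %in% apply_to)
        rows_a <- match(it, ia)  # rest rows are the class-A population
        dec <- apply_screen(features[it, , drop = FALSE], scr,
                            train_rows_a = rows_a)
        keep[it] <- dec$keep
      }
      rows[[paste(sid, rid)]] <- data.frame(
        subject_id = sid, region_id = rid, contrast = contrast,
        n_a = scr$n_a, n_b = scr$n_b, acc_a = scr$acc_a, acc_b = scr$acc_b,
        oob_acc_a = scr$oob_acc_a, oob_acc_b = scr$oob_acc_b,
        contrib_f1 = scr$contrib[["f1"]], contrib_f2 = scr$contrib[["f2"]],
        contrib_f3 = scr$contrib[["f3"]], contrib_f4 = scr$contrib[["f4"]],
        success = scr$success, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(report = report, keep = keep,
       filtered_events = events[keep, , drop = FALSE])
}

#' Legacy correlation-based empty-room correction
#'
#' `eq3_correlations()` estimates, for each region, the Pearson correlation
#' across subjects between the density measured with the subject present
#' and the same-day empty-room density. `eq3_correct()` then applies
#' `rho_corrected = rho - corr * rho_empty` element-wise; regions with a
#' missing empty-room density yield `NA`.
#'
#' @param rho,rho_empty numeric vectors of aligned regional densities, or
#'   (for `eq3_correlations`) density tables from [compute_density()] for
#'   the subject-present and empty-room recordings.
#' @param corr numeric vector of per-region correlations aligned with `rho`.
#' @return `eq3_correlations()` returns a data.frame `region_id, corr`;
#'   `eq3_correct()` returns the corrected density vector.
#' @export
eq3_correct <- function(rho, rho_empty, corr) {
  stopifnot(length(rho) == length(rho_empty), length(rho) == length(corr))
  out <- rho - corr * rho_empty
  out[is.na(rho_empty)] <- NA_real_
  out
}

#' @rdname eq3_correct
#' @export
eq3_correlations <- function(rho, rho_empty) {
  stopifnot(all(c("subject_id", "region_id", "rho") %in% names(rho)),
            all(c("subject_id", "region_id", "rho") %in% names(rho_empty)))
  m <- merge(rho[, c("subject_id", "region_id", "rho")],
             rho_empty[, c("subject_id", "region_id", "rho")],
             by = c("subject_id", "region_id"), suffixes = c("", "_empty"))
  out <- do.call(rbind, lapply(split(m, m$region_id), function(d) {
    r <- if (nrow(d) >= 3 && stats::sd(d$rho) > 0 && stats::sd(d$rho_empty) > 0)
      stats::cor(d$rho, d$rho_empty) else NA_real_
    data.frame(region_id = d$region_id[1], corr = r)
  }))
  rownames(out) <- NULL
  out[order(out$region_id), ]
}
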