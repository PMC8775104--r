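# Cortex vs adjacent white matter differential activity: per-pair
# chi-square against volume-based expected counts.

#' Chi-square test of a cortex / white-rim pair
#'
#' Expected counts split the pair's observed total in proportion to the two
#' region volumes: `expected_ctx = (n_ctx + n_wm) * vol_ctx / (vol_ctx +
#' vol_wm)`. The goodness-of-fit chi-square has 1 df (no continuity
#' correction; counts are large). The verdict compares the observed with
#' the expected direction when `p < threshold`; pairs with a zero total
#' count — or flagged unevaluated, e.g. when the dark-count screen failed —
#' are `not_evaluated`. All arguments are vectorized over pairs.
#'
#' @param n_ctx,n_wm observed counts.
#' @param vol_ctx,vol_wm region volumes (> 0).
#' @param threshold significance threshold (default `1e-8`, guarding the
#'   large number of pair comparisons).
#' @param evaluated logical; FALSE forces `not_evaluated`.
#' @return data.frame `n_ctx, n_wm, expected_ctx, expected_wm, chi2, p,
#'   verdict` with verdict in `cortex_greater, wm_greater, not_significant,
#'   not_evaluated`.
#' @export
pair_chisq <- function(n_ctx, n_wm, vol_ctx, vol_wm, threshold = 1e-8,
                       evaluated = TRUE) {
  stopifnot(all(vol_ctx > 0), all(vol_wm > 0), all(n_ctx >= 0),
            all(n_wm >= 0))
  k <- max(length(n_ctx), length(n_wm))
  n_ctx <- rep_len(n_ctx, k); n_wm <- rep_len(n_wm, k)
  vol_ctx <- rep_len(vol_ctx, k); vol_wm <- rep_len(vol_wm, k)
  evaluated <- rep_len(evaluated, k)
  total <- n_ctx + n_wm
  e_ctx <- total * vol_ctx / (vol_ctx + vol_wm)
  e_wm <- total - e_ctx
  chi2 <- ifelse(total > 0,
                 (n_ctx - e_ctx)^2 / e_ctx + (n_wm - e_wm)^2 / e_wm,
                 NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  verdict <- rep("not_significant", k)
  verdict[!is.na(p) & p < threshold & n_ctx > e_ctx] <- "cortex_greater"
  verdict[!is.na(p) & p < threshold & n_wm > e_wm] <- "wm_greater"
  verdict[total == 0 | !evaluated] <- "not_evaluated"
  chi2[!evaluated] <- NA_real_
  p[!evaluated] <- NA_real_
  data.frame(n_ctx = n_ctx, n_wm = n_wm, expected_ctx = e_ctx,
             expected_wm = e_wm, chi2 = chi2, p = p, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Differential activity over all subjects and cortex/white-rim pairs
#'
#' Builds the per-subject observed counts for every paired cortical /
#' adjacent white-matter region from a count table and applies
#' [pair_chisq()]. When a screen report is supplied, a pair counts as
#' evaluated only if the dark-count screen succeeded for both members for
#' that subject.
#'
#' @param counts count table from [count_events()] (restrict to the
#'   recordings of interest before calling, e.g. baseline rest).
#' @param regions parcellation data.frame.
#' @param screen_report optional report from [screen_cohort()] with columns
#'   `subject_id, region_id, success`.
#' @param threshold significance threshold.
#' @return data.frame `subject_id, ctx_region, wm_region` plus the
#'   [pair_chisq()] columns.
#' @export
differential_pairs <- function(counts, regions, screen_report = NULL,
                               threshold = 1e-8) {
  ctx <- regions[regions$tissue == "cortex" & !is.na(regions$paired_region_id), ]
  key <- function(s, r) paste(s, r, sep = "\r")
  cnt <- stats::setNames(counts$count, key(counts$subject_id, counts$region_id))
  ok <- if (!is.null(screen_report))
    stats::setNames(screen_report$success,
                    key(screen_report$subject_id, screen_report$region_id))
  subjects <- unique(counts$subject_id)
  grid <- expand.grid(subject_id = subjects, i = seq_len(nrow(ctx)),
                      stringsAsFactors = FALSE)
  ctx_id <- ctx$region_id[grid$i]
  wm_id <- ctx$paired_region_id[grid$i]
  n_ctx <- cnt[key(grid$subject_id, ctx_id)]
  n_wm <- cnt[key(grid$subject_id, wm_id)]
  n_ctx[is.na(n_ctx)] <- 0
  n_wm[is.na(n_wm)] <- 0
  evaluated <- if (is.null(ok)) TRUE else {
    e1 <- ok[key(grid$subject_id, ctx_id)]
    e2 <- ok[key(grid$subject_id, wm_id)]
    !is.na(e1) & e1 & !is.na(e2) & e2
  }
  vol <- stats::setNames(regions$volume_mm3, regions$region_id)
  res <- pair_chisq(n_ctx, n_wm, vol[as.character(ctx_id)],
                    vol[as.character(wm_id)], threshold = threshold,
                    evaluated = evaluated)
  cbind(data.frame(subject_id = grid$subject_id, ctx_region = ctx_id,
                   wm_region = wm_id, stringsAsFactors = FALSE), res)
}

#' Tally differential-activity verdicts
#'
#' Counts and percentages of `cortex_greater` / `wm_greater` /
#' `not_significant` verdicts over all subject-pair results; percentages
#' are reported over evaluated pairs (those for which the correction
#' succeeded), matching the convention of reporting rates over
#' screen-successful pairs only.
#'
#' @param results data.frame with a `verdict` column ([differential_pairs()]
#'   output, or any table of verdicts).
#' @return A list with `n_total`, `n_evaluated`, `n_cortex_greater`,
#'   `n_wm_greater`, `n_not_significant`, `pct_cortex_greater`,
#'   `pct_wm_greater`, `pct_not_significant`.
#' @export
tally_pairs <- function(results) {
  v <- results$verdict
  n_eval <- sum(v != "not_evaluated")
  n_cg <- sum(v == "cortex_greater")
  n_wg <- sum(v == "wm_greater")
  n_ns <- sum(v == "not_significant")
  pct <- function(x) if (n_eval > 0) 100 * x / n_eval else 0
  list(n_total = length(v), n_evaluated = n_eval, n_cortex_greater = n_cg,
       n_wm_greater = n_wg, n_not_significant = n_ns,
       pct_cortex_greater = pct(n_cg), pct_wm_greater = pct(n_wg),
       pct_not_significant = pct(n_ns))
}
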