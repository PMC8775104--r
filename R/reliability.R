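# Test-retest reliability: per-region Pearson correlation and mean signed
# difference between two measurement occasions, plus the Welch comparison
# between correction methods.

#' Per-region test-retest reliability between two occasions
#'
#' Subjects are inner-joined on `subject_id`; subjects missing either
#' occasion are excluded. For each region with at least `min_n` paired
#' subjects, reports the Pearson correlation across subjects and the mean
#' signed difference (occasion 2 minus occasion 1; subtracting `mean_diff`
#' from a follow-up measure corrects it for comparison with baseline).
#' Regions with fewer pairs are omitted with a warning.
#'
#' @param z1,z2 long tables with columns `subject_id, region_id` and the
#'   value column (occasion 1 and occasion 2).
#' @param value value column name (default `"z"`).
#' @param min_n minimum paired subjects for a region to be emitted
#'   (default 3).
#' @return data.frame `region_id, n, pearson_r, mean_diff`.
#' @export
test_retest <- function(z1, z2, value = "z", min_n = 3) {
  m <- merge(z1[, c("subject_id", "region_id", value)],
             z2[, c("subject_id", "region_id", value)],
             by = c("subject_id", "region_id"), suffixes = c("_1", "_2"))
  v1 <- paste0(value, "_1"); v2 <- paste0(value, "_2")
  m <- m[stats::complete.cases(m[, c(v1, v2)]), ]
  parts <- split(m, m$region_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    if (nrow(d) < min_n) return(NULL)
    r <- if (stats::sd(d[[v1]]) > 0 && stats::sd(d[[v2]]) > 0)
      stats::cor(d[[v1]], d[[v2]]) else NA_real_
    data.frame(region_id = d$region_id[1], n = nrow(d), pearson_r = r,
               mean_diff = mean(d[[v2]] - d[[v1]]))
  }))
  dropped <- sum(vapply(parts, nrow, 0L) < min_n)
  if (dropped > 0)
    warning(dropped, " regions omitted (fewer than ", min_n,
            " paired subjects)")
  if (is.null(out))
    return(data.frame(region_id = integer(), n = integer(),
                      pearson_r = numeric(), mean_diff = numeric()))
  rownames(out) <- NULL
  out[order(out$region_id), ]
}

#' Welch comparison of two sets of per-region reliabilities
#'
#' Two-sample Welch t-test (unequal variances, Welch--Satterthwaite df) on
#' two vectors of per-region test-retest correlations, e.g. random-forest
#' screened vs the legacy correlation correction.
#'
#' @param r_a,r_b numeric vectors of per-region correlations (lengths may
#'   differ); at least 2 finite values each.
#' @param alternative test sidedness, as in [stats::t.test()].
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_methods <- function(r_a, r_b, alternative = "two.sided") {
  r_a <- r_a[is.finite(r_a)]
  r_b <- r_b[is.finite(r_b)]
  if (length(r_a) < 2 || length(r_b) < 2)
    stop("need at least 2 finite correlations per method")
  ht <- stats::t.test(r_a, r_b, var.equal = FALSE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(r_a), mean_b = mean(r_b))
}
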