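# Volume-normalized regional current densities, the normative atlas, and
# z-scoring against it.

#' Tabulate per-recording regional current counts
#'
#' Counts events per (subject, session, condition, region) on the complete
#' grid of parcellation regions (zeros included) and attaches the
#' per-recording total count, region volumes, and the total parcellation
#' volume.
#'
#' @param events events data.frame.
#' @param regions parcellation data.frame (see [read_parcellation()]).
#' @param vol_total total reference volume, mm^3; defaults to the sum of all
#'   parcellation region volumes.
#' @return data.frame with columns `subject_id, session, condition,
#'   region_id, count, count_total, volume_mm3, vol_total`.
#' @export
count_events <- function(events, regions, vol_total = NULL) {
  validate_parcellation(regions)
  vol_total <- vol_total %||% sum(regions$volume_mm3)
  rec <- unique(events[, c("subject_id", "session", "condition")])
  grid <- merge(rec, data.frame(region_id = regions$region_id), by = NULL)
  tab <- stats::aggregate(list(count = rep(1L, nrow(events))),
                          events[, c("subject_id", "session", "condition",
                                     "region_id")], sum)
  out <- merge(grid, tab, all.x = TRUE,
               by = c("subject_id", "session", "condition", "region_id"))
  out$count[is.na(out$count)] <- 0L
  tot <- stats::aggregate(list(count_total = out$count),
                          out[, c("subject_id", "session", "condition")], sum)
  out <- merge(out, tot, by = c("subject_id", "session", "condition"))
  out$volume_mm3 <- regions$volume_mm3[match(out$region_id, regions$region_id)]
  out$vol_total <- vol_total
  out[order(out$subject_id, out$session, out$condition, out$region_id), ]
}

#' Regional current density
#'
#' `rho = (count_region / count_total) / (vol_region / vol_total)`: the
#' region's share of validated currents divided by its share of brain
#' volume. Under spatially uniform currents `rho = 1` for every region; the
#' count-total denominator makes `rho` invariant to data quality and record
#' length (any constant rescaling of all counts). Recordings with a zero
#' total count are flagged invalid and emit no densities.
#'
#' @param counts count table from [count_events()] (or any data.frame with
#'   columns `count, count_total, volume_mm3, vol_total`).
#' @return The input with a `rho` column appended; zero-total recordings
#'   are dropped with a warning.
#' @export
compute_density <- function(counts) {
  need <- c("count", "count_total", "volume_mm3", "vol_total")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$volume_mm3 <= 0)) stop("region volumes must be > 0")
  bad <- counts$count_total == 0
  if (any(bad)) {
    warning(sum(bad), " rows from zero-count recordings flagged invalid")
    counts <- counts[!bad, , drop = FALSE]
  }
  counts$rho <- (counts$count / counts$count_total) /
    (counts$volume_mm3 / counts$vol_total)
  counts
}

#' Build a normative density atlas
#'
#' Per-region sample mean and standard deviation (n - 1 denominator) of the
#' normative cohort's densities, by convention from baseline resting
#' recordings only. Regions with zero spread are flagged degenerate.
#'
#' @param density density table from [compute_density()].
#' @param session,condition which recordings constitute the norm.
#' @return data.frame `region_id, mean_rho, sd_rho, n, degenerate`.
#' @export
build_atlas <- function(density, session = "baseline", condition = "rest") {
  d <- density[density$session == session & density$condition == condition, ]
  if (length(unique(d$subject_id)) < 2)
    stop("a normative atlas needs at least 2 subjects")
  out <- do.call(rbind, lapply(split(d, d$region_id), function(g) {
    data.frame(region_id = g$region_id[1], mean_rho = mean(g$rho),
               sd_rho = stats::sd(g$rho), n = nrow(g))
  }))
  rownames(out) <- NULL
  out$degenerate <- out$sd_rho == 0
  out[order(out$region_id), ]
}

#' Transform densities to z-scores against an atlas
#'
#' `z = (rho - mean_rho) / sd_rho`. Scoring a cohort against its own atlas
#' nominally equalizes the variances across regions (per-region sample
#' variance is exactly 1 with the n - 1 convention), so composite measures
#' weight each region approximately equally. Regions whose atlas SD is zero
#' are emitted as `NA` with a warning.
#'
#' @param density density table from [compute_density()].
#' @param atlas atlas from [build_atlas()]; must cover all regions present.
#' @return data.frame `subject_id, session, condition, region_id, z`.
#' @export
to_zscores <- function(density, atlas) {
  miss <- setdiff(unique(density$region_id), atlas$region_id)
  if (length(miss))
    stop("atlas does not cover regions: ", paste(miss, collapse = ", "))
  i <- match(density$region_id, atlas$region_id)
  sd_rho <- atlas$sd_rho[i]
  z <- (density$rho - atlas$mean_rho[i]) / sd_rho
  if (any(sd_rho == 0)) {
    warning("zero-SD atlas regions produce missing z-scores")
    z[sd_rho == 0] <- NA_real_
  }
  data.frame(subject_id = density$subject_id, session = density$session,
             condition = density$condition, region_id = density$region_id,
             z = z, stringsAsFactors = FALSE)
}

#' Read / write an atlas table
#'
#' TSV with header `region_id, name, mean_rho, sd_rho, n`.
#'
#' @param atlas atlas data.frame; @param path file path;
#' @param regions optional parcellation supplying region names.
#' @return `read_atlas()` returns a data.frame.
#' @export
write_atlas <- function(atlas, path, regions = NULL) {
  if (!is.null(regions))
    atlas$name <- regions$name[match(atlas$region_id, regions$region_id)]
  write_tsv_table(atlas, path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) read_tsv_table(path)

#' Pivot a long z-score (or density) table to a subjects-by-regions matrix
#'
#' @param z long table with `subject_id, session, region_id` and a value
#'   column.
#' @param value name of the value column (`"z"` or `"rho"`).
#' @return Numeric matrix; rows named `subject_id/session`, columns are
#'   region ids.
#' @export
zscore_matrix <- function(z, value = "z") {
  row_key <- paste(z$subject_id, z$session, sep = "/")
  rows <- unique(row_key)
  cols <- sort(unique(z$region_id))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, as.character(cols)))
  m[cbind(match(row_key, rows), match(z$region_id, cols))] <- z[[value]]
  m
}
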