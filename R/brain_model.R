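# Brain model: parcellation table, head-approximating sphere, gray/white and
# pial surfaces, and the four per-current geometric features.

#' Assemble a brain model
#'
#' Bundles the head-approximating sphere (center + central exclusion radius),
#' the parcellation table, and the two cortical surfaces. The gray/white
#' interface mesh carries the interface points and normals used by the
#' per-current features; the pial mesh provides cortical thickness.
#'
#' @param regions parcellation data.frame with columns `region_id`, `name`,
#'   `hemisphere` (`left`/`right`/`midline`), `tissue`
#'   (`cortex`/`white_rim`/`subcortical`), `volume_mm3`, `paired_region_id`
#'   (NA where unpaired). Pairing must be symmetric and only link `cortex`
#'   with `white_rim`.
#' @param gw_mesh,pial_mesh `trimesh` surfaces (gray/white interface, pial).
#' @param sphere_center 3-vector, mm (head-sphere origin).
#' @param exclusion_radius mm; currents closer than this to the sphere center
#'   are invalid for brain conditions (the forward solution is ill-behaved
#'   near the center). Default 30.
#' @return An object of class `brain_model`.
#' @export
brain_model <- function(regions, gw_mesh, pial_mesh,
                        sphere_center = c(0, 0, 0), exclusion_radius = 30) {
  validate_parcellation(regions)
  stopifnot(inherits(gw_mesh, "trimesh"), inherits(pial_mesh, "trimesh"),
            length(sphere_center) == 3, exclusion_radius >= 0)
  model <- structure(list(regions = regions, gw_mesh = gw_mesh,
                          pial_mesh = pial_mesh,
                          sphere_center = as.numeric(sphere_center),
                          exclusion_radius = exclusion_radius),
                     class = "brain_model")
  # cache per-gw-vertex cortical thickness: distance to the nearest pial vertex
  model$gw_thickness <- nearest_dist(gw_mesh$vertices, pial_mesh$vertices)
  model
}

#' @export
print.brain_model <- function(x, ...) {
  cat(sprintf(
    "brain_model: %d regions (%d cortex, %d white_rim, %d subcortical)\n",
    nrow(x$regions), sum(x$regions$tissue == "cortex"),
    sum(x$regions$tissue == "white_rim"),
    sum(x$regions$tissue == "subcortical")))
  cat(sprintf("  gw: %d vertices; pial: %d vertices; exclusion %.0f mm\n",
              nrow(x$gw_mesh$vertices), nrow(x$pial_mesh$vertices),
              x$exclusion_radius))
  invisible(x)
}

validate_parcellation <- function(regions) {
  need <- c("region_id", "name", "hemisphere", "tissue", "volume_mm3",
            "paired_region_id")
  if (!all(need %in% names(regions)))
    stop("parcellation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(regions$region_id)) stop("region_ids must be unique")
  if (any(regions$volume_mm3 <= 0)) stop("region volumes must be > 0")
  if (!all(regions$tissue %in% c("cortex", "white_rim", "subcortical")))
    stop("tissue must be cortex, white_rim or subcortical")
  paired <- !is.na(regions$paired_region_id)
  for (i in which(paired)) {
    j <- match(regions$paired_region_id[i], regions$region_id)
    if (is.na(j)) stop("paired_region_id refers to a missing region")
    if (is.na(regions$paired_region_id[j]) ||
        regions$paired_region_id[j] != regions$region_id[i])
      stop("region pairing must be symmetric")
    if (!setequal(regions$tissue[c(i, j)], c("cortex", "white_rim")))
      stop("pairing is only allowed between cortex and white_rim")
  }
  invisible(regions)
}

# row-wise nearest-neighbour distances from points to a vertex set (chunked
# full scan; vertex counts here are small enough that this is exact and fast)
nearest_dist <- function(points, vertices) {
  nearest_index(points, vertices)$dist
}

nearest_index <- function(points, vertices) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  idx <- integer(n)
  dst <- numeric(n)
  v2 <- rowSums(vertices^2)
  chunk <- max(1L, as.integer(2e6 / nrow(vertices)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    p <- points[s:e, , drop = FALSE]
    # squared distances via the expansion |p - v|^2 = |p|^2 - 2 p.v + |v|^2
    d2 <- outer(rowSums(p^2), v2, "+") - 2 * p %*% t(vertices)
    idx[s:e] <- max.col(-d2, ties.method = "first")  # lowest index on ties
    dst[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(e - s + 1L), idx[s:e])]))
  }
  list(index = idx, dist = dst)
}

#' Nearest point on the gray/white interface
#'
#' Returns, for each query location, the gray/white-interface mesh vertex
#' minimizing Euclidean distance, together with the interface normal at that
#' vertex. Queries operate on mesh vertices (not interpolated surface
#' points); ties break to the lowest vertex index.
#'
#' @param location numeric 3-vector, or an `n x 3` matrix of locations (mm).
#' @param model a [brain_model()].
#' @return A list with `point` (`n x 3`), `normal` (`n x 3`, unit rows),
#'   `index` (vertex index) and `dist` (mm). For a single 3-vector input the
#'   matrices have one row.
#' @export
nearest_interface_point <- function(location, model) {
  if (nrow(model$gw_mesh$vertices) == 0) stop("empty gray/white mesh")
  loc <- matrix(as.numeric(location), ncol = 3)
  ni <- nearest_index(loc, model$gw_mesh$vertices)
  list(point = model$gw_mesh$vertices[ni$index, , drop = FALSE],
       normal = model$gw_mesh$normals[ni$index, , drop = FALSE],
       index = ni$index, dist = ni$dist)
}

#' Radial unit vector from the head-sphere origin through a location
#'
#' @param location numeric 3-vector or `n x 3` matrix (mm).
#' @param model a [brain_model()].
#' @return Unit 3-vector (or `n x 3` matrix of unit rows).
#' @export
radial_vector <- function(location, model) {
  loc <- matrix(as.numeric(location), ncol = 3)
  d <- sweep(loc, 2, model$sphere_center)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("location coincides with the sphere center")
  out <- d / len
  if (length(location) == 3 && is.null(dim(location))) out[1, ] else out
}

#' Four local geometric features of a current event
#'
#' For each current with location `I` and tangent-plane direction vector `d`:
#' \itemize{
#'   \item `f1 = cos(d, n)` — cosine between the current direction and the
#'     gray/white-interface normal `n` at the nearest interface point;
#'   \item `f2 = cos(r, n)` — cosine between the radial vector through `I`
#'     and that normal;
#'   \item `f3` — distance (mm) from `I` to the nearest interface point;
#'   \item `f4` — cortical thickness (mm) at `I`: distance from that
#'     interface point to its nearest pial point.
#' }
#' Only `f1` depends on the direction of current flow; `f2`--`f4` are purely
#' positional, which is why `f1` carries the state-vs-state signal while all
#' four separate brain currents from empty-room dark counts.
#'
#' @param events data.frame with columns `x_mm`, `y_mm`, `z_mm`, `dx`, `dy`,
#'   `dz` (one row per current), or a single list/row with those fields.
#' @param model a [brain_model()].
#' @return data.frame with columns `f1`, `f2`, `f3`, `f4` (one row per event).
#' @export
compute_features <- function(events, model) {
  events <- as.data.frame(events)
  loc <- as.matrix(events[, c("x_mm", "y_mm", "z_mm")])
  dir <- as.matrix(events[, c("dx", "dy", "dz")])
  cdist <- sqrt(rowSums(sweep(loc, 2, model$sphere_center)^2))
  if (any(cdist == 0))
    stop("event located at the sphere center: radial vector undefined")
  nip <- nearest_interface_point(loc, model)
  r <- radial_vector(loc, model)
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  dlen <- sqrt(rowSums(dir^2))
  f1 <- rowSums(dir * nip$normal) / dlen
  f2 <- rowSums(r * nip$normal)
  f4 <- model$gw_thickness[nip$index]
  data.frame(f1 = pmin(1, pmax(-1, f1)), f2 = pmin(1, pmax(-1, f2)),
             f3 = nip$dist, f4 = f4)
}

#' Read / write a parcellation table
#'
#' TSV with header `region_id, name, hemisphere, tissue, volume_mm3,
#' paired_region_id`.
#'
#' @param path file path.
#' @param regions parcellation data.frame.
#' @return `read_parcellation()` returns the validated data.frame.
#' @export
read_parcellation <- function(path) {
  validate_parcellation(read_tsv_table(path))
}

#' @rdname read_parcellation
#' @export
write_parcellation <- function(regions, path) {
  write_tsv_table(validate_parcellation(regions), path)
}

#' Read / write current-event tables
#'
#' TSV with header `subject_id, session, condition, time_ms, x_mm, y_mm,
#' z_mm, dx, dy, dz, region_id` plus the optional ground-truth column
#' `is_dark` emitted by the synthetic generator (excluded from analysis
#' inputs, retained for oracle evaluation of the screen).
#'
#' @param path file path.
#' @param events events data.frame.
#' @return `read_events()` returns a data.frame.
#' @export
read_events <- function(path) read_tsv_table(path)

#' @rdname read_events
#' @export
write_events <- function(events, path) write_tsv_table(events, path)

#' Check current-event validity against a brain model
#'
#' Verifies the event invariants: unit direction vectors, direction
#' orthogonal to the radial vector at the event location (directions live in
#' the tangent plane of the head-approximating sphere), and — for brain
#' conditions (`rest`/`task`) — location outside the central exclusion
#' sphere.
#'
#' @param events events data.frame.
#' @param model a [brain_model()].
#' @param tol tolerance for the unit-norm and orthogonality checks.
#' @return Logical vector, one entry per event.
#' @export
validate_events <- function(events, model, tol = 1e-6) {
  loc <- as.matrix(events[, c("x_mm", "y_mm", "z_mm")])
  dir <- as.matrix(events[, c("dx", "dy", "dz")])
  ok_unit <- abs(sqrt(rowSums(dir^2)) - 1) <= tol
  r <- sweep(loc, 2, model$sphere_center)
  rlen <- sqrt(rowSums(r^2))
  ok_tan <- abs(rowSums(dir * r) / pmax(rlen, .Machine$double.eps)) <= tol
  ok_excl <- rlen >= model$exclusion_radius |
    events$condition %in% "empty"
  ok_unit & ok_tan & ok_excl
}
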