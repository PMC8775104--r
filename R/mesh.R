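# Triangulated surface meshes: construction, vertex normals, ASCII OFF/PLY io.

#' Triangulated surface mesh
#'
#' A minimal triangle-mesh container: an `n x 3` vertex matrix (mm), an
#' `m x 3` integer face matrix (1-based vertex indices), and unit vertex
#' normals. Vertex normals are area-weighted averages of incident face
#' normals: summing un-normalized face cross-products weights each face by
#' twice its area, after which the per-vertex sum is normalized.
#'
#' @param vertices numeric matrix `n x 3`.
#' @param faces integer matrix `m x 3`, 1-based indices into `vertices`.
#' @return An object of class `trimesh` with elements `vertices`, `faces`,
#'   `normals`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || nrow(vertices) == 0)
    stop("mesh vertices must be a non-empty n x 3 matrix")
  if (!all(is.finite(vertices))) stop("mesh vertices must be finite")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 normals = area_weighted_normals(vertices, faces)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

area_weighted_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  # cross product of the two edge vectors: |.| = 2 * face area
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # accumulate over the three face corners (vectorized per coordinate)
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- faces[, k]
    for (j in 1:3) {
      acc <- rowsum(fn[, j], idx)
      vn[as.integer(rownames(acc)), j] <- vn[as.integer(rownames(acc)), j] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Unit icosphere mesh
#'
#' Recursively subdivided icosahedron projected to the unit sphere; the
#' standard starting point for closed genus-0 test surfaces.
#'
#' @param subdivisions non-negative integer; 0 gives the icosahedron
#'   (12 vertices), each level quadruples the face count (3 gives 642
#'   vertices / 1280 faces).
#' @return A `trimesh` with unit-length vertices.
#' @export
icosphere <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- edge_mid[[key]]
      if (!is.null(got)) return(got)
      m <- unit(v[i, ] + v[j, ])
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- matrix(m, 1)
      edge_mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); cc <- midpoint(k, i)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(c(i, a, cc), c(j, b, a),
                                       c(k, cc, b), c(a, b, cc))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  trimesh(v, f)
}

#' Read and write meshes in ASCII OFF / PLY formats
#'
#' `read_mesh()` dispatches on the leading magic line (`OFF` or `ply`);
#' writers emit minimal valid ASCII files. Only triangle faces are supported.
#'
#' @param path file path.
#' @param mesh a `trimesh`.
#' @return `read_mesh`, `read_off`, `read_ply` return a `trimesh`.
#' @export
read_mesh <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^OFF", first)) read_off(path)
  else if (grepl("^ply", first)) read_ply(path)
  else stop("unrecognized mesh format (expected ASCII OFF or PLY): ", path)
}

#' @rdname read_mesh
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (nv < 1) stop("empty mesh in ", path)
  vals <- scan(text = lines[3:(2 + nv)], quiet = TRUE)
  v <- matrix(vals, ncol = 3, byrow = TRUE)
  fvals <- scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE)
  f <- matrix(fvals, ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("only triangle faces are supported")
  trimesh(v, f[, 2:4] + 1L)
}

#' @rdname read_mesh
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 10), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("not a PLY file: ", path)
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1):length(lines)]
  v <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  f <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("only triangle faces are supported")
  trimesh(v, f[, 2:4] + 1L)
}

#' @rdname read_mesh
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 10), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}
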