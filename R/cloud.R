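#' Point-cloud tibbles
#'
#' Throughout the package a point cloud is an ordinary tibble with numeric
#' columns `x`, `y`, `z` (centimetres once the scene scale has been restored)
#' and, optionally, 8-bit integer color columns `r`, `g`, `b` in `[0, 255]`.
#' Extra columns (class labels, leaf ids, ...) ride along untouched, so clouds
#' compose naturally with dplyr verbs. `as_cloud()` builds such a tibble from
#' a matrix or data frame and validates it.
#'
#' @param x A data frame with columns `x`, `y`, `z` (and optionally `r`, `g`,
#'   `b`), or a numeric matrix with 3 (coordinates) or 6 (coordinates + RGB)
#'   columns.
#' @return A tibble with at least columns `x`, `y`, `z`.
#' @examples
#' as_cloud(matrix(rnorm(30), ncol = 3))
#' @export
as_cloud <- function(x) {
  if (is.matrix(x)) {
    if (!ncol(x) %in% c(3L, 6L)) {
      abort("matrix input must have 3 or 6 columns")
    }
    m <- unname(x)
    out <- tibble(x = m[, 1], y = m[, 2], z = m[, 3])
    if (ncol(m) == 6L) {
      out$r <- as.integer(round(m[, 4]))
      out$g <- as.integer(round(m[, 5]))
      out$b <- as.integer(round(m[, 6]))
    }
  } else if (is.data.frame(x)) {
    out <- as_tibble(x)
  } else {
    abort("cannot interpret `x` as a point cloud")
  }
  validate_cloud(out)
  out
}

#' @param cloud A point-cloud tibble.
#' @param colors Require color columns?
#' @rdname as_cloud
#' @export
validate_cloud <- function(cloud, colors = FALSE) {
  if (!is.data.frame(cloud)) abort("a point cloud must be a data frame")
  miss <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(miss)) {
    abort(paste0("point cloud is missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in c("x", "y", "z")) {
    v <- cloud[[col]]
    if (!is.numeric(v)) abort(paste0("column `", col, "` must be numeric"))
    if (length(v) && any(!is.finite(v))) {
      abort(paste0("column `", col, "` contains non-finite coordinates"))
    }
  }
  if (has_colors(cloud)) {
    for (col in c("r", "g", "b")) {
      v <- cloud[[col]]
      if (any(is.na(v)) || any(v < 0 | v > 255)) {
        abort(paste0("color column `", col, "` must lie in [0, 255]"))
      }
    }
  } else if (colors) {
    abort("point cloud has no r/g/b color columns")
  }
  invisible(cloud)
}

#' @rdname as_cloud
#' @export
has_colors <- function(cloud) {
  all(c("r", "g", "b") %in% names(cloud))
}

# n x 3 coordinate matrix of a cloud (no dimnames)
cloud_matrix <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

cloud_colors <- function(cloud) {
  cbind(cloud$r, cloud$g, cloud$b)
}

# rebuild a cloud from a coordinate matrix, keeping non-coordinate columns
set_coords <- function(cloud, mat) {
  cloud$x <- mat[, 1]
  cloud$y <- mat[, 2]
  cloud$z <- mat[, 3]
  cloud
}

#' Triangle meshes
#'
#' A triangle mesh couples an `n x 3` vertex coordinate matrix (cm) with an
#' `m x 3` matrix of 1-based vertex indices. Faces with out-of-range or
#' repeated indices are rejected.
#'
#' @param vertices Numeric matrix (or data frame) of vertex coordinates.
#' @param faces Integer matrix of 1-based vertex index triples.
#' @return An object of class `triangle_mesh`.
#' @examples
#' triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' @export
triangle_mesh <- function(vertices, faces) {
  if (is.data.frame(vertices)) vertices <- cloud_matrix(as_cloud(vertices))
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) abort("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(faces) && ncol(faces) != 3) abort("faces must have 3 columns")
  if (length(faces)) {
    if (any(faces < 1L) || any(faces > nrow(vertices))) {
      abort("face indices out of range")
    }
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3])) {
      abort("faces with repeated vertices are not allowed")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @param mesh A `triangle_mesh`.
#' @rdname triangle_mesh
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  F <- mesh$faces
  if (!nrow(F)) return(0)
  P <- mesh$vertices
  v1 <- P[F[, 2], , drop = FALSE] - P[F[, 1], , drop = FALSE]
  v2 <- P[F[, 3], , drop = FALSE] - P[F[, 1], , drop = FALSE]
  cr <- cbind(
    v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
    v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
    v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  )
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, area ", format(mesh_area(x)), "\n", sep = "")
  invisible(x)
}
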