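#' Read and write colored point clouds
#'
#' Supported formats: PLY (ASCII and binary little-endian), PCD (ASCII) and
#' plain XYZ / XYZRGB text. Color, when present in the file, is returned in
#' the `r`, `g`, `b` columns; point order is preserved as stored. Coordinates
#' are held as doubles regardless of the on-disk precision.
#'
#' @param path File path.
#' @param format One of `"auto"` (detect from the extension), `"ply"`,
#'   `"pcd"`, `"xyz"`.
#' @return `read_cloud()`: a point-cloud tibble. `write_cloud()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' write_cloud(as_cloud(matrix(rnorm(9), 3)), f)
#' read_cloud(f)
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") format <- guess_format(path)
  switch(format,
    ply = read_ply(path)$cloud,
    pcd = read_pcd(path),
    xyz = read_xyz(path)
  )
}

#' @param cloud A non-empty point-cloud tibble.
#' @param binary For PLY: write binary little-endian (doubles, bit-exact
#'   round trip) instead of ASCII?
#' @rdname read_cloud
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = FALSE) {
  format <- match.arg(format)
  validate_cloud(cloud)
  if (!nrow(cloud)) abort("refusing to write an empty point cloud")
  if (format == "auto") format <- guess_format(path)
  switch(format,
    ply = write_ply(cloud, path, binary = binary),
    pcd = write_pcd(cloud, path),
    xyz = write_xyz(cloud, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "xyz")) return(ext)
  if (ext %in% c("txt", "pts")) return("xyz")
  abort(paste0("cannot detect point-cloud format from extension: .", ext))
}

# ---------------------------------------------------------------- PLY reading

ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

ply_read_bin <- function(raw_vec, type, n) {
  sz <- ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !type %in% c("uchar", "uint8", "ushort", "uint16")
  # readBin cannot do unsigned 4-byte; values beyond 2^31 are not expected here
  if (type %in% c("uint", "uint32")) signed <- TRUE
  readBin(raw_vec, what, n = n, size = sz, signed = signed || sz == 4 || sz == 8,
          endian = "little")
}

parse_ply_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  chunk <- readBin(con, "raw", n = 262144L)
  pos <- grepRaw("end_header\r\n|end_header\n", chunk)
  if (!length(pos)) abort(paste0("malformed PLY (no end_header): ", path))
  hdr_end <- grepRaw("\n", chunk, offset = pos)[1]
  header_len <- hdr_end
  txt <- rawToChar(chunk[seq_len(header_len)])
  Encoding(txt) <- "latin1"
  lines <- strsplit(substr(txt, 1, header_len), "\r?\n")[[1]]
  if (!length(lines) || trimws(lines[1]) != "ply") {
    abort(paste0("not a PLY file: ", path))
  }
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (!length(fmt_line)) abort("malformed PLY: missing format line")
  fmt <- strsplit(trimws(fmt_line[1]), "[[:space:]]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    abort(paste0("unsupported PLY format: ", fmt))
  }
  elements <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements, header_bytes = header_len)
}

read_ply <- function(path) {
  hd <- parse_ply_header(path)
  if (is.null(hd$elements$vertex)) abort(paste0("PLY without vertex element: ", path))
  if (hd$format == "ascii") read_ply_ascii(path, hd) else read_ply_binary(path, hd)
}

ply_vertex_columns <- function(props) {
  nm <- vapply(props, `[[`, "", "name")
  coord <- match(c("x", "y", "z"), nm)
  if (any(is.na(coord))) abort("PLY vertex element lacks x/y/z properties")
  rgb <- match(c("red", "green", "blue"), nm)
  if (any(is.na(rgb))) rgb <- match(c("r", "g", "b"), nm)
  list(coord = coord, rgb = if (any(is.na(rgb))) NULL else rgb)
}

read_ply_ascii <- function(path, hd) {
  all_lines <- readLines(path, warn = FALSE)
  i_end <- grep("^end_header", all_lines)[1]
  body <- all_lines[-seq_len(i_end)]
  body <- body[nzchar(trimws(body))]
  pos <- 0L
  out <- list(cloud = NULL, faces = NULL)
  for (el in hd$elements) {
    n <- el$count
    if (pos + n > length(body)) {
      abort(paste0("PLY declares ", n, " '", el$name, "' records but the file ends at record ",
                   length(body) - pos))
    }
    rows <- body[pos + seq_len(n)]
    pos <- pos + n
    if (el$name == "vertex") {
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        abort("list properties on the vertex element are not supported")
      }
      vals <- tryCatch(
        scan(text = rows, quiet = TRUE),
        warning = function(w) abort("malformed PLY vertex records"),
        error = function(e) abort("malformed PLY vertex records")
      )
      np <- length(el$props)
      if (length(vals) != n * np) {
        bad <- which(vapply(strsplit(trimws(rows), "[[:space:]]+"), length, 1L) != np)[1]
        abort(paste0("malformed PLY vertex record at data line ", bad %||% NA))
      }
      m <- matrix(vals, ncol = np, byrow = TRUE)
      cols <- ply_vertex_columns(el$props)
      cl <- tibble(x = m[, cols$coord[1]], y = m[, cols$coord[2]], z = m[, cols$coord[3]])
      if (!is.null(cols$rgb)) {
        cl$r <- as.integer(m[, cols$rgb[1]])
        cl$g <- as.integer(m[, cols$rgb[2]])
        cl$b <- as.integer(m[, cols$rgb[3]])
      }
      out$cloud <- cl
    } else if (el$name == "face") {
      toks <- strsplit(trimws(rows), "[[:space:]]+")
      cnt <- vapply(toks, function(t) as.integer(t[1]), 1L)
      if (any(is.na(cnt)) || any(cnt != 3L)) {
        abort(paste0("only triangular faces are supported (record ",
                     which(is.na(cnt) | cnt != 3L)[1], ")"))
      }
      out$faces <- t(vapply(toks, function(t) as.integer(t[2:4]), integer(3))) + 1L
    }
  }
  if (any(!is.finite(cloud_matrix(out$cloud)))) abort("malformed PLY: non-finite coordinates")
  out
}

read_ply_binary <- function(path, hd) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = hd$header_bytes))
  data <- readBin(con, "raw", n = sz - hd$header_bytes)
  offset <- 0L
  out <- list(cloud = NULL, faces = NULL)
  for (el in hd$elements) {
    n <- el$count
    is_list <- vapply(el$props, `[[`, TRUE, "list")
    if (el$name == "vertex") {
      if (any(is_list)) abort("list properties on the vertex element are not supported")
      sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
      rec <- sum(sizes)
      need <- as.numeric(n) * rec
      if (offset + need > length(data)) abort("binary PLY truncated in vertex element")
      base <- offset + (seq_len(n) - 1L) * rec
      vals <- vector("list", length(el$props))
      off_in <- c(0L, cumsum(sizes))
      for (j in seq_along(el$props)) {
        s <- sizes[j]
        sel <- as.vector(outer(seq_len(s), base + off_in[j], `+`))
        vals[[j]] <- ply_read_bin(data[sel], el$props[[j]]$type, n)
      }
      offset <- offset + as.integer(need)
      nm <- vapply(el$props, `[[`, "", "name")
      cols <- ply_vertex_columns(el$props)
      cl <- tibble(x = vals[[cols$coord[1]]], y = vals[[cols$coord[2]]],
                   z = vals[[cols$coord[3]]])
      if (!is.null(cols$rgb)) {
        cl$r <- as.integer(vals[[cols$rgb[1]]])
        cl$g <- as.integer(vals[[cols$rgb[2]]])
        cl$b <- as.integer(vals[[cols$rgb[3]]])
      }
      out$cloud <- cl
    } else if (el$name == "face") {
      if (length(el$props) != 1L || !is_list[1]) abort("unsupported face element layout")
      p <- el$props[[1]]
      csz <- ply_type_size[[p$count_type]]
      isz <- ply_type_size[[p$type]]
      rec <- csz + 3L * isz
      cnt1 <- ply_read_bin(data[offset + 1L + 0L * rec + seq_len(csz)], p$count_type, 1L)
      if (cnt1 != 3L) abort("only triangular faces are supported")
      need <- as.numeric(n) * rec
      if (offset + need > length(data)) abort("binary PLY truncated in face element")
      base <- offset + (seq_len(n) - 1L) * rec
      cnts <- ply_read_bin(data[as.vector(outer(seq_len(csz), base, `+`))], p$count_type, n)
      if (any(cnts != 3L)) abort("only triangular faces are supported")
      idx <- matrix(0L, n, 3)
      for (j in 1:3) {
        sel <- as.vector(outer(seq_len(isz), base + csz + (j - 1L) * isz, `+`))
        idx[, j] <- ply_read_bin(data[sel], p$type, n)
      }
      out$faces <- idx + 1L
      offset <- offset + as.integer(need)
    } else {
      abort(paste0("unsupported PLY element: ", el$name))
    }
  }
  out
}

# ---------------------------------------------------------------- PLY writing

ply_header_lines <- function(n_vert, colors, binary, n_face = NULL) {
  c("ply",
    paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
    "comment written by wheatpheno",
    paste("element vertex", n_vert),
    "property double x", "property double y", "property double z",
    if (colors) c("property uchar red", "property uchar green", "property uchar blue"),
    if (!is.null(n_face)) c(paste("element face", n_face),
                            "property list uchar int vertex_indices"),
    "end_header")
}

write_ply <- function(cloud, path, binary = FALSE) {
  n <- nrow(cloud)
  colors <- has_colors(cloud)
  hdr <- ply_header_lines(n, colors, binary)
  if (!binary) {
    co <- sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z)
    if (colors) co <- paste(co, cloud$r, cloud$g, cloud$b)
    writeLines(c(hdr, co), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    coord_raw <- writeBin(as.vector(t(cloud_matrix(cloud))), raw(), size = 8,
                          endian = "little")
    if (colors) {
      rec <- 27L
      out <- raw(n * rec)
      base <- (seq_len(n) - 1L) * rec
      out[as.vector(outer(1:24, base, `+`))] <- coord_raw
      col_raw <- as.raw(as.vector(t(cloud_colors(cloud))))
      out[as.vector(outer(25:27, base, `+`))] <- col_raw
      writeBin(out, con)
    } else {
      writeBin(coord_raw, con)
    }
  }
  invisible(path)
}

# ----------------------------------------------------------------------- PCD

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i_data <- grep("^DATA", lines)[1]
  if (is.na(i_data)) abort(paste0("malformed PCD (no DATA line): ", path))
  hdr <- lines[seq_len(i_data)]
  get <- function(key) {
    ln <- grep(paste0("^", key, " "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][-1]
  }
  if (!identical(tolower(get("DATA")), "ascii")) abort("only ASCII PCD is supported")
  fields <- get("FIELDS")
  types <- get("TYPE")
  npts <- as.integer(get("POINTS")[1])
  body <- lines[-seq_len(i_data)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != npts) {
    abort(paste0("PCD declares ", npts, " points but the file has ", length(body),
                 " data lines"))
  }
  vals <- tryCatch(scan(text = body, quiet = TRUE),
                   warning = function(w) abort("malformed PCD data"),
                   error = function(e) abort("malformed PCD data"))
  if (length(vals) != npts * length(fields)) abort("malformed PCD data record")
  m <- matrix(vals, ncol = length(fields), byrow = TRUE)
  ix <- match(c("x", "y", "z"), fields)
  if (any(is.na(ix))) abort("PCD lacks x/y/z fields")
  cl <- tibble(x = m[, ix[1]], y = m[, ix[2]], z = m[, ix[3]])
  irgb <- match("rgb", fields)
  if (!is.na(irgb)) {
    v <- m[, irgb]
    packed <- if (!is.na(match("rgb", fields)) && types[irgb] == "F") {
      # float-packed rgb: reinterpret the float bits as an unsigned int
      readBin(writeBin(as.numeric(v), raw(), size = 4, endian = "little"),
              "integer", n = npts, size = 4, endian = "little")
    } else {
      as.integer(v)
    }
    cl$r <- bitwAnd(bitwShiftR(packed, 16L), 255L)
    cl$g <- bitwAnd(bitwShiftR(packed, 8L), 255L)
    cl$b <- bitwAnd(packed, 255L)
  }
  validate_cloud(cl)
  cl
}

write_pcd <- function(cloud, path) {
  n <- nrow(cloud)
  colors <- has_colors(cloud)
  fields <- if (colors) "x y z rgb" else "x y z"
  k <- if (colors) 4L else 3L
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", paste(rep(4, k), collapse = " ")),
           paste("TYPE", paste(c("F", "F", "F", "U")[seq_len(k)], collapse = " ")),
           paste("COUNT", paste(rep(1, k), collapse = " ")),
           paste("WIDTH", n), "HEIGHT 1", "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n), "DATA ascii")
  rows <- sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z)
  if (colors) {
    packed <- cloud$r * 65536L + cloud$g * 256L + cloud$b
    rows <- paste(rows, packed)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ------------------------------------------------------------------ XYZ text

read_xyz <- function(path) {
  m <- tryCatch(as.matrix(read.table(path)),
                error = function(e) abort(paste0("malformed XYZ file: ", conditionMessage(e))))
  if (!is.numeric(m)) abort("malformed XYZ file: non-numeric fields")
  if (!ncol(m) %in% c(3L, 6L)) {
    abort(paste0("XYZ file must have 3 or 6 columns, found ", ncol(m)))
  }
  as_cloud(unname(m))
}

write_xyz <- function(cloud, path) {
  rows <- sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z)
  if (has_colors(cloud)) rows <- paste(rows, cloud$r, cloud$g, cloud$b)
  writeLines(rows, path)
  invisible(path)
}

# ---------------------------------------------------------------------- mesh

#' Read and write triangle meshes
#'
#' PLY (ASCII or binary little-endian) and OBJ, chosen by file extension.
#'
#' @param mesh A [triangle_mesh()] with at least one face.
#' @param path Output path ending in `.ply` or `.obj`.
#' @return `write_mesh()`: `path` invisibly; `read_mesh()`: a `triangle_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!nrow(mesh$faces)) abort("refusing to write a mesh with no faces")
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    v <- sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
                 mesh$vertices[, 3])
    f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
    writeLines(c(v, f), path)
  } else if (ext == "ply") {
    hdr <- ply_header_lines(nrow(mesh$vertices), FALSE, FALSE, nrow(mesh$faces))
    v <- sprintf("%.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
                 mesh$vertices[, 3])
    f <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                 mesh$faces[, 3] - 1L)
    writeLines(c(hdr, v, f), path)
  } else {
    abort(paste0("unsupported mesh format: .", ext))
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
    fidx <- lapply(strsplit(sub("^f ", "", fl), "[[:space:]]+"), function(t) {
      as.integer(vapply(strsplit(t, "/"), `[[`, "", 1L))
    })
    f <- do.call(rbind, fidx)
    triangle_mesh(v, f)
  } else if (ext == "ply") {
    parts <- read_ply(path)
    if (is.null(parts$faces)) abort(paste0("PLY has no face element: ", path))
    triangle_mesh(cloud_matrix(parts$cloud), parts$faces)
  } else {
    abort(paste0("unsupported mesh format: .", ext))
  }
}
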