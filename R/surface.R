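#' Surface model of one proximal ulna
#'
#' Container for one side's segmented proximal-ulna surface: a point cloud in
#' mm (optionally with triangle faces), the anatomical side and a subject
#' identifier. CT segmentation and surface export happen upstream; this
#' package consumes the exported surface.
#'
#' @param points n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces Optional m x 3 integer matrix of 1-based vertex indices.
#' @param side `"left"` or `"right"`.
#' @param subject_id Subject identifier string.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(points, faces = NULL, side = c("right", "left"),
                          subject_id = "subject") {
  side <- match.arg(side)
  points <- as_points_matrix(points)
  if (nrow(points) < 3L) {
    rlang::abort("a surface model needs at least 3 points",
                 class = "coronoid_degenerate_error")
  }
  if (!all(is.finite(points))) {
    rlang::abort("surface coordinates must be finite",
                 class = "coronoid_degenerate_error")
  }
  # non-collinearity: rank of centred coordinates must exceed 1
  sv <- svd(sweep(points, 2, colMeans(points)), nu = 0)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-12)) {
    rlang::abort("surface points are collinear",
                 class = "coronoid_degenerate_error")
  }
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    stopifnot(ncol(faces) == 3L)
    if (any(faces < 1L) || any(faces > nrow(points))) {
      rlang::abort("face indices out of range", class = "coronoid_format_error")
    }
  }
  structure(list(points = points, faces = faces, side = side,
                 subject_id = as.character(subject_id)),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %s %s: %d points%s%s\n",
              x$subject_id, x$side, nrow(x$points),
              if (is.null(x$faces)) "" else sprintf(", %d faces", nrow(x$faces)),
              if (isTRUE(attr(x, "local"))) ", local frame" else ""))
  invisible(x)
}

#' @export
as_tibble.surface_model <- function(x, ...) {
  tibble::tibble(x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
                 side = x$side, subject_id = x$subject_id)
}

#' Read a surface model from file
#'
#' Supports ASCII/binary little-endian PLY, ASCII/binary STL, OBJ (`v`/`f`
#' records) and XYZ (whitespace-separated triples, `#` comments).
#' Coordinates are assumed to be in mm; no unit metadata is parsed (STL and
#' OBJ carry none, matching the CT-export convention). Triangle soups (STL)
#' are converted to point clouds by taking unique vertices; faces are
#' retained when the format provides them.
#'
#' @param path File path; extension selects the format.
#' @param side `"left"` or `"right"`.
#' @param subject_id Subject identifier.
#' @return A [surface_model()].
#' @export
read_surface <- function(path, side = c("right", "left"), subject_id = "subject") {
  side <- match.arg(side)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "coronoid_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    xyz = read_xyz(path),
    obj = read_obj(path),
    stl = read_stl(path),
    ply = read_ply(path),
    rlang::abort(sprintf("unsupported surface format '.%s'", ext),
                 class = "coronoid_format_error")
  )
  surface_model(parsed$points, parsed$faces, side = side, subject_id = subject_id)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    rlang::abort("empty XYZ file", class = "coronoid_degenerate_error")
  }
  vals <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(vals) != 3L)) {
    rlang::abort("XYZ rows must have exactly 3 columns", class = "coronoid_format_error")
  }
  pts <- matrix(suppressWarnings(as.numeric(unlist(vals))), ncol = 3, byrow = TRUE)
  if (anyNA(pts)) {
    rlang::abort("non-numeric XYZ coordinates", class = "coronoid_format_error")
  }
  list(points = pts, faces = NULL)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) {
    rlang::abort("OBJ file has no vertices", class = "coronoid_degenerate_error")
  }
  vt <- strsplit(trimws(sub("^v", "", vlines)), "[[:space:]]+")
  pts <- t(vapply(vt, function(v) as.numeric(v[1:3]), numeric(3)))
  faces <- NULL
  if (length(flines)) {
    ft <- strsplit(trimws(sub("^f", "", flines)), "[[:space:]]+")
    if (any(lengths(ft) != 3L)) {
      rlang::abort("only triangular OBJ faces are supported",
                   class = "coronoid_format_error")
    }
    # 'a/b/c' face syntax: keep the leading vertex index
    faces <- t(vapply(ft, function(f) as.integer(sub("/.*$", "", f)), integer(3)))
  }
  if (anyNA(pts)) rlang::abort("bad OBJ vertex line", class = "coronoid_format_error")
  list(points = pts, faces = faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  if (length(header) < 80L) {
    rlang::abort("truncated STL file", class = "coronoid_format_error")
  }
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (length(ntri) == 1L && !is.na(ntri) && file.size(path) == expected && ntri > 0) {
    # binary STL: 50-byte records of normal + 3 vertices (float32) + attribute
    tri <- matrix(NA_real_, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    if (!any(grepl("facet", txt, fixed = TRUE))) {
      rlang::abort("not a recognisable STL file", class = "coronoid_format_error")
    }
    vl <- grep("^[[:space:]]*vertex[[:space:]]", txt, value = TRUE)
    vt <- strsplit(trimws(sub("vertex", "", vl)), "[[:space:]]+")
    tri <- t(vapply(vt, function(v) as.numeric(v[1:3]), numeric(3)))
  }
  if (nrow(tri) %% 3L != 0L || anyNA(tri)) {
    rlang::abort("malformed STL triangle data", class = "coronoid_format_error")
  }
  # triangle soup -> unique vertices + index map (winding-agnostic by nature)
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  idx <- match(key, unique(key))
  pts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(points = pts, faces = faces)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!identical(magic, "ply")) {
    rlang::abort("missing 'ply' magic", class = "coronoid_format_error")
  }
  read_header_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) rlang::abort("truncated PLY header", class = "coronoid_format_error")
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  read_header_line() # rest of magic line
  fmt <- NULL; elements <- list(); current <- NULL
  repeat {
    ln <- trimws(read_header_line())
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      current <- tok[2]
      elements[[current]] <- list(count = as.integer(tok[3]), props = list())
    }
    if (tok[1] == "property") {
      p <- if (tok[2] == "list") list(list = TRUE, sizes = tok[3:4], name = tok[5]) else
        list(list = FALSE, type = tok[2], name = tok[3])
      elements[[current]]$props <- c(elements[[current]]$props, list(p))
    }
    if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    rlang::abort("unsupported PLY format (need ascii or binary_little_endian)",
                 class = "coronoid_format_error")
  }
  if (is.null(elements$vertex)) {
    rlang::abort("PLY file lacks a vertex element", class = "coronoid_format_error")
  }
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                 int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar_bin <- function(type, n = 1L) {
    sz <- type_size[[type]]
    what <- if (type %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
    readBin(con, what, n, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  pts <- NULL; faces <- NULL
  if (fmt == "ascii") {
    rest <- strsplit(paste(readLines(con, warn = FALSE), collapse = " "),
                     "[[:space:]]+")[[1]]
    rest <- rest[nzchar(rest)]
    cursor <- 1L
    take <- function(n) {
      v <- suppressWarnings(as.numeric(rest[cursor:(cursor + n - 1L)]))
      cursor <<- cursor + n
      v
    }
    for (el in names(elements)) {
      e <- elements[[el]]
      if (el == "vertex") {
        np <- length(e$props)
        block <- matrix(take(e$count * np), e$count, np, byrow = TRUE)
        nm <- vapply(e$props, `[[`, "", "name")
        pts <- block[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (el == "face") {
        faces <- matrix(NA_integer_, e$count, 3L)
        for (i in seq_len(e$count)) {
          k <- take(1)
          if (k != 3) rlang::abort("only triangular PLY faces supported",
                                   class = "coronoid_format_error")
          faces[i, ] <- take(3) + 1L
        }
      } else {
        for (i in seq_len(e$count)) take(length(e$props)) # skip unknown element
      }
    }
  } else {
    for (el in names(elements)) {
      e <- elements[[el]]
      if (el == "vertex") {
        nm <- vapply(e$props, `[[`, "", "name")
        vals <- matrix(NA_real_, e$count, length(e$props))
        for (i in seq_len(e$count)) {
          for (j in seq_along(e$props)) {
            vals[i, j] <- read_scalar_bin(e$props[[j]]$type)
          }
        }
        pts <- vals[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (el == "face") {
        faces <- matrix(NA_integer_, e$count, 3L)
        for (i in seq_len(e$count)) {
          k <- read_scalar_bin(e$props[[1]]$sizes[1])
          if (k != 3) rlang::abort("only triangular PLY faces supported",
                                   class = "coronoid_format_error")
          faces[i, ] <- read_scalar_bin(e$props[[1]]$sizes[2], 3L) + 1L
        }
      }
    }
  }
  if (is.null(pts) || anyNA(pts)) {
    rlang::abort("failed to parse PLY vertices", class = "coronoid_format_error")
  }
  list(points = pts, faces = faces)
}

#' Write a surface model to file
#'
#' PLY (ASCII or binary little-endian with double-precision coordinates),
#' OBJ and XYZ are supported. Binary STL (float32 vertices) is provided for
#' interchange but truncates coordinates to single precision.
#'
#' @param model A [surface_model()].
#' @param path Output path; extension selects the format.
#' @param binary For PLY/STL: write the binary flavour.
#' @return `path`, invisibly.
#' @export
write_surface <- function(model, path, binary = FALSE) {
  stopifnot(inherits(model, "surface_model"))
  ext <- tolower(tools::file_ext(path))
  pts <- model$points
  faces <- model$faces
  if (ext == "xyz") {
    writeLines(c("# exported point cloud (mm)",
                 sprintf("%.10g %.10g %.10g", pts[, 1], pts[, 2], pts[, 3])), path)
  } else if (ext == "obj") {
    out <- sprintf("v %.10g %.10g %.10g", pts[, 1], pts[, 2], pts[, 3])
    if (!is.null(faces)) {
      out <- c(out, sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]))
    }
    writeLines(out, path)
  } else if (ext == "ply") {
    hdr <- c("ply",
             sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
             sprintf("element vertex %d", nrow(pts)),
             "property double x", "property double y", "property double z")
    if (!is.null(faces)) {
      hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices")
    }
    hdr <- c(hdr, "end_header")
    if (binary) {
      con <- file(path, "wb")
      writeLines(hdr, con)
      writeBin(as.numeric(t(pts)), con, size = 8L, endian = "little")
      if (!is.null(faces)) {
        for (i in seq_len(nrow(faces))) {
          writeBin(as.raw(3L), con)
          writeBin(as.integer(faces[i, ] - 1L), con, size = 4L, endian = "little")
        }
      }
      close(con)
    } else {
      body <- sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])
      if (!is.null(faces)) {
        body <- c(body, sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                                faces[, 3] - 1L))
      }
      writeLines(c(hdr, body), path)
    }
  } else if (ext == "stl") {
    if (is.null(faces)) {
      rlang::abort("STL export needs faces", class = "coronoid_format_error")
    }
    con <- file(path, "wb")
    writeBin(c(rep(as.raw(0L), 80L)), con)
    writeBin(as.integer(nrow(faces)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(faces))) {
      v <- pts[faces[i, ], , drop = FALSE]
      nrm <- tryCatch(unit3(cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])),
                      error = function(e) c(0, 0, 1))
      writeBin(as.numeric(c(nrm, t(v))), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
    close(con)
  } else {
    rlang::abort(sprintf("unsupported export format '.%s'", ext),
                 class = "coronoid_format_error")
  }
  invisible(path)
}
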