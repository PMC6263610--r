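#' Read a point cloud from PLY, PCD or XYZ
#'
#' Supported formats: PLY (ASCII and binary little-endian, `element vertex`
#' with `x`/`y`/`z` and optional `red`/`green`/`blue`), PCD v0.7 ASCII
#' (`FIELDS x y z` with optional packed `rgb` or separate `r g b`), and
#' whitespace-delimited XYZ / XYZRGB text. Point order in the file is
#' preserved. Colors are normalized to `[0, 1]`; the dialect they arrived in
#' is recorded so [write_cloud()] round-trips them.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`. `"auto"` uses
#'   the file extension, falling back to content sniffing.
#' @return A point cloud tibble (see [point_cloud()]). An empty file yields
#'   an empty cloud.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
#' read_cloud(f)
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File does not exist: ", path))
  if (format == "auto") format <- guess_cloud_format(path)
  switch(format,
    ply = read_ply(path),
    pcd = read_pcd(path),
    xyz = read_xyz(path)
  )
}

guess_cloud_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "xyz")) return(ext)
  head_bytes <- readBin(path, "raw", n = 16L)
  head_txt <- rawToChar(head_bytes[head_bytes != as.raw(0)])
  if (startsWith(head_txt, "ply")) return("ply")
  if (grepl("^#|^VERSION", head_txt)) return("pcd")
  "xyz"
}

#' Write a point cloud to PLY, PCD or XYZ
#'
#' Colors, when present, are written back in the dialect they were read in
#' (`color_dialect` attribute; 0--255 integers by default).
#'
#' @param cloud a point cloud tibble.
#' @param path output file.
#' @param format `"auto"` (from extension), `"ply"`, `"pcd"` or `"xyz"`.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = FALSE) {
  check_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "pcd", "xyz")) ext else "xyz"
  }
  switch(format,
    ply = write_ply(cloud, path, binary = binary),
    pcd = write_pcd(cloud, path),
    xyz = write_xyz(cloud, path)
  )
  invisible(path)
}

# ---- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(point_cloud(matrix(numeric(), ncol = 3)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (!all(nf %in% c(3L, 6L)) || length(unique(nf)) != 1L) {
    bad <- which(!(nf %in% c(3L, 6L)))[1]
    if (is.na(bad)) bad <- which(nf != nf[1])[1]
    abort(paste0("Malformed XYZ record on line ", bad,
                 ": expected 3 (xyz) or 6 (xyzrgb) fields."))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = nf[1], byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    abort(paste0("Non-numeric value in XYZ file on line ", bad, "."))
  }
  colors <- if (nf[1] == 6L) vals[, 4:6, drop = FALSE] else NULL
  point_cloud(vals[, 1:3, drop = FALSE], colors)
}

write_xyz <- function(cloud, path) {
  xyz <- cloud_xyz(cloud)
  if (has_colors(cloud)) {
    col <- denormalize_colors(cloud)
    mat <- cbind(format_coord(xyz), format_color(col, attr_dialect(cloud)))
  } else {
    mat <- format_coord(xyz)
  }
  writeLines(apply(mat, 1, paste, collapse = " "), path)
}

attr_dialect <- function(cloud) {
  attr(cloud, "color_dialect") %||% "uchar255"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

denormalize_colors <- function(cloud) {
  col <- cbind(cloud$r, cloud$g, cloud$b)
  if (attr_dialect(cloud) == "uchar255") round(col * 255) else col
}

format_coord <- function(m) {
  matrix(formatC(m, format = "g", digits = 9), nrow = nrow(m))
}

format_color <- function(col, dialect) {
  if (dialect == "uchar255") {
    matrix(formatC(col, format = "d"), nrow = nrow(col))
  } else {
    matrix(formatC(col, format = "g", digits = 7), nrow = nrow(col))
  }
}

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) {
    abort("Not a PLY file: missing 'ply' magic line.")
  }
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) abort("Truncated PLY header: no end_header.")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(), list = logical())
    } else if (tok[1] == "property") {
      if (is.null(cur)) abort("PLY header: property before any element.")
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, tok[4])
        cur$list <- c(cur$list, TRUE)
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
        cur$list <- c(cur$list, FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      abort(paste0("Unrecognized PLY header line: '", line, "'"))
    }
  }
  if (is.null(fmt)) abort("PLY header missing 'format' line.")
  if (!"vertex" %in% names(elements)) {
    abort("PLY file has no 'element vertex'.")
  }
  if (fmt == "ascii") {
    read_ply_ascii_body(con, elements)
  } else if (fmt == "binary_little_endian") {
    read_ply_binary_body(con, elements, endian = "little")
  } else if (fmt == "binary_big_endian") {
    read_ply_binary_body(con, elements, endian = "big")
  } else {
    abort(paste0("Unsupported PLY format: ", fmt))
  }
}

ply_vertex_cloud <- function(vert, values) {
  need <- c("x", "y", "z")
  if (!all(need %in% vert$props)) {
    abort("PLY vertex element lacks x/y/z properties.")
  }
  pts <- cbind(values[["x"]], values[["y"]], values[["z"]])
  color_names <- c("red", "green", "blue")
  alt <- c("r", "g", "b")
  if (all(color_names %in% vert$props)) {
    cols <- cbind(values[["red"]], values[["green"]], values[["blue"]])
    tp <- vert$types[match(color_names, vert$props)]
  } else if (all(alt %in% vert$props)) {
    cols <- cbind(values[["r"]], values[["g"]], values[["b"]])
    tp <- vert$types[match(alt, vert$props)]
  } else {
    return(point_cloud(pts))
  }
  dialect <- if (all(tp %in% c("float", "float32", "double", "float64"))) {
    "float01"
  } else {
    "uchar255"
  }
  point_cloud(pts, cols, color_dialect = dialect)
}

read_ply_ascii_body <- function(con, elements) {
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 0L
  for (el in elements) {
    if (el$name == "vertex") {
      if (any(el$list)) abort("PLY vertex element with list properties is unsupported.")
      if (el$count == 0) return(point_cloud(matrix(numeric(), ncol = 3)))
      take <- lines[pos + seq_len(el$count)]
      if (anyNA(take)) abort("Truncated PLY: fewer vertex records than declared.")
      toks <- strsplit(trimws(take), "\\s+")
      if (any(lengths(toks) < length(el$props))) {
        bad <- which(lengths(toks) < length(el$props))[1]
        abort(paste0("Malformed PLY vertex record ", bad,
                     ": fewer fields than declared properties."))
      }
      m <- matrix(as.numeric(unlist(lapply(toks, `[`, seq_along(el$props)))),
                  ncol = length(el$props), byrow = TRUE)
      values <- stats::setNames(
        lapply(seq_along(el$props), function(j) m[, j]), el$props)
      return(ply_vertex_cloud(el, values))
    }
    pos <- pos + el$count  # each record of a preceding element is one line
  }
}

read_ply_binary_body <- function(con, elements, endian) {
  for (el in elements) {
    if (any(el$list)) {
      abort("Binary PLY: list properties before/within vertex are unsupported.")
    }
    sizes <- ply_type_size[el$types]
    if (anyNA(sizes)) abort("Unknown PLY property type.")
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * el$count)
    if (el$name != "vertex") next
    if (length(raw) < rec * el$count) {
      abort("Truncated binary PLY: fewer vertex bytes than declared.")
    }
    offs <- cumsum(c(0L, sizes))
    bytes <- matrix(raw, nrow = rec)
    values <- list()
    for (j in seq_along(el$props)) {
      bj <- as.vector(bytes[(offs[j] + 1):offs[j + 1], , drop = FALSE])
      tp <- el$types[j]
      values[[el$props[j]]] <- switch(tp,
        float = , float32 = readBin(bj, "double", n = el$count, size = 4,
                                    endian = endian),
        double = , float64 = readBin(bj, "double", n = el$count, size = 8,
                                     endian = endian),
        uchar = , uint8 = as.double(readBin(bj, "integer", n = el$count,
                                            size = 1, signed = FALSE,
                                            endian = endian)),
        char = , int8 = as.double(readBin(bj, "integer", n = el$count,
                                          size = 1, signed = TRUE,
                                          endian = endian)),
        ushort = , uint16 = as.double(readBin(bj, "integer", n = el$count,
                                              size = 2, signed = FALSE,
                                              endian = endian)),
        short = , int16 = as.double(readBin(bj, "integer", n = el$count,
                                            size = 2, signed = TRUE,
                                            endian = endian)),
        as.double(readBin(bj, "integer", n = el$count, size = 4,
                          endian = endian))
      )
    }
    return(ply_vertex_cloud(el, values))
  }
}

write_ply <- function(cloud, path, binary = FALSE) {
  xyz <- cloud_xyz(cloud)
  n <- nrow(xyz)
  with_color <- has_colors(cloud)
  dialect <- attr_dialect(cloud)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    paste("element vertex", n),
    "property float x", "property float y", "property float z")
  if (with_color) {
    ctype <- if (dialect == "uchar255") "uchar" else "float"
    header <- c(header,
                paste("property", ctype, "red"),
                paste("property", ctype, "green"),
                paste("property", ctype, "blue"))
  }
  header <- c(header, "end_header")
  if (!binary) {
    body <- format_coord(xyz)
    if (with_color) {
      body <- cbind(body, format_color(denormalize_colors(cloud), dialect))
    }
    writeLines(c(header, apply(body, 1, paste, collapse = " ")), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    col <- if (with_color) denormalize_colors(cloud) else NULL
    for (i in seq_len(n)) {
      writeBin(as.double(xyz[i, ]), con, size = 4, endian = "little")
      if (with_color) {
        if (dialect == "uchar255") {
          writeBin(as.raw(col[i, ]), con)
        } else {
          writeBin(as.double(col[i, ]), con, size = 4, endian = "little")
        }
      }
    }
  }
  invisible(path)
}

# ---- PCD ------------------------------------------------------------------

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  hdr <- list()
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 0) next
    key <- toupper(tok[1])
    hdr[[key]] <- tok[-1]
    if (key == "DATA") {
      if (!identical(tolower(tok[2]), "ascii")) {
        abort("Only ASCII PCD files are supported.")
      }
      body_start <- i + 1L
      break
    }
  }
  if (is.na(body_start)) abort("PCD header has no DATA line.")
  fields <- tolower(hdr[["FIELDS"]])
  if (!all(c("x", "y", "z") %in% fields)) {
    abort("PCD file must have FIELDS x y z.")
  }
  n <- as.integer(hdr[["POINTS"]][1] %||% hdr[["WIDTH"]][1])
  body <- lines[seq(body_start, length.out = length(lines) - body_start + 1)]
  body <- body[nzchar(trimws(body))]
  if (!is.na(n) && length(body) < n) {
    abort("Truncated PCD: fewer data rows than POINTS declares.")
  }
  if (length(body) == 0) return(point_cloud(matrix(numeric(), ncol = 3)))
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != length(fields))) {
    bad <- which(lengths(toks) != length(fields))[1]
    abort(paste0("Malformed PCD record on data row ", bad, "."))
  }
  m <- matrix(as.numeric(unlist(toks)), ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  if ("rgb" %in% fields) {
    cols <- unpack_pcd_rgb(m[, "rgb"])
    point_cloud(pts, cols, color_dialect = "uchar255")
  } else if (all(c("r", "g", "b") %in% fields)) {
    point_cloud(pts, m[, c("r", "g", "b"), drop = FALSE])
  } else {
    point_cloud(pts)
  }
}

# PCL packs rgb into the bit pattern of a float: 0x00RRGGBB.
unpack_pcd_rgb <- function(rgb_float) {
  raw <- writeBin(as.double(rgb_float), raw(), size = 4, endian = "little")
  bytes <- matrix(as.integer(raw), nrow = 4)
  cbind(bytes[3, ], bytes[2, ], bytes[1, ])
}

pack_pcd_rgb <- function(col255) {
  col255 <- round(col255)
  packed <- col255[, 1] * 65536 + col255[, 2] * 256 + col255[, 3]
  raw <- writeBin(as.integer(packed), raw(), size = 4, endian = "little")
  readBin(raw, "double", n = nrow(col255), size = 4, endian = "little")
}

write_pcd <- function(cloud, path) {
  xyz <- cloud_xyz(cloud)
  n <- nrow(xyz)
  with_color <- has_colors(cloud)
  fields <- if (with_color) "x y z rgb" else "x y z"
  nf <- if (with_color) 4L else 3L
  header <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    paste("FIELDS", fields),
    paste("SIZE", paste(rep(4, nf), collapse = " ")),
    paste("TYPE", paste(rep("F", nf), collapse = " ")),
    paste("COUNT", paste(rep(1, nf), collapse = " ")),
    paste("WIDTH", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    paste("POINTS", n),
    "DATA ascii")
  body <- format_coord(xyz)
  if (with_color) {
    packed <- pack_pcd_rgb(cbind(cloud$r, cloud$g, cloud$b) * 255)
    body <- cbind(body, formatC(packed, format = "g", digits = 9))
  }
  writeLines(c(header, apply(body, 1, paste, collapse = " ")), path)
  invisible(path)
}

# ---- labels ---------------------------------------------------------------

#' Read or write per-point segmentation labels
#'
#' Label files are plain text, one integer per line, in cloud point order.
#' The label `-1` is reserved for unassigned/noise points.
#'
#' @param labels integer vector of per-point labels.
#' @param path file to read or write.
#' @param cloud optional cloud the labels annotate; when given, the label
#'   count is checked against its point count.
#' @return `read_labels()` returns an integer vector; `write_labels()`
#'   returns `path` invisibly.
#' @export
write_labels <- function(labels, path, cloud = NULL) {
  if (anyNA(labels) || any(labels != as.integer(labels))) {
    abort("`labels` must be integers (use -1 for unassigned).")
  }
  if (!is.null(cloud)) {
    check_cloud(cloud)
    if (length(labels) != nrow(cloud)) {
      abort(paste0("Label length (", length(labels),
                   ") does not match cloud size (", nrow(cloud), ")."))
    }
  }
  writeLines(formatC(as.integer(labels), format = "d"), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(integer())
  vals <- suppressWarnings(as.integer(lines))
  if (anyNA(vals)) {
    abort(paste0("Non-integer label on line ", which(is.na(vals))[1], "."))
  }
  vals
}
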