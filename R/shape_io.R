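# Shape and sample-sheet I/O. All geometry is in millimetres; no unit
# inference is performed. Mesh formats are ASCII only (the deliverable and its
# fixtures are plain text).

#' Construct a shape sample
#'
#' One bone/structure instance: identifying metadata plus an n x 3 point
#' matrix and optional triangle faces (1-based vertex indices).
#'
#' @param sample_id,subject_id identifier strings.
#' @param side "L" or "R".
#' @param sex "F", "M" or "unknown".
#' @param age age in years, NA if unavailable.
#' @param points n x 3 numeric matrix (mm), n >= 4, finite.
#' @param faces optional integer matrix with 3 columns of vertex indices.
#' @return object of class `shape_sample`.
#' @export
shape_sample <- function(points, sample_id = "sample", subject_id = sample_id,
                         side = "L", sex = "unknown", age = NA_real_,
                         faces = NULL) {
  .check_points(points)
  if (nrow(points) < 4L)
    stop("a shape_sample needs at least 4 points", call. = FALSE)
  if (!side %in% c("L", "R"))
    stop("side must be 'L' or 'R'", call. = FALSE)
  if (!sex %in% c("F", "M", "unknown"))
    stop("sex must be 'F', 'M' or 'unknown'", call. = FALSE)
  if (!is.null(faces)) {
    faces <- matrix(as.integer(faces), ncol = 3L)
    if (any(faces < 1L) || any(faces > nrow(points)))
      stop("faces index points outside 1..n_points", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 subject_id = as.character(subject_id),
                 side = side, sex = sex, age = as.double(age),
                 points = points, faces = faces),
            class = "shape_sample")
}

#' @export
print.shape_sample <- function(x, ...) {
  cat(sprintf("<shape_sample %s> subject=%s side=%s sex=%s age=%s; %d points%s\n",
              x$sample_id, x$subject_id, x$side, x$sex,
              ifelse(is.na(x$age), "NA", format(x$age, digits = 3)),
              nrow(x$points),
              if (is.null(x$faces)) "" else sprintf(", %d faces", nrow(x$faces))))
  invisible(x)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = "ply", off = "off", stl = "stl",
         csv = "csv", txt = "csv",
         stop(sprintf("cannot infer shape format from extension '%s'", ext),
              call. = FALSE))
}

#' Read a shape from file
#'
#' Supported formats: ASCII PLY, OFF, ASCII STL and CSV landmark tables (one
#' `x,y,z` row per point, optional header). Coordinates are taken as stored
#' (millimetres by package convention). Faces are retained where the format
#' carries them; STL facets are welded into a shared-vertex mesh by exact
#' coordinate match.
#'
#' @param path file to read.
#' @param format one of "auto", "ply", "off", "stl", "csv".
#' @return a [shape_sample()] carrying geometry only (metadata left at
#'   defaults; fill in from a sample sheet).
#' @export
read_shape <- function(path, format = c("auto", "ply", "off", "stl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") format <- .guess_format(path)
  geo <- switch(format,
                ply = .read_ply(path),
                off = .read_off(path),
                stl = .read_stl(path),
                csv = list(points = .read_csv_xyz(path), faces = NULL))
  if (is.null(geo$points) || nrow(geo$points) == 0L)
    stop(sprintf("%s: empty geometry", path), call. = FALSE)
  shape_sample(points = geo$points, faces = geo$faces,
               sample_id = tools::file_path_sans_ext(basename(path)))
}

.read_csv_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: empty file", path), call. = FALSE)
  start <- 1L
  first <- strsplit(lines[1L], ",")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  rows <- lines[seq.int(start, length(lines))]
  parsed <- lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(rows[i], ",")[[1L]]))
    if (length(v) < 3L || any(is.na(v[1:3])))
      stop(sprintf("%s: non-numeric or short row at line %d", path,
                   i + start - 1L), call. = FALSE)
    v[1:3]
  })
  pts <- do.call(rbind, parsed)
  colnames(pts) <- c("x", "y", "z")
  pts
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop(sprintf("%s: not a PLY file (missing 'ply' magic)", path), call. = FALSE)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop(sprintf("%s: PLY header not terminated", path), call. = FALSE)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop(sprintf("%s: only ASCII PLY is supported", path), call. = FALSE)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element\\s+vertex\\s", hdr, value = TRUE)))
  if (!length(nv) || is.na(nv[1L]))
    stop(sprintf("%s: PLY header lacks 'element vertex'", path), call. = FALSE)
  nv <- nv[1L]
  nf_line <- grep("^element\\s+face\\s", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("^element\\s+face\\s+", "", nf_line[1L])) else 0L
  body <- lines[seq.int(hdr_end + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop(sprintf("%s: expected %d vertex + %d face lines, found %d",
                 path, nv, nf, length(body)), call. = FALSE)
  pts <- t(vapply(seq_len(nv), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1L]]))
    if (length(v) < 3L || any(is.na(v[1:3])))
      stop(sprintf("%s: malformed vertex element %d", path, i), call. = FALSE)
    v[1:3]
  }, numeric(3)))
  faces <- NULL
  if (nf > 0L) {
    faces <- t(vapply(seq_len(nf), function(i) {
      v <- suppressWarnings(as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1L]]))
      if (length(v) < 4L || is.na(v[1L]) || v[1L] != 3L)
        stop(sprintf("%s: face element %d is not a triangle", path, i), call. = FALSE)
      v[2:4] + 1L
    }, integer(3)))
  }
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, faces = faces)
}

.read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  if (!length(lines) || toupper(trimws(lines[1L])) != "OFF")
    stop(sprintf("%s: not an OFF file (missing 'OFF' magic)", path), call. = FALSE)
  cnt <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(cnt) < 2L || any(is.na(cnt[1:2])))
    stop(sprintf("%s: malformed OFF count line", path), call. = FALSE)
  nv <- cnt[1L]; nf <- cnt[2L]
  if (length(lines) < 2L + nv + nf)
    stop(sprintf("%s: expected %d vertices and %d faces, file too short",
                 path, nv, nf), call. = FALSE)
  pts <- t(vapply(seq_len(nv), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + i]), "\\s+")[[1L]]))
    if (length(v) < 3L || any(is.na(v[1:3])))
      stop(sprintf("%s: malformed OFF vertex %d", path, i), call. = FALSE)
    v[1:3]
  }, numeric(3)))
  faces <- NULL
  if (nf > 0L) {
    faces <- t(vapply(seq_len(nf), function(i) {
      v <- suppressWarnings(as.integer(strsplit(trimws(lines[2L + nv + i]), "\\s+")[[1L]]))
      if (length(v) < 4L || is.na(v[1L]) || v[1L] != 3L)
        stop(sprintf("%s: OFF face %d is not a triangle", path, i), call. = FALSE)
      v[2:4] + 1L
    }, integer(3)))
  }
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, faces = faces)
}

.read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1L]))
    stop(sprintf("%s: only ASCII STL is supported (missing 'solid')", path),
         call. = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop(sprintf("%s: STL vertex count (%d) is not a multiple of 3",
                 path, length(vl)), call. = FALSE)
  verts <- t(vapply(vl, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])[-1L])
    if (length(v) < 3L || any(is.na(v[1:3])))
      stop(sprintf("%s: malformed STL vertex at line %d", path, i), call. = FALSE)
    v[1:3]
  }, numeric(3)))
  key <- apply(verts, 1L, function(r) paste(sprintf("%.9g", r), collapse = "_"))
  uid <- match(key, unique(key))
  pts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, faces = faces)
}

#' Write a shape to file
#'
#' @param shape a [shape_sample()] or an n x 3 matrix.
#' @param path output path.
#' @param format one of "auto", "ply", "off", "stl", "csv". STL requires
#'   faces.
#' @return `path`, invisibly.
#' @export
write_shape <- function(shape, path, format = c("auto", "ply", "off", "stl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (is.matrix(shape)) shape <- list(points = shape, faces = NULL)
  pts <- shape$points; faces <- shape$faces
  .check_points(pts)
  fmt <- function(m) apply(m, 1L, function(r) paste(sprintf("%.9g", r), collapse = " "))
  out <- switch(
    format,
    csv = c("x,y,z", apply(pts, 1L, function(r) paste(sprintf("%.9g", r), collapse = ","))),
    ply = {
      hdr <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z")
      if (!is.null(faces))
        hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
                 "property list uchar int vertex_indices")
      body <- fmt(pts)
      if (!is.null(faces))
        body <- c(body, apply(faces - 1L, 1L, function(r) paste(c(3L, r), collapse = " ")))
      c(hdr, "end_header", body)
    },
    off = {
      nf <- if (is.null(faces)) 0L else nrow(faces)
      body <- fmt(pts)
      if (nf > 0L)
        body <- c(body, apply(faces - 1L, 1L, function(r) paste(c(3L, r), collapse = " ")))
      c("OFF", sprintf("%d %d 0", nrow(pts), nf), body)
    },
    stl = {
      if (is.null(faces)) stop("STL output requires faces", call. = FALSE)
      tri <- lapply(seq_len(nrow(faces)), function(i) {
        p <- pts[faces[i, ], , drop = FALSE]
        nrm <- c((p[2, ] - p[1, ])[2] * (p[3, ] - p[1, ])[3] - (p[2, ] - p[1, ])[3] * (p[3, ] - p[1, ])[2],
                 (p[2, ] - p[1, ])[3] * (p[3, ] - p[1, ])[1] - (p[2, ] - p[1, ])[1] * (p[3, ] - p[1, ])[3],
                 (p[2, ] - p[1, ])[1] * (p[3, ] - p[1, ])[2] - (p[2, ] - p[1, ])[2] * (p[3, ] - p[1, ])[1])
        nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
        c(sprintf("  facet normal %s", paste(sprintf("%.9g", nrm), collapse = " ")),
          "    outer loop",
          sprintf("      vertex %s", fmt(p)),
          "    endloop", "  endfacet")
      })
      c("solid shape", unlist(tri), "endsolid shape")
    })
  writeLines(out, path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' CSV with required columns `sample_id`, `subject_id`, `side`, `sex`, `age`
#' (and optionally `path` pointing at a geometry file per sample). Validation
#' enforces unique sample ids, side values in {L, R} and at most one L and one
#' R per subject. Missing ages are parsed as NA and flagged (attribute
#' `missing_age`) so downstream ANCOVA can exclude them with a logged count.
#'
#' @param path CSV file.
#' @return a data.frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "side", "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("sample sheet lacks required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample_id: %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")),
         call. = FALSE)
  bad_side <- setdiff(unique(df$side), c("L", "R"))
  if (length(bad_side))
    stop(sprintf("side values outside {L, R}: %s", paste(bad_side, collapse = ", ")),
         call. = FALSE)
  dup <- duplicated(df[, c("subject_id", "side")])
  if (any(dup))
    stop(sprintf("subject(s) with two same-side entries: %s",
                 paste(unique(df$subject_id[dup]), collapse = ", ")), call. = FALSE)
  df$age <- suppressWarnings(as.numeric(df$age))
  df$sex[!df$sex %in% c("F", "M")] <- "unknown"
  attr(df, "missing_age") <- df$sample_id[is.na(df$age)]
  df
}

#' Write a sample sheet
#' @param sheet data.frame with sample-sheet columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
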