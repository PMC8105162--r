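#' Labeled point cloud
#'
#' The core container used throughout the package: an `N x 3` coordinate
#' matrix in millimetres plus a per-point integer instance label. Label `-1`
#' marks unassigned points; label `1` is reserved for the stem and the pot
#' (when present) carries the largest instance id. Optional per-point unit
#' normals are carried for the MRF smoothness term.
#'
#' @param coords numeric matrix with 3 columns (x, y, z), millimetres.
#' @param labels integer vector of length `nrow(coords)`; `-1` = unassigned.
#'   Defaults to all `-1`.
#' @param normals optional numeric matrix of unit row vectors, same shape as
#'   `coords`.
#' @param source_path optional character scalar recording provenance.
#' @return An object of class `labeled_cloud`.
#' @examples
#' pc <- labeled_cloud(matrix(rnorm(30), ncol = 3))
#' pc
#' @export
labeled_cloud <- function(coords, labels = NULL, normals = NULL,
                          source_path = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have exactly 3 columns")
  if (nrow(coords) < 1L) stop("empty input: a cloud needs at least one point")
  if (!all(is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  if (is.null(labels)) labels <- rep(-1L, n)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have one entry per point")
  if (any(is.na(labels)) || any(labels != -1L & labels < 1L)) {
    stop("labels must be -1 (unassigned) or positive instance ids")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!identical(dim(normals), dim(coords))) {
      stop("normals must match coords in shape")
    }
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6)) stop("normals must be unit vectors")
  }
  structure(
    list(coords = coords, labels = labels, normals = normals,
         source_path = source_path),
    class = "labeled_cloud"
  )
}

#' @export
print.labeled_cloud <- function(x, ...) {
  n <- nrow(x$coords)
  ids <- sort(unique(x$labels[x$labels != -1L]))
  cat(sprintf("<labeled_cloud> %d points, %d labeled instance(s)%s\n",
              n, length(ids),
              if (is.null(x$normals)) "" else ", with normals"))
  if (length(ids)) {
    cnt <- table(factor(x$labels, levels = ids))
    cat("  instances:", paste(sprintf("%s:%d", names(cnt), cnt), collapse = " "),
        "\n")
  }
  cat(sprintf("  unassigned: %d\n", sum(x$labels == -1L)))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [labeled_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

# ---------------------------------------------------------------------------
# readers / writers

#' Read a point cloud from disk
#'
#' Supports whitespace- or comma-delimited text (`x y z [label ...]`, extra
#' columns beyond the fourth are ignored with a warning) and PLY files (ASCII
#' or binary little-endian) carrying `x`, `y`, `z` vertex properties plus an
#' optional scalar `label` property. Points without a label column are read as
#' unassigned (`-1`). Row order is preserved.
#'
#' @param path file to read.
#' @param dialect `"auto"` (by extension), `"txt"` or `"ply"`.
#' @param units coordinate units in the file; coordinates are rescaled to
#'   millimetres on read.
#' @return a [labeled_cloud()].
#' @export
read_cloud <- function(path, dialect = c("auto", "txt", "ply"),
                       units = c("mm", "cm", "m")) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "txt"
  }
  cloud <- if (dialect == "ply") .read_ply(path) else .read_txt(path)
  scale <- c(mm = 1, cm = 10, m = 1000)[[units]]
  if (scale != 1) cloud$coords <- cloud$coords * scale
  cloud$source_path <- path
  cloud
}

.read_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty input: ", path)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop(sprintf("parse error at line %d: expected at least 3 fields, got %d",
                 bad, nf[which(nf < 3L)[1L]]))
  }
  if (any(nf > 4L)) {
    warning(sprintf("%d row(s) with more than 4 columns; extra columns ignored",
                    sum(nf > 4L)))
  }
  vals <- suppressWarnings(lapply(fields, function(f) as.numeric(f[1:min(4, length(f))])))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-numeric field", lineno[bad[1L]]))
  }
  coords <- t(vapply(vals, function(v) v[1:3], numeric(3)))
  labels <- if (all(nf >= 4L)) {
    vapply(vals, function(v) as.integer(v[4L]), integer(1))
  } else if (any(nf >= 4L)) {
    stop("parse error: mixed labeled and unlabeled rows")
  } else NULL
  labeled_cloud(coords, labels)
}

#' Write a point cloud to disk
#'
#' Text output emits one `x y z label` row per point (unassigned points carry
#' `-1`); PLY output is ASCII with double `x`, `y`, `z` and an `int` `label`
#' vertex property.
#'
#' @param cloud a [labeled_cloud()].
#' @param path output file.
#' @param dialect `"auto"` (by extension), `"txt"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, dialect = c("auto", "txt", "ply")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "txt"
  }
  if (dialect == "ply") .write_ply(cloud, path) else .write_txt(cloud, path)
  invisible(path)
}

.write_txt <- function(cloud, path) {
  rows <- sprintf("%.6f %.6f %.6f %d",
                  cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3],
                  cloud$labels)
  ok <- tryCatch(
    { writeLines(rows, path); TRUE },
    error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e))
  )
  invisible(ok)
}

.write_ply <- function(cloud, path) {
  n <- n_points(cloud)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error opening ", path))
  on.exit(close(con))
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    "property int label", "end_header"
  )
  writeLines(header, con)
  writeLines(sprintf("%.6f %.6f %.6f %d",
                     cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3],
                     cloud$labels), con)
}

# read one LF-terminated header line from a binary connection
.read_header_line <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("parse error: truncated PLY header")
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  sub("\r$", "", rawToChar(bytes))
}

.ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (.read_header_line(con) != "ply") stop("parse error: not a PLY file")
  format <- NULL
  count <- NULL
  props <- list()
  in_vertex <- FALSE
  repeat {
    line <- .read_header_line(con)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (tok[2] == "vertex") {
        count <- as.integer(tok[3])
        in_vertex <- TRUE
      } else {
        if (is.null(count)) stop("parse error: vertex element must come first")
        in_vertex <- FALSE
      }
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("list properties on vertices are unsupported")
      props[[length(props) + 1L]] <- list(type = tok[2], name = tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(format) || is.null(count)) stop("parse error: malformed PLY header")
  if (count < 1L) stop("empty input: ", path)
  names <- vapply(props, `[[`, character(1), "name")
  if (!all(c("x", "y", "z") %in% names)) {
    stop("PLY vertex element must define x, y, z properties")
  }
  if (format == "ascii") {
    vals <- matrix(NA_real_, count, length(props))
    for (i in seq_len(count)) {
      tok <- strsplit(trimws(.read_header_line(con)), "[[:space:]]+")[[1]]
      if (length(tok) < length(props)) {
        stop(sprintf("parse error: vertex row %d has %d fields, expected %d",
                     i, length(tok), length(props)))
      }
      v <- suppressWarnings(as.numeric(tok[seq_along(props)]))
      if (any(is.na(v))) stop(sprintf("parse error: non-numeric field in vertex row %d", i))
      vals[i, ] <- v
    }
  } else if (format == "binary_little_endian") {
    types <- vapply(props, `[[`, character(1), "type")
    sizes <- .ply_type_size[types]
    if (any(is.na(sizes))) stop("unsupported PLY property type")
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = stride * count)
    if (length(raw) < stride * count) stop("parse error: truncated PLY body")
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))
    vals <- matrix(NA_real_, count, length(props))
    base <- (seq_len(count) - 1L) * stride
    for (j in seq_along(props)) {
      sel <- as.vector(outer(seq_len(sizes[j]), base + offsets[j], "+"))
      bytes <- raw[sel]
      vals[, j] <- switch(types[j],
        float = , float32 = readBin(bytes, "numeric", n = count, size = 4L,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = count, size = 8L,
                                     endian = "little"),
        uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = count,
                                             size = 1L, signed = FALSE,
                                             endian = "little")),
        char = , int8 = as.numeric(readBin(bytes, "integer", n = count,
                                           size = 1L, signed = TRUE,
                                           endian = "little")),
        ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = count,
                                               size = 2L, signed = FALSE,
                                               endian = "little")),
        short = , int16 = as.numeric(readBin(bytes, "integer", n = count,
                                             size = 2L, signed = TRUE,
                                             endian = "little")),
        as.numeric(readBin(bytes, "integer", n = count, size = 4L,
                           endian = "little"))
      )
    }
  } else {
    stop("unsupported PLY format: ", format)
  }
  coords <- vals[, match(c("x", "y", "z"), names), drop = FALSE]
  labels <- if ("label" %in% names) as.integer(vals[, match("label", names)]) else NULL
  labeled_cloud(coords, labels)
}

# ---------------------------------------------------------------------------
# normals

#' Estimate per-point surface normals
#'
#' Each normal is the least-variance principal direction of the point's
#' k-neighbourhood (the point itself included). Normal sign is arbitrary for
#' the downstream angle term, so a deterministic convention is applied:
#' positive dot product with +Z, ties resolved toward +X and then +Y.
#'
#' @param cloud a [labeled_cloud()].
#' @param k neighbourhood size, `k >= 3` and `k < n_points(cloud)`.
#' @return the cloud with `normals` populated.
#' @export
estimate_normals <- function(cloud, k = 10L) {
  k <- as.integer(k)
  n <- n_points(cloud)
  if (k < 3L) stop("k must be >= 3")
  if (n <= k) stop("cloud must have more than k points")
  nb <- .knn(cloud$coords, cloud$coords, k = k)$idx
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    x <- cloud$coords[nb[i, ], , drop = FALSE]
    cv <- cov(x)
    if (!all(is.finite(cv)) || sum(diag(cv)) < 1e-18) {
      stop(sprintf("zero-variance neighbourhood at point %d", i))
    }
    e <- eigen(cv, symmetric = TRUE)
    v <- e$vectors[, 3L]
    tol <- 1e-8
    if (v[3] < -tol) v <- -v
    else if (abs(v[3]) <= tol) {
      if (v[1] < -tol) v <- -v
      else if (abs(v[1]) <= tol && v[2] < 0) v <- -v
    }
    normals[i, ] <- v / sqrt(sum(v^2))
  }
  cloud$normals <- normals
  cloud
}
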