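#' Write a mesh to PLY
#'
#' ASCII or binary little-endian PLY. Optional per-face scalar fields are
#' embedded as extra float properties of the face element (after the vertex
#' index list), one property per column.
#'
#' @param mesh a [trimesh].
#' @param path output file.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @param face_fields optional data frame / named list of per-face numeric
#'   fields (one value per face).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("ascii", "binary_little_endian"),
                      face_fields = NULL) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces - 1L
  nf <- nrow(f)
  if (!is.null(face_fields)) {
    face_fields <- as.data.frame(face_fields)
    stopifnot(nrow(face_fields) == nf)
  }
  hdr <- c("ply", paste("format", format, "1.0"),
           "comment rbcmesh export",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  if (!is.null(face_fields))
    hdr <- c(hdr, sprintf("property double %s", names(face_fields)))
  hdr <- c(hdr, "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(format_sig(v), 1, paste, collapse = " "), con)
    face_txt <- paste(3L, f[, 1], f[, 2], f[, 3])
    if (!is.null(face_fields)) {
      extra <- apply(format_sig(as.matrix(face_fields)), 1, paste, collapse = " ")
      face_txt <- paste(face_txt, extra)
    }
    writeLines(face_txt, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    ff <- if (is.null(face_fields)) NULL else as.matrix(face_fields)
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
      if (!is.null(ff)) writeBin(as.numeric(ff[i, ]), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

format_sig <- function(m, digits = 9) {
  matrix(formatC(m, digits = digits, format = "g"), nrow = nrow(m))
}

#' Read a PLY mesh written by [write_ply()]
#'
#' Supports ASCII and binary little-endian files with double vertex
#' coordinates and optional per-face double properties.
#'
#' @param path PLY file.
#' @return A [trimesh]; per-face fields, if present, are returned in
#'   `attr(, "face_fields")`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
    if (length(hdr) > 200) stop("not a PLY file: header too long")
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE))
  fmt <- strsplit(fmt, " ")[[1]][1]
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face", hdr, value = TRUE)))
  iface <- grep("^element face", hdr)
  fld <- grep("^property double ", hdr[(iface + 1):length(hdr)], value = TRUE)
  fld <- setdiff(sub("^property double ", "", fld), c("x", "y", "z"))
  nfld <- length(fld)
  if (fmt == "ascii") {
    txt <- readLines(con)
    vtx <- do.call(rbind, lapply(txt[seq_len(nv)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    fc <- do.call(rbind, lapply(txt[nv + seq_len(nf)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    faces <- fc[, 2:4, drop = FALSE] + 1
    fields <- if (nfld > 0) fc[, 4 + seq_len(nfld), drop = FALSE] else NULL
  } else if (fmt == "binary_little_endian") {
    vtx <- matrix(readBin(con, "numeric", n = 3 * nv, size = 8,
                          endian = "little"), ncol = 3, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    fields <- if (nfld > 0) matrix(0, nf, nfld) else NULL
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stop("only triangle faces are supported")
      faces[i, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little") + 1L
      if (nfld > 0)
        fields[i, ] <- readBin(con, "numeric", n = nfld, size = 8, endian = "little")
    }
  } else stop("unsupported PLY format: ", fmt)
  mesh <- trimesh(vtx[, 1:3, drop = FALSE], faces)
  if (nfld > 0) {
    colnames(fields) <- fld
    attr(mesh, "face_fields") <- as.data.frame(fields)
  }
  mesh
}

#' Write a mesh to OFF
#' @inheritParams write_ply
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nrow(mesh$vertices), nrow(mesh$faces), 0L), con)
  writeLines(apply(format_sig(mesh$vertices), 1, paste, collapse = " "), con)
  f <- mesh$faces - 1L
  writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Write a mesh to ASCII STL
#' @inheritParams write_ply
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, name = "rbcmesh") {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
  n <- n / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  fmt <- function(m) apply(format_sig(m), 1, paste, collapse = " ")
  block <- paste0("facet normal ", fmt(n), "\n outer loop\n  vertex ",
                  fmt(v[f[, 1], , drop = FALSE]), "\n  vertex ",
                  fmt(v[f[, 2], , drop = FALSE]), "\n  vertex ",
                  fmt(v[f[, 3], , drop = FALSE]), "\n endloop\nendfacet")
  writeLines(block, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a per-face scalar table to CSV
#'
#' @param fields data frame with a `face` column (e.g. a curvature field).
#' @param path output CSV.
#' @export
write_face_csv <- function(fields, path) {
  df <- as.data.frame(fields)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "face"
  df[num] <- lapply(df[num], function(x) as.numeric(formatC(x, digits = 9, format = "g")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
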