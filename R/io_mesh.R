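#' Read a surface mesh file
#'
#' Supports ASCII PLY, OFF and STL. STL files carry no connectivity, so
#' vertices are merged exactly on read to recover a shared-vertex mesh.
#'
#' @param path mesh file (`.ply`, `.off`, `.stl`).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         off = read_off(path),
         stl = read_stl(path),
         stop(sprintf("unsupported mesh format '.%s' (use .ply, .off or .stl)", ext)))
}

#' Write a surface mesh file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format chosen by extension (`.ply`, `.off`,
#'   `.stl`).
#' @param digits significant digits for coordinates (default 17, lossless for
#'   doubles).
#' @export
write_mesh <- function(mesh, path, digits = 17L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, digits),
         off = write_off(mesh, path, digits),
         stl = write_stl(mesh, path, digits),
         stop(sprintf("unsupported mesh format '.%s' (use .ply, .off or .stl)", ext)))
  invisible(path)
}

fmt_coords <- function(m, digits) {
  apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                collapse = " "))
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0L || trimws(ln[1]) != "ply") stop("not a PLY file")
  hdr_end <- which(trimws(ln) == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- ln[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", trimws(hdr), value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", trimws(hdr), value = TRUE)[1]))
  if (is.na(nv)) stop("malformed PLY: missing vertex element")
  body <- ln[(hdr_end + 1L):length(ln)]
  vl <- body[seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
               nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fm <- matrix(0L, 0L, 3L)
  if (!is.na(nf) && nf > 0L) {
    fl <- body[nv + seq_len(nf)]
    toks <- strsplit(trimws(fl), "\\s+")
    fm <- t(vapply(toks, function(tk) {
      if (as.integer(tk[1]) != 3L) stop("only triangular PLY faces are supported")
      as.integer(tk[2:4]) + 1L
    }, integer(3)))
  }
  triangle_mesh(vm, fm)
}

write_ply <- function(mesh, path, digits) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(fmt_coords(mesh$vertices, digits), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

read_off <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (ln[1] != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vm <- matrix(as.numeric(unlist(strsplit(ln[2 + seq_len(nv)], "\\s+"))),
               nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fm <- matrix(0L, 0L, 3L)
  if (nf > 0L) {
    toks <- strsplit(ln[2 + nv + seq_len(nf)], "\\s+")
    fm <- t(vapply(toks, function(tk) {
      if (as.integer(tk[1]) != 3L) stop("only triangular OFF faces are supported")
      as.integer(tk[2:4]) + 1L
    }, integer(3)))
  }
  triangle_mesh(vm, fm)
}

write_off <- function(mesh, path, digits) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nrow(mesh$vertices), nrow(mesh$faces), 0L)), con)
  writeLines(fmt_coords(mesh$vertices, digits), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

read_stl <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  if (!startsWith(tolower(ln[1]), "solid")) stop("only ASCII STL is supported")
  vl <- grep("^vertex\\s", ln, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3")
  vm <- matrix(as.numeric(unlist(strsplit(sub("^vertex\\s+", "", vl), "\\s+"))),
               ncol = 3L, byrow = TRUE)
  key <- apply(vm, 1, paste, collapse = " ")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  fm <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(vm[uk, , drop = FALSE], fm)
}

write_stl <- function(mesh, path, digits) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  f <- mesh$faces; v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    writeLines(c("facet normal 0 0 0", "outer loop",
                 paste("vertex", fmt_coords(tri, digits)),
                 "endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}
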