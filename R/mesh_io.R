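#' Export an interface mesh to OFF or OBJ
#'
#' Writes the boundary surface (vertices and triangular facets) in the OFF
#' or Wavefront OBJ format, chosen by file extension. OBJ facet indices are
#' 1-based, OFF indices 0-based, per the respective conventions. Only
#' boundary vertices are written; facet indices are remapped accordingly.
#'
#' @param mesh an `interface_mesh`.
#' @param path output path ending in `.off` or `.obj`.
#' @return the path, invisibly.
#' @export
export_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "interface_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("off", "obj"))
    stop_fmt("unsupported mesh extension '.%s' (use off or obj)", ext)
  vid <- mesh$vertices
  remap <- integer(nrow(mesh$points))
  remap[vid] <- seq_along(vid)
  v <- mesh$points[vid, , drop = FALSE]
  f <- matrix(remap[mesh$facets], ncol = 3)
  lines <- if (ext == "off") {
    c("OFF",
      sprintf("%d %d 0", nrow(v), nrow(f)),
      sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else {
    c(sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a triangulated surface from OFF or OBJ
#'
#' @param path path to a `.off` or `.obj` file.
#' @return list with `vertices` (n x 3 matrix) and 1-based `facets`
#'   (m x 3 matrix).
#' @export
import_mesh <- function(path) {
  if (!file.exists(path)) stop_fmt("cannot read mesh file: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "off") {
    if (!startsWith(trimws(lines[1]), "OFF"))
      stop_fmt("'%s' is not an OFF file", path)
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    v <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind,
                 lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]),
                                 "\\s+"),
                        function(x) as.integer(x[2:4]) + 1L))
  } else if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[1:3]))))
  } else {
    stop_fmt("unsupported mesh extension '.%s' (use off or obj)", ext)
  }
  list(vertices = v, facets = f)
}
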