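# Mesh and field I/O: VTK legacy ASCII unstructured grids (biquadratic
# quads, VTK cell type 28, whose node ordering matches the local ordering
# used here) and a minimal Abaqus-style .inp reader for *NODE / *ELEMENT
# blocks.

#' Write a mesh (and optional point data) as a legacy VTK file
#'
#' @param mesh an `fe_mesh`.
#' @param file output path.
#' @param point_data named list of per-node numeric vectors written as
#'   `POINT_DATA` scalars.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aaastress mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * 10L), con)
  writeLines(apply(mesh$elems - 1L, 1, function(r) {
    paste(c(9L, r), collapse = " ")
  }), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("28", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.12g", point_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Read a legacy VTK unstructured grid of biquadratic quads
#'
#' Restores nodes, elements and the `region` cell field; boundary sets are
#' not stored in VTK files and come back empty.
#'
#' @param file a file written by [write_vtk()] (or compatible).
#' @return an `fe_mesh` (empty boundary sets).
#' @export
read_vtk <- function(file) {
  ln <- readLines(file)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + n)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  }))
  ic <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  elems <- do.call(rbind, lapply(ln[(ic + 1):(ic + ne)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 9L) stop("only 9-node biquadratic quads are supported")
    v[-1] + 1L
  }))
  region <- rep("wall", ne)
  ir <- grep("^SCALARS region", ln)
  if (length(ir)) {
    vals <- as.integer(ln[(ir[1] + 2):(ir[1] + 1 + ne)])
    region <- c("thrombus", "wall")[vals]  # factor order is alphabetical
    if (length(unique(vals)) == 1L) region <- rep("wall", ne)
  }
  .new_mesh(pts[, 1:2, drop = FALSE], elems, region,
            sets = list(lumen_edges = matrix(integer(0), 0, 3),
                        fix_z = integer(0), fix_x = integer(0)))
}

#' Read node/element blocks from an Abaqus-style .inp file
#'
#' Minimal reader: the first `*NODE` block (id, x, y) and all `*ELEMENT`
#' blocks of 9-node elements. Element set names (`ELSET=`) become regions
#' (`wall` when absent).
#'
#' @param file path to the .inp file.
#' @return an `fe_mesh` (empty boundary sets).
#' @export
read_inp <- function(file) {
  ln <- trimws(readLines(file))
  ln <- ln[nzchar(ln) & !startsWith(ln, "**")]
  up <- toupper(ln)
  starts <- grep("^\\*", up)
  bounds <- c(starts, length(ln) + 1L)
  nodes <- NULL; elems <- list(); regions <- list()
  for (i in seq_along(starts)) {
    head <- up[starts[i]]
    body <- ln[seq(starts[i] + 1L, bounds[i + 1L] - 1L)]
    if (!length(body)) next
    if (startsWith(head, "*NODE") && is.null(nodes)) {
      m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
      nodes <- m[order(m[, 1]), 2:3, drop = FALSE]
    } else if (startsWith(head, "*ELEMENT")) {
      reg <- sub(".*ELSET=([^,]+).*", "\\1", head)
      if (reg == head) reg <- "wall"
      m <- do.call(rbind, lapply(strsplit(body, ","), as.integer))
      if (ncol(m) != 10L) stop("only 9-node elements are supported")
      elems[[length(elems) + 1L]] <- m[, -1, drop = FALSE]
      regions[[length(regions) + 1L]] <- rep(tolower(reg), nrow(m))
    }
  }
  if (is.null(nodes) || !length(elems)) stop("no *NODE/*ELEMENT blocks found")
  .new_mesh(nodes, do.call(rbind, elems), unlist(regions),
            sets = list(lumen_edges = matrix(integer(0), 0, 3),
                        fix_z = integer(0), fix_x = integer(0)))
}
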