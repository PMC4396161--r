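#' Write a mesh as Gmsh MSH v2.2 ASCII
#'
#' Nodes are written with a zero z-coordinate; triangles as element type 2
#' with physical/elementary tags 0, and boundary edges as element type 1
#' with physical tag 1 (the cell membrane).
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nd <- mesh$nodes; tr <- mesh$triangles; be <- mesh$boundary_edges
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(nd))), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nrow(nd)),
                     nd[, 1L], nd[, 2L]), con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(be) + nrow(tr))), con)
  if (nrow(be) > 0L) {
    writeLines(sprintf("%d 1 2 1 1 %d %d", seq_len(nrow(be)),
                       be[, 1L], be[, 2L]), con)
  }
  writeLines(sprintf("%d 2 2 0 0 %d %d %d", nrow(be) + seq_len(nrow(tr)),
                     tr[, 1L], tr[, 2L], tr[, 3L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2.2 ASCII mesh
#'
#' Parses `$Nodes` and `$Elements`; triangles (element type 2) become the
#' triangulation, line elements (type 1) are ignored (the boundary is
#' re-derived from the triangulation). Malformed files raise an error
#' naming the offending section.
#'
#' @param path file path.
#' @return A `triangle_mesh`.
#' @export
read_msh <- function(path) {
  if (!file.exists(path)) stop("read_msh: no such file: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i0 <- match(paste0("$", name), ln)
    i1 <- match(paste0("$End", name), ln)
    if (is.na(i0) || is.na(i1) || i1 <= i0) {
      stop("read_msh: missing or malformed $", name, " section", call. = FALSE)
    }
    ln[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  ver <- strsplit(trimws(fmt[1L]), "\\s+")[[1L]][1L]
  if (!startsWith(ver, "2.2")) {
    stop("read_msh: unsupported MSH version '", ver, "' in $MeshFormat",
         call. = FALSE)
  }
  nl <- sec("Nodes")
  nn <- suppressWarnings(as.integer(nl[1L]))
  if (is.na(nn) || length(nl) != nn + 1L) {
    stop("read_msh: node count mismatch in $Nodes", call. = FALSE)
  }
  ntab <- matrix(suppressWarnings(as.numeric(
    unlist(strsplit(trimws(nl[-1L]), "\\s+")))), ncol = 4L, byrow = TRUE)
  if (any(!is.finite(ntab))) stop("read_msh: bad node line in $Nodes", call. = FALSE)
  ord <- order(ntab[, 1L])
  nodes <- ntab[ord, 2:3, drop = FALSE]
  remap <- integer(max(ntab[, 1L]))
  remap[as.integer(ntab[ord, 1L])] <- seq_len(nn)

  el <- sec("Elements")
  ne <- suppressWarnings(as.integer(el[1L]))
  if (is.na(ne) || length(el) != ne + 1L) {
    stop("read_msh: element count mismatch in $Elements", call. = FALSE)
  }
  tris <- list()
  for (line in el[-1L]) {
    v <- suppressWarnings(as.integer(strsplit(trimws(line), "\\s+")[[1L]]))
    if (length(v) < 3L || any(is.na(v))) {
      stop("read_msh: bad element line in $Elements", call. = FALSE)
    }
    etype <- v[2L]; ntags <- v[3L]
    conn <- v[-(1:(3L + ntags))]
    if (etype == 2L) {
      if (length(conn) != 3L) stop("read_msh: triangle with wrong node count in $Elements", call. = FALSE)
      tris[[length(tris) + 1L]] <- remap[conn]
    }
  }
  if (length(tris) == 0L) {
    stop("read_msh: no triangles found in $Elements", call. = FALSE)
  }
  triangle_mesh(nodes, do.call(rbind, tris))
}
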