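#' Write a field snapshot (legacy VTK ASCII or CSV point cloud)
#'
#' VTK format: an `UNSTRUCTURED_GRID` with the mesh triangles, a `TIME`
#' field-data entry, and point-data scalars named `phi` and `C1`..`C6`.
#' CSV format: one row per node with columns `x, y, phi, C1..C6` and the
#' time in a comment header.
#'
#' @param state a `system_state` (see [initial_state()]).
#' @param mesh the `triangle_mesh` the state lives on.
#' @param path output file path.
#' @param format `"vtk"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, mesh, path, format = c("vtk", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(state, "system_state"), inherits(mesh, "triangle_mesh"))
  fields <- c(list(phi = state$phi),
              stats::setNames(lapply(1:6, function(i) state$C[, i]),
                              paste0("C", 1:6)))
  if (format == "vtk") {
    write_vtk(mesh, fields, path, time = state$t)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# t = %.17g s; units: phi mV, C uM", state$t), con)
    df <- data.frame(x = mesh$nodes[, 1L], y = mesh$nodes[, 2L])
    for (nm in names(fields)) df[[nm]] <- fields[[nm]]
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}

#' Write nodal fields on a triangle mesh as legacy VTK ASCII
#'
#' @param mesh a `triangle_mesh`.
#' @param fields named list of nodal vectors.
#' @param path output file path.
#' @param time simulation time stored as VTK field data (default 0).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, fields, path, time = 0) {
  stopifnot(inherits(mesh, "triangle_mesh"), is.list(fields),
            length(names(fields)) == length(fields))
  nd <- mesh$nodes; tr <- mesh$triangles
  n <- nrow(nd); m <- nrow(tr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("npcable snapshot t=%.17g", time),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               "FIELD FieldData 1", "TIME 1 1 double",
               sprintf("%.17g", time),
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g 0", nd[, 1L], nd[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L,
                     tr[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) != n) stop("write_vtk: field '", nm, "' has wrong length", call. = FALSE)
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 sprintf("%.17g", v)), con)
  }
  invisible(path)
}

#' Read a legacy VTK ASCII snapshot written by [write_vtk()]
#'
#' @param path file path.
#' @return A list with `nodes`, `triangles`, `time` and `fields`
#'   (named list of nodal vectors).
#' @export
read_vtk <- function(path) {
  if (!file.exists(path)) stop("read_vtk: no such file: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS ", ln)
  if (length(ip) != 1L) stop("read_vtk: missing POINTS section", call. = FALSE)
  n <- as.integer(strsplit(ln[ip], "\\s+")[[1L]][2L])
  pts <- matrix(as.numeric(unlist(strsplit(trimws(ln[ip + seq_len(n)]), "\\s+"))),
                ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS ", ln)
  if (length(ic) != 1L) stop("read_vtk: missing CELLS section", call. = FALSE)
  m <- as.integer(strsplit(ln[ic], "\\s+")[[1L]][2L])
  cl <- matrix(as.integer(unlist(strsplit(trimws(ln[ic + seq_len(m)]), "\\s+"))),
               ncol = 4L, byrow = TRUE)
  tr <- cl[, 2:4, drop = FALSE] + 1L
  it <- grep("^TIME 1 1 double", ln)
  time <- if (length(it) == 1L) as.numeric(ln[it + 1L]) else NA_real_
  isc <- grep("^SCALARS ", ln)
  fields <- list()
  for (i in isc) {
    nm <- strsplit(ln[i], "\\s+")[[1L]][2L]
    fields[[nm]] <- as.numeric(ln[i + 1L + seq_len(n)])
  }
  list(nodes = pts[, 1:2, drop = FALSE], triangles = tr,
       time = time, fields = fields)
}

#' Write a probe time series as CSV
#'
#' One file per probe with a header comment giving the probe location,
#' the sampled (nearest) node and model units; columns
#' `t, phi, C1..C6` with a monotone time column.
#'
#' @param run an `npcable_run` from [run_simulation()].
#' @param path output path for the first probe; additional probes get
#'   `_2`, `_3`, ... suffixes before the extension.
#' @return Character vector of written paths, invisibly.
#' @export
write_probe_csv <- function(run, path) {
  stopifnot(inherits(run, "npcable_run"))
  paths <- character(length(run$probes))
  for (i in seq_along(run$probes)) {
    p <- if (i == 1L) path else
      sub("(\\.[^.]*)?$", sprintf("_%d\\1", i), path)
    con <- file(p, "w")
    pt <- run$config$output$probes[[i]]
    writeLines(sprintf("# probe at (%g, %g), node %d; t s, phi mV, C uM",
                       pt[1L], pt[2L], run$probe_nodes[i]), con)
    utils::write.csv(run$probes[[i]], con, row.names = FALSE)
    close(con)
    paths[i] <- p
  }
  invisible(paths)
}

#' Reproducibility manifest of a run
#'
#' Everything needed to reproduce the run bit-exactly: the configuration
#' (plus its MD5 hash as serialised YAML), achieved mesh size, node/step
#' counts and the package version. The pipeline is fully deterministic
#' (the mesher and solver contain no randomness); the config's `seed`
#' field is recorded for future stochastic extensions.
#'
#' @param run an `npcable_run`.
#' @param path optional path to also write the manifest as JSON.
#' @return The manifest list, invisibly when `path` is given.
#' @export
run_manifest <- function(run, path = NULL) {
  stopifnot(inherits(run, "npcable_run"))
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(run$config), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  man <- list(package = "npcable",
              version = as.character(utils::packageVersion("npcable")),
              config = unclass(run$config),
              config_md5 = hash,
              h_achieved = run$summary$h_achieved,
              nodes = run$summary$nodes,
              steps = run$summary$steps,
              seed = run$config$seed,
              deterministic = TRUE)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
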