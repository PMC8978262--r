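#' Read a tetrahedral mesh from a legacy VTK unstructured-grid file
#'
#' Accepts legacy ASCII VTK files (`DATASET UNSTRUCTURED_GRID`) whose cells
#' are all tetrahedra (VTK cell type 10) with an integer per-cell region
#' array under `CELL_DATA`. Coordinates declared in cm are converted to the
#' package's canonical mm at read time.
#'
#' @param path file path.
#' @param unit unit the coordinates are expressed in, `"mm"` (default) or
#'   `"cm"`.
#' @param region_array name of the per-cell integer region array
#'   (default `"region"`).
#' @return a [tetra_mesh()]; any further `CELL_DATA` arrays are attached as
#'   attribute `cell_arrays` (named list of numeric vectors).
#' @export
read_tetra_mesh_vtk <- function(path, unit = c("mm", "cm"),
                                region_array = "region") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- .vtk_tokens(lines)

  dataset_i <- which(toupper(toks) == "DATASET")
  if (length(dataset_i) == 0L || toupper(toks[dataset_i[1L] + 1L]) != "UNSTRUCTURED_GRID")
    stop("not a legacy VTK unstructured grid (DATASET UNSTRUCTURED_GRID)")

  pi_ <- which(toupper(toks) == "POINTS")[1L]
  if (is.na(pi_)) stop("VTK file has no POINTS block")
  n_pts <- as.integer(toks[pi_ + 1L])
  coords <- as.numeric(toks[(pi_ + 3L):(pi_ + 2L + 3L * n_pts)])
  verts <- matrix(coords, ncol = 3L, byrow = TRUE)
  if (unit == "cm") verts <- verts * 10

  ci <- which(toupper(toks) == "CELLS")[1L]
  if (is.na(ci)) stop("VTK file has no CELLS block")
  n_cells <- as.integer(toks[ci + 1L])
  n_ints <- as.integer(toks[ci + 2L])
  cell_ints <- as.integer(toks[(ci + 3L):(ci + 2L + n_ints)])

  ti <- which(toupper(toks) == "CELL_TYPES")[1L]
  if (is.na(ti)) stop("VTK file has no CELL_TYPES block")
  ctypes <- as.integer(toks[(ti + 2L):(ti + 1L + n_cells)])
  bad <- unique(ctypes[ctypes != 10L])
  if (length(bad) > 0L)
    stop("mesh contains non-tetrahedral cells (VTK cell type ",
         paste(bad, collapse = ", "), "); only type 10 (tetra) is supported")

  # unpack connectivity: each record is "4 v0 v1 v2 v3"
  sizes <- cell_ints[cumsum(c(1L, rep(5L, n_cells - 1L)))]
  if (any(sizes != 4L)) stop("CELLS records must each list 4 vertices")
  conn <- matrix(cell_ints, ncol = 5L, byrow = TRUE)[, 2:5, drop = FALSE] + 1L

  arrays <- .vtk_cell_data(toks, n_cells)
  if (!region_array %in% names(arrays))
    stop("no per-cell region array found; expected a CELL_DATA SCALARS array ",
         "named \"", region_array, "\"")
  region <- as.integer(arrays[[region_array]])
  mesh <- tetra_mesh(verts, conn, region)
  attr(mesh, "cell_arrays") <- arrays[setdiff(names(arrays), region_array)]
  mesh
}

.vtk_tokens <- function(lines) {
  # drop the two header/comment lines' effect by tokenizing everything;
  # the title line may contain arbitrary words, so cut lines 1-2 header
  # conservatively: keep from the first line starting with ASCII/BINARY on.
  fmt_i <- grep("^\\s*(ASCII|BINARY)\\s*$", toupper(lines))[1L]
  if (is.na(fmt_i)) stop("missing ASCII/BINARY format line")
  if (toupper(trimws(lines[fmt_i])) == "BINARY")
    stop("binary VTK files are not supported; use ASCII")
  unlist(strsplit(trimws(lines[fmt_i:length(lines)]), "\\s+"))
}

.vtk_cell_data <- function(toks, n_cells) {
  out <- list()
  cd <- which(toupper(toks) == "CELL_DATA")[1L]
  if (is.na(cd)) return(out)
  i <- cd + 2L
  while (i <= length(toks)) {
    if (toupper(toks[i]) == "SCALARS") {
      nm <- toks[i + 1L]
      # optional numComp token then LOOKUP_TABLE <name>
      j <- i + 3L
      while (j <= length(toks) && toupper(toks[j]) != "LOOKUP_TABLE") j <- j + 1L
      vals <- as.numeric(toks[(j + 2L):(j + 1L + n_cells)])
      out[[nm]] <- vals
      i <- j + 2L + n_cells
    } else if (toupper(toks[i]) == "POINT_DATA") {
      break
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write a mesh and per-tet arrays to a legacy VTK file
#'
#' Writes legacy ASCII VTK (`DATASET UNSTRUCTURED_GRID`) with the mesh
#' geometry and the given per-tet `CELL_DATA` arrays. The `region` array is
#' written as int, everything else as double with full precision, so a
#' read/write round trip recovers the values.
#'
#' @param mesh a [tetra_mesh()].
#' @param cell_arrays named list of per-tet numeric vectors (for example
#'   `fluence`); the mesh region is always written as array `"region"`.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_fluence_vtk <- function(mesh, cell_arrays = list(), path) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  n_tet <- nrow(mesh$tets)
  if (length(cell_arrays) > 0L) {
    if (is.null(names(cell_arrays)) || any(names(cell_arrays) == ""))
      stop("cell_arrays must be a named list")
    len <- vapply(cell_arrays, length, integer(1L))
    if (any(len != n_tet))
      stop("cell array length mismatch: expected ", n_tet, ", got ",
           paste(unique(len[len != n_tet]), collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "tetramc mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", nrow(mesh$vertices)))
  wl(apply(mesh$vertices, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")))
  wl(sprintf("CELLS %d %d", n_tet, 5L * n_tet))
  wl(apply(mesh$tets - 1L, 1L, function(r) paste(c(4L, r), collapse = " ")))
  wl(sprintf("CELL_TYPES %d", n_tet))
  wl(as.character(rep(10L, n_tet)))
  wl(sprintf("CELL_DATA %d", n_tet))
  wl("SCALARS region int 1", "LOOKUP_TABLE default")
  wl(as.character(mesh$region))
  for (nm in names(cell_arrays)) {
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    wl(sprintf("%.17g", as.numeric(cell_arrays[[nm]])))
  }
  invisible(path)
}
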