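#' Cell lattices
#'
#' The model tissue is a static lattice of cells: a one-dimensional chain
#' (used for front/pulse profiles), a rectangular patch of a hexagonal lattice
#' (mimicking the neuroepithelial sheet), or a hexagonal disc (circular tissue
#' geometry). All lattices use unit spacing between adjacent cell centres and
#' no-flux boundaries: boundary cells simply have fewer neighbours, so the
#' discrete diffusion operator conserves total mass.
#'
#' Internally hexagonal lattices use axial coordinates converted to Cartesian
#' cell centres; the wave axis is the x axis and `col` holds the integer
#' column index used for wavefront tracking. Discs additionally carry each
#' cell's distance (`radius`) and counter-clockwise polar angle (`angle`, in
#' `[0, 2*pi)`) from the disc centre, used for angular-sector initial
#' conditions.
#'
#' @name cell_lattice
NULL

new_cell_lattice <- function(kind, coords, col, neighbors,
                             radius = NULL, angle = NULL) {
  n <- nrow(coords)
  stopifnot(length(neighbors) == n, length(col) == n)
  deg <- lengths(neighbors)
  structure(list(
    n_cells = n,
    kind = kind,
    boundary = "no_flux",
    coords = coords,
    col = as.integer(col),
    radius = radius,
    angle = angle,
    neighbors = neighbors,
    degree = as.integer(deg),
    lap_coef = if (kind == "chain_1d") 1 else 2 / 3
  ), class = "cell_lattice")
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat(sprintf("<cell_lattice> kind = %s, %d cells, %d undirected edges\n",
              x$kind, x$n_cells, sum(x$degree) %/% 2L))
  invisible(x)
}

# neighbor lists from Cartesian centres: adjacent iff distance ~ 1
neighbors_from_coords <- function(coords, tol = 1e-6) {
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))
  lapply(seq_len(n), function(i)
    as.integer(unname(which(abs(d2[i, ] - 1) < tol))))
}

#' Build a one-dimensional chain of cells
#'
#' @param n Number of cells (>= 2); unit spacing, no-flux ends.
#' @return A `cell_lattice` of kind `"chain_1d"`.
#' @export
build_chain <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("build_chain: need n >= 2 cells")
  coords <- data.frame(x = as.numeric(seq_len(n) - 1L), y = 0)
  nb <- lapply(seq_len(n), function(i) {
    c(if (i > 1L) i - 1L, if (i < n) i + 1L)
  })
  new_cell_lattice("chain_1d", coords, col = seq_len(n) - 1L, neighbors = nb)
}

#' Build a rectangular patch of a hexagonal lattice
#'
#' Pointy-top hexagonal packing in "odd-r" offset layout: row `r` is shifted
#' by half a cell spacing for odd `r`. Columns (constant `col`) are stacks of
#' cells along y; the wave axis runs along increasing column index.
#'
#' @param n_cols,n_rows Patch dimensions in cells (each >= 2).
#' @return A `cell_lattice` of kind `"hex_rect"`.
#' @export
build_hex_rect <- function(n_cols, n_rows) {
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || is.na(n_rows) || n_cols < 2L || n_rows < 2L)
    stop("build_hex_rect: need n_cols >= 2 and n_rows >= 2")
  g <- expand.grid(q = seq_len(n_cols) - 1L, r = seq_len(n_rows) - 1L)
  coords <- data.frame(x = g$q + 0.5 * (g$r %% 2L), y = g$r * sqrt(3) / 2)
  nb <- neighbors_from_coords(coords)
  new_cell_lattice("hex_rect", coords, col = g$q, neighbors = nb)
}

#' Build a hexagonal disc
#'
#' Contains every hexagonal-lattice cell whose centre lies within Euclidean
#' distance `radius` (in units of the cell spacing) of the central cell.
#' `build_hex_disc(1)` is the central cell plus its 6 neighbours.
#'
#' @param radius Disc radius in lattice units (>= 1).
#' @return A `cell_lattice` of kind `"hex_disc"` with per-cell `radius` and
#'   polar `angle` fields.
#' @export
build_hex_disc <- function(radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L)
  if (!is.finite(radius) || radius < 1) stop("build_hex_disc: need radius >= 1")
  # axial ranges covering the disc: |r| <= 2R/sqrt(3), |q| <= R(1 + 1/sqrt(3))
  mr <- ceiling(2 * radius / sqrt(3)) + 1L
  mq <- ceiling(radius * (1 + 1 / sqrt(3))) + 1L
  g <- expand.grid(q = -mq:mq, r = -mr:mr)
  # axial -> Cartesian, unit spacing
  x <- g$q + g$r / 2
  y <- g$r * sqrt(3) / 2
  dist <- sqrt(x^2 + y^2)
  keep <- dist <= radius + 1e-9
  coords <- data.frame(x = x[keep], y = y[keep])
  ang <- atan2(coords$y, coords$x) %% (2 * pi)
  nb <- neighbors_from_coords(coords)
  new_cell_lattice("hex_disc", coords, col = round(coords$x), neighbors = nb,
                   radius = dist[keep], angle = ang)
}

#' Sparse discrete Laplacian of a lattice
#'
#' Matrix `L` with `(L f)_i = c * sum_{j ~ i} (f_j - f_i)`, where `c = 1` on
#' chains and `c = 2/3` on hexagonal lattices so that the stencil matches the
#' continuum Laplacian at unit spacing. No-flux boundaries arise from the
#' missing neighbours of edge cells.
#'
#' @param lattice A `cell_lattice`.
#' @return A sparse symmetric `Matrix` of dimension `n_cells x n_cells`.
#' @export
laplacian_matrix <- function(lattice) {
  stopifnot(inherits(lattice, "cell_lattice"))
  n <- lattice$n_cells
  i <- rep.int(seq_len(n), lattice$degree)
  j <- unlist(lattice$neighbors, use.names = FALSE)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  lattice$lap_coef * (A - Matrix::Diagonal(n, lattice$degree))
}

#' Apply the discrete Laplacian to a per-cell field
#'
#' @param field Numeric vector of length `n_cells`.
#' @param lattice A `cell_lattice`.
#' @return Numeric vector of the same length.
#' @export
laplacian <- function(field, lattice) {
  stopifnot(inherits(lattice, "cell_lattice"))
  if (length(field) != lattice$n_cells)
    stop("laplacian: field length does not match lattice size")
  as.numeric(laplacian_matrix(lattice) %*% field)
}

#' Neighbour-averaging operator
#'
#' Row-stochastic sparse matrix `M` with `(M f)_i` the arithmetic mean of `f`
#' over the neighbours of cell `i`; realises the trans (juxtacrine) coupling
#' of Delta-Notch signalling, where a cell senses the Delta presented by its
#' contacting neighbours.
#'
#' @param lattice A `cell_lattice`; every cell must have at least 1 neighbour.
#' @return A sparse `Matrix`.
#' @export
neighbor_mean_matrix <- function(lattice) {
  stopifnot(inherits(lattice, "cell_lattice"))
  if (any(lattice$degree == 0L))
    stop("neighbor_mean_matrix: lattice contains isolated cells")
  n <- lattice$n_cells
  i <- rep.int(seq_len(n), lattice$degree)
  j <- unlist(lattice$neighbors, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / lattice$degree[i], dims = c(n, n))
}

#' Mean of a field over each cell's neighbours
#'
#' @inheritParams laplacian
#' @return Numeric vector of per-cell neighbour means.
#' @export
neighbor_mean <- function(field, lattice) {
  stopifnot(inherits(lattice, "cell_lattice"))
  if (length(field) != lattice$n_cells)
    stop("neighbor_mean: field length does not match lattice size")
  as.numeric(neighbor_mean_matrix(lattice) %*% field)
}

#' Write / read a lattice as plain-text tables
#'
#' Serialises a lattice to a coordinate table (`cell_id`, `x`, `y`, `col`)
#' and an undirected edge list (`from`, `to`), both as tab-separated files
#' under `path` (a directory, created if needed).
#'
#' @param lattice A `cell_lattice`.
#' @param path Output directory.
#' @return `write_lattice` returns `path` invisibly; `read_lattice` a
#'   `cell_lattice`.
#' @export
write_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "cell_lattice"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cells <- data.frame(cell_id = seq_len(lattice$n_cells),
                      x = lattice$coords$x, y = lattice$coords$y,
                      col = lattice$col)
  if (!is.null(lattice$radius)) {
    cells$radius <- lattice$radius
    cells$angle <- lattice$angle
  }
  edges <- do.call(rbind, lapply(seq_len(lattice$n_cells), function(i) {
    js <- lattice$neighbors[[i]]
    js <- js[js > i]
    if (length(js)) data.frame(from = i, to = js) else NULL
  }))
  utils::write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(edges, file.path(path, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("kind: ", lattice$kind), "boundary: no_flux"),
             file.path(path, "lattice.yaml"))
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "lattice.yaml"))
  cells <- utils::read.delim(file.path(path, "cells.tsv"))
  edges <- utils::read.delim(file.path(path, "edges.tsv"))
  n <- nrow(cells)
  nb <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, function(v) sort(as.integer(v)))
  new_cell_lattice(meta$kind,
                   data.frame(x = cells$x, y = cells$y),
                   col = cells$col, neighbors = nb,
                   radius = cells$radius, angle = cells$angle)
}
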