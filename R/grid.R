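#' Single-band raster grid
#'
#' Lightweight in-memory raster: a numeric matrix plus a geotransform
#' (upper-left corner, square cell size). Row 1 is the northernmost row;
#' missing cells are `NA`. Two grids are *aligned* iff origin, cell size and
#' shape all match, which is what every multi-layer operation in the package
#' requires.
#'
#' @param values numeric matrix (rows = north to south).
#' @param origin_x,origin_y coordinates of the upper-left corner of the grid.
#'   Defaults place the lower-left corner at (0, 0).
#' @param cell_size positive cell edge length, in the map unit (km throughout
#'   the package).
#' @param nodata sentinel used when writing to disk; in memory missing cells
#'   are always `NA`.
#' @return an object of class `podo_grid`.
#' @export
grid_create <- function(values, origin_x = 0, origin_y = NULL, cell_size = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (is.null(origin_y)) origin_y <- nrow(values) * cell_size
  g <- structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, nodata = nodata),
    class = "podo_grid")
  g
}

#' @export
print.podo_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("podo_grid: %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin_x, x$origin_y))
  cat(sprintf("  values: [%s, %s], %d NA\n",
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

is_grid <- function(x) inherits(x, "podo_grid")

#' Test whether two grids share origin, cell size and shape
#' @param a,b grids.
#' @return logical.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(is_grid(a), is_grid(b))
  isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    all(dim(a$values) == dim(b$values))
}

grid_extent <- function(g) {
  c(xmin = g$origin_x,
    xmax = g$origin_x + ncol(g$values) * g$cell_size,
    ymin = g$origin_y - nrow(g$values) * g$cell_size,
    ymax = g$origin_y)
}

## cell centres of every cell, as vectors recycled over the matrix layout
grid_cell_centres <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(x = g$origin_x + (seq_len(nc) - 0.5) * g$cell_size,
       y = g$origin_y - (seq_len(nr) - 0.5) * g$cell_size)
}

## half-open cell membership: [x0, x0 + cs) horizontally, (y0 - cs, y0]
## mapped so a point exactly on an interior boundary belongs to the
## right/lower cell. Returns row/col, NA when outside the extent.
point_to_cell <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell_size) + 1L
  row <- floor((g$origin_y - y) / g$cell_size) + 1L
  ## the top edge belongs to row 1, the left edge to col 1
  row[(g$origin_y - y) == 0] <- 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  ## points exactly on the bottom/right outer edge are inside by convention
  on_right <- x == g$origin_x + ncol(g$values) * g$cell_size
  on_bottom <- y == g$origin_y - nrow(g$values) * g$cell_size
  col[on_right] <- ncol(g$values)
  row[on_bottom] <- nrow(g$values)
  bad <- (col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values))
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Nearest-neighbour alignment of a grid onto a template geometry
#'
#' Each output cell takes the value of the source cell whose centre is
#' nearest to the output cell centre. Output cells whose centres fall outside
#' the source extent are `NA`; source `NA` propagates.
#'
#' @param source grid to resample.
#' @param template grid providing the target origin, cell size and shape.
#' @return a grid aligned to `template`.
#' @export
align_nearest <- function(source, template) {
  stopifnot(is_grid(source), is_grid(template))
  if (length(source$values) == 0L) stop("empty source grid")
  es <- grid_extent(source); et <- grid_extent(template)
  if (es["xmin"] >= et["xmax"] || es["xmax"] <= et["xmin"] ||
      es["ymin"] >= et["ymax"] || es["ymax"] <= et["ymin"])
    stop(sprintf(
      "source extent [%g,%g]x[%g,%g] does not overlap template extent [%g,%g]x[%g,%g]",
      es["xmin"], es["xmax"], es["ymin"], es["ymax"],
      et["xmin"], et["xmax"], et["ymin"], et["ymax"]))
  cc <- grid_cell_centres(template)
  ## nearest source cell centre = rounding the fractional index
  ci <- round((cc$x - source$origin_x) / source$cell_size + 0.5)
  ri <- round((source$origin_y - cc$y) / source$cell_size + 0.5)
  ci[ci < 1 | ci > ncol(source$values)] <- NA
  ri[ri < 1 | ri > nrow(source$values)] <- NA
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  ok_r <- which(!is.na(ri)); ok_c <- which(!is.na(ci))
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c] <- source$values[ri[ok_r], ci[ok_c], drop = FALSE]
  grid_create(out, template$origin_x, template$origin_y, template$cell_size,
              template$nodata)
}

## 1-D squared Euclidean distance transform (lower envelope of parabolas),
## Felzenszwalb & Huttenlocher. f is a vector of initial squared distances.
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    vk <- v[k]
    d[q] <- (q - vk)^2 + f[vk]
  }
  d
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact distance transform: every cell receives the straight-line distance
#' from its centre to the nearest feature-cell centre, in the map unit
#' (km when `cell_size` is in km). Feature cells get 0. Uses the
#' two-pass lower-envelope algorithm, so it is exact and O(cells).
#'
#' @param mask binary grid: non-zero = feature (e.g. water body), 0 =
#'   background. `NA` cells are background for distance purposes and stay
#'   `NA` in the output.
#' @return grid of distances.
#' @export
distance_to_features <- function(mask) {
  stopifnot(is_grid(mask))
  v <- mask$values
  feat <- !is.na(v) & v != 0
  if (!any(feat)) stop("mask contains no feature cells")
  nr <- nrow(v); nc <- ncol(v)
  ## finite sentinel far above any attainable squared cell distance keeps the
  ## parabola intersections finite; it can never win because >=1 feature exists
  big <- 4 * (nr + nc)^2 + 1e6
  f <- matrix(big, nr, nc)
  f[feat] <- 0
  ## columns then rows
  for (j in seq_len(nc)) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt1d(f[i, ])
  out <- sqrt(f) * mask$cell_size
  out[is.na(v)] <- NA_real_
  grid_create(out, mask$origin_x, mask$origin_y, mask$cell_size, mask$nodata)
}

## D8 neighbour scan order: clockwise starting from east (row grows south).
d8_offsets <- function() {
  list(dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
       dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))
}

#' D8 flow direction from a digital elevation model
#'
#' Assigns each cell the direction of steepest descent among its 8
#' neighbours, with slope measured as elevation drop / distance * 100
#' (distance = cell size, or cell size * sqrt(2) diagonally). Ties are broken
#' by the fixed clockwise-from-east scan order (E, SE, S, SW, W, NW, N, NE,
#' coded 1-8); a cell with no strictly lower neighbour is a sink (code 0).
#' `NA` elevations propagate: a cell that is `NA` or touches an `NA`
#' neighbour gets `NA`.
#'
#' @param dem elevation grid.
#' @return grid of direction codes (0 = sink, 1-8 = E..NE clockwise).
#' @export
flow_direction <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  off <- d8_offsets()
  dist <- dem$cell_size * c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) { out[i, j] <- NA_real_; next }
    best <- 0; bestdir <- 0L; touched_na <- FALSE
    for (k in 1:8) {
      ii <- i + off$dr[k]; jj <- j + off$dc[k]
      if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
      zn <- z[ii, jj]
      if (is.na(zn)) { touched_na <- TRUE; break }
      slope <- (z[i, j] - zn) / dist[k] * 100
      if (slope > best) { best <- slope; bestdir <- k }
    }
    out[i, j] <- if (touched_na) NA_real_ else bestdir
  }
  grid_create(out, dem$origin_x, dem$origin_y, dem$cell_size, dem$nodata)
}

#' D8 flow accumulation
#'
#' Counts, for every cell, the number of upstream cells whose flow path
#' reaches it (the cell itself excluded). Directions pointing at `NA` cells
#' drain nowhere; `NA` direction cells stay `NA`.
#'
#' @param flowdir direction grid from [flow_direction()].
#' @return grid of upstream cell counts.
#' @export
flow_accumulation <- function(flowdir) {
  stopifnot(is_grid(flowdir))
  fd <- flowdir$values
  nr <- nrow(fd); nc <- ncol(fd)
  n <- nr * nc
  off <- d8_offsets()
  ## target index (column-major linear) of each cell, NA if sink/none
  idx <- seq_len(n)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  code <- as.integer(fd)
  target <- rep(NA_integer_, n)
  flows <- which(!is.na(code) & code >= 1L)
  if (length(flows)) {
    k <- code[flows]
    tr <- ri[flows] + off$dr[k]; tc <- ci[flows] + off$dc[k]
    bad <- tr < 1L | tr > nr | tc < 1L | tc > nc
    if (any(bad)) stop("flow direction points outside the grid")
    tl <- (tc - 1L) * nr + tr
    tl[is.na(fd[cbind(tr, tc)])] <- NA_integer_  # draining into nodata: dropped
    target[flows] <- tl
  }
  acc <- rep(0, n)
  indeg <- tabulate(target[!is.na(target)], nbins = n)
  queue <- which(indeg == 0L & !is.na(code))
  processed <- 0L
  head <- 1L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    cell <- queue[head]; head <- head + 1L
    processed <- processed + 1L
    tgt <- target[cell]
    if (!is.na(tgt)) {
      acc[tgt] <- acc[tgt] + acc[cell] + 1
      indeg[tgt] <- indeg[tgt] - 1L
      if (indeg[tgt] == 0L) queue <- c(queue, tgt)
    }
  }
  if (processed < sum(!is.na(code)))
    stop("cycle detected in flow-direction graph; input is corrupted")
  out <- matrix(acc, nr, nc)
  out[is.na(fd)] <- NA_real_
  grid_create(out, flowdir$origin_x, flowdir$origin_y, flowdir$cell_size,
              flowdir$nodata)
}

#' Ordered collection of aligned grids
#'
#' @param grids list of grids, all pairwise aligned.
#' @param names unique covariate names; defaults to the list names.
#' @return an object of class `podo_stack`.
#' @export
grid_stack <- function(grids, names = base::names(grids)) {
  stopifnot(is.list(grids), length(grids) >= 1L)
  if (is.null(names) || anyNA(names) || any(names == ""))
    stop("every grid in a stack must be named")
  if (anyDuplicated(names)) stop("stack names must be unique")
  for (g in grids) stopifnot(is_grid(g))
  for (g in grids[-1L]) if (!grids_aligned(grids[[1L]], g))
    stop("all grids in a stack must be aligned")
  structure(list(grids = stats::setNames(grids, names), names = names),
            class = "podo_stack")
}

#' @export
print.podo_stack <- function(x, ...) {
  g <- x$grids[[1L]]
  cat(sprintf("podo_stack: %d layers (%s), %d x %d cells\n",
              length(x$grids), paste(x$names, collapse = ", "),
              nrow(g$values), ncol(g$values)))
  invisible(x)
}

is_stack <- function(x) inherits(x, "podo_stack")

## all stack values as a cells x layers matrix (column-major cell order)
stack_matrix <- function(stack) {
  vapply(stack$grids, function(g) as.vector(g$values),
         numeric(length(stack$grids[[1L]]$values)))
}

#' Extract covariate values at point locations
#'
#' Looks up the containing cell of every point (half-open cell convention on
#' both axes) and returns its value in each layer. Points in nodata cells
#' yield `NA`.
#'
#' @param stack a [grid_stack()].
#' @param points data.frame with columns `id`, `x`, `y`.
#' @return data.frame with `id`, `x`, `y` and one column per layer.
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(is_stack(stack), is.data.frame(points),
            all(c("x", "y") %in% names(points)))
  if (is.null(points$id)) points$id <- seq_len(nrow(points))
  g <- stack$grids[[1L]]
  rc <- point_to_cell(g, points$x, points$y)
  outside <- is.na(rc$row) | is.na(rc$col)
  if (any(outside))
    stop("points outside grid extent: ",
         paste(points$id[outside], collapse = ", "))
  out <- points[, c("id", "x", "y")]
  for (nm in stack$names)
    out[[nm]] <- stack$grids[[nm]]$values[cbind(rc$row, rc$col)]
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster interchange: a 6-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' from north to south.
#'
#' @param g grid to write.
#' @param path file path (conventionally `.asc`).
#' @return `read_asc` returns a grid; `write_asc` returns `path` invisibly.
#' @export
write_asc <- function(g, path) {
  stopifnot(is_grid(g))
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - nrow(g$values) * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          tolower(vapply(kv, `[`, "", 1L)))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals["nrows"], ncol(m) == vals["ncols"])
  m[m == vals["nodata_value"]] <- NA_real_
  grid_create(m,
              origin_x = unname(vals["xllcorner"]),
              origin_y = unname(vals["yllcorner"] +
                                  vals["nrows"] * vals["cellsize"]),
              cell_size = unname(vals["cellsize"]),
              nodata = unname(vals["nodata_value"]))
}
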