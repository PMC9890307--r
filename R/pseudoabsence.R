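#' Surface range envelope from presence records
#'
#' The envelope brackets, per covariate, the central range of values observed
#' at presence locations (by default the 5th-95th percentiles, linear
#' interpolation between order statistics). Cells outside the envelope on any
#' covariate are presumed unsuitable and become candidates for pseudoabsence
#' sampling.
#'
#' @param presence_values data.frame (or matrix) of covariate values at
#'   presence locations, one column per covariate.
#' @param lo_pct,hi_pct lower/upper percentiles (defaults 5 and 95).
#' @return an object of class `sre_envelope`: named list of `c(lo, hi)`.
#' @export
fit_envelope <- function(presence_values, lo_pct = 5, hi_pct = 95) {
  pv <- as.data.frame(presence_values)
  stopifnot(nrow(pv) >= 2L, ncol(pv) >= 1L,
            lo_pct >= 0, hi_pct <= 100, lo_pct <= hi_pct)
  miss <- which(!stats::complete.cases(pv))
  if (length(miss))
    stop("presence rows with missing covariate values: ",
         paste(miss, collapse = ", "))
  env <- lapply(pv, function(v)
    unname(stats::quantile(v, c(lo_pct, hi_pct) / 100, type = 7)))
  structure(env, class = "sre_envelope",
            lo_pct = lo_pct, hi_pct = hi_pct)
}

#' @export
print.sre_envelope <- function(x, ...) {
  cat(sprintf("surface range envelope (%g-%g percentiles)\n",
              attr(x, "lo_pct"), attr(x, "hi_pct")))
  for (nm in names(x))
    cat(sprintf("  %s: [%g, %g]\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}

#' Classify grid cells against an envelope
#'
#' A cell is inside (1) iff every covariate value lies within its envelope
#' bounds; otherwise outside (0). Cells with any missing covariate are `NA`
#' (excluded from both classes).
#'
#' @param stack covariate [grid_stack()] whose names include every envelope
#'   covariate.
#' @param env an `sre_envelope`.
#' @return binary grid.
#' @export
classify_cells <- function(stack, env) {
  stopifnot(is_stack(stack), inherits(env, "sre_envelope"))
  missing_cov <- setdiff(names(env), stack$names)
  if (length(missing_cov))
    stop("envelope covariates absent from stack: ",
         paste(missing_cov, collapse = ", "))
  tmpl <- stack$grids[[1L]]
  inside <- matrix(TRUE, nrow(tmpl$values), ncol(tmpl$values))
  anyna <- matrix(FALSE, nrow(tmpl$values), ncol(tmpl$values))
  for (nm in names(env)) {
    v <- stack$grids[[nm]]$values
    anyna <- anyna | is.na(v)
    ok <- v >= env[[nm]][1L] & v <= env[[nm]][2L]
    ok[is.na(ok)] <- FALSE
    inside <- inside & ok
  }
  out <- inside * 1
  out[anyna] <- NA_real_
  grid_create(out, tmpl$origin_x, tmpl$origin_y, tmpl$cell_size, tmpl$nodata)
}

#' Draw pseudoabsence point sets from outside the envelope
#'
#' Each set is an independent uniform sample without replacement of
#' outside-envelope cell centres (duplicates across sets are allowed).
#' Surveyed locations can be excluded from candidacy.
#'
#' @param stack covariate stack.
#' @param env an `sre_envelope`.
#' @param n_per_set points per set (default 500).
#' @param n_sets number of sets (default 5).
#' @param seed RNG seed.
#' @param exclude data.frame with `x`, `y` of locations (e.g. surveyed
#'   villages) whose cells are removed from candidacy, or `NULL`.
#' @return list of `n_sets` data.frames with columns `set_id`, `x`, `y`.
#' @export
sample_pseudoabsences <- function(stack, env, n_per_set = 500L, n_sets = 5L,
                                  seed = 1L, exclude = NULL) {
  stopifnot(n_per_set >= 1L, n_sets >= 1L)
  cls <- classify_cells(stack, env)
  v <- cls$values
  outside <- which(!is.na(v) & v == 0)
  if (!is.null(exclude) && nrow(exclude)) {
    rc <- point_to_cell(cls, exclude$x, exclude$y)
    keep <- !is.na(rc$row)
    excl_cells <- (rc$col[keep] - 1L) * nrow(v) + rc$row[keep]
    outside <- setdiff(outside, excl_cells)
  }
  if (length(outside) < n_per_set)
    stop(sprintf(
      "only %d cells outside the envelope; %d required per pseudoabsence set",
      length(outside), n_per_set))
  nr <- nrow(v)
  with_seed(seed, lapply(seq_len(n_sets), function(s) {
    cells <- sample(outside, n_per_set)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    data.frame(set_id = s,
               x = cls$origin_x + (cols - 0.5) * cls$cell_size,
               y = cls$origin_y - (rows - 0.5) * cls$cell_size)
  }))
}
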