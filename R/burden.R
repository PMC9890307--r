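#' Case-count surfaces from prevalence and population
#'
#' Per cell, cases = prevalence x population x adult fraction, applied to the
#' mean and to each uncertainty bound of the prediction surface (prevalence
#' is modelled among adults, so only the adult population contributes).
#'
#' @param prev a `prediction_surface` from [predict_surface()] (already
#'   masked to suitable cells).
#' @param pop all-ages population grid, aligned.
#' @param adult_fraction grid of the adult (>= 15 y) population fraction,
#'   aligned.
#' @return list of grids `mean`, `lower`, `upper`.
#' @export
cases_surface <- function(prev, pop, adult_fraction) {
  stopifnot(inherits(prev, "prediction_surface"), is_grid(pop),
            is_grid(adult_fraction))
  if (!grids_aligned(prev$mean_prev, pop) ||
      !grids_aligned(prev$mean_prev, adult_fraction))
    stop("population / adult-fraction grids are not aligned to the ",
         "prediction surface")
  adults <- pop$values * adult_fraction$values
  mk <- function(pg) grid_create(pg$values * adults, pg$origin_x,
                                 pg$origin_y, pg$cell_size, pg$nodata)
  list(mean = mk(prev$mean_prev), lower = mk(prev$lower95),
       upper = mk(prev$upper95))
}

#' Population living in environmentally suitable cells
#'
#' @param pop all-ages population grid.
#' @param limits binary limits grid, aligned.
#' @param admin optional admin-label grid, aligned; when given, per-unit
#'   totals are returned as well.
#' @return list: `total`, and `by_admin` (data.frame) when `admin` is given.
#' @export
population_at_risk <- function(pop, limits, admin = NULL) {
  stopifnot(is_grid(pop), is_grid(limits))
  if (!grids_aligned(pop, limits)) stop("population and limits grids differ")
  suit <- !is.na(limits$values) & limits$values == 1 & !is.na(pop$values)
  total <- sum(pop$values[suit])
  out <- list(total = total)
  if (!is.null(admin)) {
    if (!grids_aligned(pop, admin)) stop("admin grid is not aligned")
    lab <- admin$values[suit]
    agg <- tapply(pop$values[suit], lab, sum)
    out$by_admin <- data.frame(admin_id = as.integer(names(agg)),
                               population_at_risk = as.numeric(agg))
  }
  out
}

#' Suitable area and national suitable fraction
#'
#' @param limits binary limits grid.
#' @param cell_area area of one cell in square km (default `cell_size^2`).
#' @param admin optional aligned admin-label grid for per-unit areas.
#' @return list: `area_km2`, `fraction_pct` (suitable cells / valid cells,
#'   in percent), and `by_admin` when `admin` is given.
#' @export
suitable_area <- function(limits, cell_area = NULL, admin = NULL) {
  stopifnot(is_grid(limits))
  if (is.null(cell_area)) cell_area <- limits$cell_size^2
  valid <- !is.na(limits$values)
  suit <- valid & limits$values == 1
  out <- list(area_km2 = sum(suit) * cell_area,
              fraction_pct = 100 * sum(suit) / sum(valid))
  if (!is.null(admin)) {
    if (!grids_aligned(limits, admin)) stop("admin grid is not aligned")
    lab <- admin$values[suit]
    agg <- tapply(rep(cell_area, sum(suit)), lab, sum)
    out$by_admin <- data.frame(admin_id = as.integer(names(agg)),
                               suitable_area_km2 = as.numeric(agg))
  }
  out
}

#' Totals row for a burden table
#'
#' Column sums of per-admin burden rows; rounding is left to report time, so
#' totals are exact sums of the (unrounded) rows.
#'
#' @param rows data.frame of per-admin burden rows with numeric columns
#'   `suitable_area_km2`, `population_at_risk`, `cases_mean`, `cases_lower`,
#'   `cases_upper` (missing columns are skipped; `NA` entries are dropped).
#' @return one-row data.frame with `admin_id = "total"` and the column sums.
#' @export
burden_totals <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  num_cols <- intersect(c("suitable_area_km2", "population_at_risk",
                          "cases_mean", "cases_lower", "cases_upper"),
                        names(rows))
  tot <- lapply(rows[num_cols], function(v) sum(v, na.rm = TRUE))
  cbind(data.frame(admin_id = "total"), as.data.frame(tot))
}

#' Aggregate burden by administrative unit
#'
#' Zonal sums of suitable area, population at risk and case surfaces over an
#' admin-label raster, plus a totals row computed by [burden_totals()].
#'
#' @param cases list of grids `mean`, `lower`, `upper` from
#'   [cases_surface()].
#' @param pop all-ages population grid.
#' @param limits binary limits grid.
#' @param admin admin-label grid (integer labels covering every valid cell).
#' @return data.frame of `BurdenRow`s (one per admin unit, labels as
#'   character) with a final `total` row.
#' @export
aggregate_by_admin <- function(cases, pop, limits, admin) {
  stopifnot(is.list(cases), is_grid(pop), is_grid(limits), is_grid(admin))
  for (g in cases) if (!grids_aligned(g, admin))
    stop("case grids are not aligned to the admin grid")
  if (!grids_aligned(pop, admin) || !grids_aligned(limits, admin))
    stop("population / limits grids are not aligned to the admin grid")
  valid <- !is.na(limits$values)
  if (any(is.na(admin$values[valid])))
    stop("cells with missing admin label inside the valid area")
  ids <- sort(unique(as.integer(admin$values[valid])))
  suit <- valid & limits$values == 1
  zsum <- function(vals, mask) {
    agg <- tapply(vals[mask], as.integer(admin$values[mask]), sum,
                  na.rm = TRUE)
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[names(agg)] <- agg
    as.numeric(out)
  }
  rows <- data.frame(
    admin_id = as.character(ids),
    suitable_area_km2 = zsum(rep(limits$cell_size^2, length(suit)), suit),
    population_at_risk = zsum(pop$values, suit),
    cases_mean = zsum(cases$mean$values, suit & !is.na(cases$mean$values)),
    cases_lower = zsum(cases$lower$values, suit & !is.na(cases$lower$values)),
    cases_upper = zsum(cases$upper$values, suit & !is.na(cases$upper$values)))
  rbind(rows, burden_totals(rows))
}

#' Crude pooled survey prevalence with exact binomial CI
#'
#' @param survey data.frame of village records with `n_cases`, `n_examined`.
#' @param level confidence level (default 0.95).
#' @return list: `cases`, `examined`, `percent` (rounded to one decimal),
#'   `proportion`, `ci_lower`, `ci_upper` (proportions).
#' @export
crude_prevalence <- function(survey, level = 0.95) {
  stopifnot(is.data.frame(survey), nrow(survey) >= 1L)
  cases <- sum(survey$n_cases)
  examined <- sum(survey$n_examined)
  if (examined == 0L) stop("zero participants examined")
  ci <- stats::binom.test(cases, examined, conf.level = level)$conf.int
  list(cases = cases, examined = examined,
       percent = round(100 * cases / examined, 1L),
       proportion = cases / examined,
       ci_lower = ci[1L], ci_upper = ci[2L])
}
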