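#' Compute soil-surface N surplus and nitrogen use efficiency per record
#'
#' Applies the soil-surface budget identity to a wide table of component
#' records: surplus = (fertilizer + manure + deposition + fixation) -
#' (crop removal + pasture removal), per region, year, ensemble member and
#' sector. The agricultural and non-agricultural sectors are kept separate;
#' all fluxes are kgN per hectare of the record's sector area per year.
#'
#' Negative surpluses (outputs exceeding inputs) are retained, not floored:
#' the budget is a pure balance. They are flagged through `nue > 100`.
#'
#' @param records wide component-record table with columns
#'   `region_id,country,year,member_id,sector`, the six flux components
#'   `in_fert,in_man,in_dep,in_bnf,out_crops,out_past` and the two areas
#'   `ag_area,nonag_area` (hectares).
#' @return the input table with added columns `total_in`, `total_out`,
#'   `surplus` (all kgN ha^-1 yr^-1) and `nue` (%, `NA` where `total_in` is 0).
#' @export
#' @examples
#' rec <- data.frame(region_id = "r1", country = "DE", year = 2000,
#'   member_id = 1, sector = "agricultural", in_fert = 10, in_man = 5,
#'   in_dep = 2, in_bnf = 3, out_crops = 12, out_past = 3,
#'   ag_area = 1000, nonag_area = 500)
#' compute_surplus(rec)$surplus  # 5
compute_surplus <- function(records) {
  validate_records(records)
  out <- data.table::as.data.table(records)
  out[, `:=`(
    total_in  = in_fert + in_man + in_dep + in_bnf,
    total_out = out_crops + out_past
  )]
  out[, surplus := total_in - total_out]
  out[, nue := data.table::fifelse(total_in > 0, 100 * total_out / total_in,
                                   NA_real_)]
  data.table::setDF(out)
  out
}

#' Aggregate a budget table over regions
#'
#' Area-weighted aggregation of per-hectare fluxes from regions to a larger
#' scope (typology, country, or the EU-27 domain as a whole). Per-ha fluxes
#' are weighted by the basis area, so the aggregate of an extensive mass is
#' conserved: aggregate surplus equals aggregate inputs minus aggregate
#' outputs at every scope, and aggregation is order-invariant
#' (region to country to EU equals region to EU).
#'
#' @param budget output of [compute_surplus()].
#' @param scope `"EU27"`, `"country"`, or `"typology"`.
#' @param assignment for `scope = "typology"`, a data.frame
#'   `region_id,label` mapping every region to its typology.
#' @param basis which normalization to aggregate on: `"agricultural"`
#'   (agricultural-sector fluxes per ha of agricultural area),
#'   `"non-agricultural"`, or `"total"` (both sectors combined, per ha of
#'   total area — the basis used for typology classification).
#' @return a data.frame with columns `scope`, `scope_id`, `year`,
#'   `member_id`, the six components, `area` (ha of the basis area),
#'   `total_in`, `total_out`, `surplus` (kgN ha^-1 yr^-1) and `nue` (%).
#' @export
aggregate_budget <- function(budget,
                             scope = c("EU27", "country", "typology"),
                             assignment = NULL,
                             basis = c("agricultural", "non-agricultural",
                                       "total")) {
  scope <- match.arg(scope)
  basis <- match.arg(basis)
  dt <- data.table::as.data.table(budget)

  if (scope == "typology") {
    if (is.null(assignment))
      stop_ns("scope = 'typology' requires an assignment table")
    map <- data.table::as.data.table(assignment)[, .(region_id, label)]
    unassigned <- setdiff(unique(dt$region_id), map$region_id)
    if (length(unassigned) > 0)
      stop_ns("region(s) without typology assignment: %s",
              paste(head(unassigned, 5), collapse = ", "))
    dt <- merge(dt, map, by = "region_id")
    dt[, scope_id := label]
  } else if (scope == "country") {
    dt[, scope_id := country]
  } else {
    dt[, scope_id := "EU27"]
  }

  if (basis == "total") {
    # convert sector per-ha fluxes to masses, sum sectors, renormalize
    dt[, w := data.table::fifelse(sector == "agricultural", ag_area, nonag_area)]
    dt[, tot_area := ag_area + nonag_area]
  } else {
    dt <- dt[sector == basis]
    if (nrow(dt) == 0) stop_ns("no records for sector '%s'", basis)
    if (basis == "agricultural") dt[, w := ag_area] else dt[, w := nonag_area]
  }
  if (any(dt$w < 0)) stop_ns("negative area weight")

  cols <- BUDGET_COMPONENTS
  agg <- dt[, {
    a <- sum(w)
    if (a <= 0) stop_ns("zero total area in aggregation group")
    c(lapply(.SD, function(x) sum(x * w) / a), list(area = a))
  }, by = .(scope_id, year, member_id), .SDcols = cols]

  agg[, `:=`(total_in = in_fert + in_man + in_dep + in_bnf,
             total_out = out_crops + out_past)]
  agg[, surplus := total_in - total_out]
  agg[, nue := data.table::fifelse(total_in > 0, 100 * total_out / total_in,
                                   NA_real_)]
  data.table::set(agg, j = "scope", value = scope)
  data.table::setcolorder(agg, c("scope", "scope_id", "year", "member_id"))
  data.table::setorder(agg, scope_id, year, member_id)
  data.table::setDF(agg)
  agg
}

#' Per-year ensemble summary
#'
#' Summarizes a value over the ensemble members for every year (and scope
#' group): mean, minimum, maximum and standard deviation (n-1 denominator).
#' The min-max band is the uncertainty range reported alongside headline
#' means; with a single member the band is degenerate and `sd` is `NA`.
#'
#' @param series an aggregated budget table (see [aggregate_budget()]) or any
#'   data.frame with `year`, `member_id` and the value column.
#' @param value name of the column to summarize (default `"surplus"`).
#' @return a data.frame keyed by the scope columns and `year` with columns
#'   `mean`, `min`, `max`, `sd`, `n_members`.
#' @export
ensemble_stats <- function(series, value = "surplus") {
  if (!value %in% names(series)) stop_ns("no column '%s' in series", value)
  dt <- data.table::as.data.table(series)
  keys <- intersect(c("scope", "scope_id", "region_id", "sector", "year"),
                    names(dt))
  out <- dt[, {
    v <- .SD[[1L]]
    list(mean = mean(v), min = min(v), max = max(v),
         sd = if (.N >= 2) sd(v) else NA_real_, n_members = .N)
  }, by = keys, .SDcols = value]
  data.table::setDF(out)
  out
}

#' Mean series over ensemble members
#'
#' Collapses an aggregated budget table to the per-year mean of each flux
#' over the 16 members. Because the budget identity is linear, the surplus
#' of the member-mean components equals the member-mean surplus.
#'
#' @param series an aggregated budget table (see [aggregate_budget()]).
#' @return the table averaged over `member_id` (column dropped).
#' @export
member_mean <- function(series) {
  dt <- data.table::as.data.table(series)
  keys <- intersect(c("scope", "scope_id", "region_id", "sector", "year"),
                    names(dt))
  vals <- intersect(c(BUDGET_COMPONENTS, "area", "total_in", "total_out",
                      "surplus"), names(dt))
  out <- dt[, lapply(.SD, mean), by = keys, .SDcols = vals]
  if (all(c("total_in", "total_out") %in% names(out)))
    out[, nue := data.table::fifelse(total_in > 0, 100 * total_out / total_in,
                                     NA_real_)]
  data.table::setDF(out)
  out
}

#' Phase summary of budget components
#'
#' Summarizes an aggregated budget over the two historical phases — the
#' early development phase (1940-1985, sharp surplus rise) and the
#' sustainable intensification phase (1986-2019, decline under policy and
#' technology). For each phase it reports the mean mass flux of every
#' component in TgN per year (1 Tg = 1e9 kg; computed with the
#' year-specific areas by default), each input component's share of total
#' N inputs in percent, and the mean NUE.
#'
#' @param series an aggregated budget table for one scope
#'   (see [aggregate_budget()]); members are averaged first.
#' @param phases named list of `c(start, end)` year pairs; defaults to the
#'   two historical phases.
#' @param fixed_area optionally, a single area (ha) used for all years in
#'   the TgN conversion instead of the year-specific areas.
#' @return a data.frame with one row per phase and component, columns
#'   `phase`, `component`, `mean_tg` (TgN yr^-1), `share_pct` (inputs only,
#'   `NA` for outputs), plus attribute-free rows `total_in`/`total_out`, and
#'   a `nue_pct` column (phase mean NUE, repeated within phase).
#' @export
phase_summary <- function(series,
                          phases = list(early = c(1940, 1985),
                                        intensification = c(1986, 2019)),
                          fixed_area = NULL) {
  m <- data.table::as.data.table(member_mean(series))
  if (length(unique(m$scope_id %||% "x")) > 1)
    stop_ns("phase_summary expects a single scope; aggregate first")
  yrs <- range(m$year)
  res <- list()
  for (ph in names(phases)) {
    w <- phases[[ph]]
    if (w[1] < yrs[1] || w[2] > yrs[2])
      stop_ns("phase '%s' (%d-%d) outside data range %d-%d",
              ph, w[1], w[2], yrs[1], yrs[2])
    sub <- m[year >= w[1] & year <= w[2]]
    area <- if (is.null(fixed_area)) sub$area else rep(fixed_area, nrow(sub))
    comp_tg <- vapply(BUDGET_COMPONENTS,
                      function(v) mean(sub[[v]] * area * 1e-9), numeric(1))
    in_tg <- comp_tg[c("in_fert", "in_man", "in_dep", "in_bnf")]
    out_tg <- comp_tg[c("out_crops", "out_past")]
    shares <- 100 * in_tg / sum(in_tg)
    nue_ph <- mean(sub$nue, na.rm = TRUE)
    res[[ph]] <- data.frame(
      phase = ph,
      component = names(comp_tg),
      mean_tg = unname(comp_tg),
      share_pct = c(unname(shares), NA_real_, NA_real_),
      nue_pct = nue_ph,
      row.names = NULL
    )
  }
  do.call(rbind, res)
}

#' Percent change between two 3-year windows
#'
#' Change of a series between a start and an end interval, each summarized
#' by its 3-year moving average (the mean of the three annual values), as
#' 100 * (end - start) / start. This is the convention used for phase-wise
#' surplus and NUE change reporting.
#'
#' @param series data.frame with columns `year` and the value column
#'   (single scope, single member or member mean).
#' @param window_start,window_end `c(first, last)` year pairs spanning
#'   exactly three years each.
#' @param value name of the value column (default `"surplus"`).
#' @return percent change (a single numeric).
#' @export
#' @examples
#' s <- data.frame(year = 1939:1987, surplus = c(rep(10, 4), seq(10, 67.1,
#'   length.out = 45)))
#' # rise from a mean of 10 to a mean of about 67 is about +570%
percent_change <- function(series, window_start, window_end,
                           value = "surplus") {
  if (!value %in% names(series)) stop_ns("no column '%s' in series", value)
  for (w in list(window_start, window_end)) {
    if (length(w) != 2 || w[2] - w[1] != 2)
      stop_ns("windows must span exactly three years (c(first, last))")
    if (!all(seq(w[1], w[2]) %in% series$year))
      stop_ns("window %d-%d not fully inside the data range", w[1], w[2])
  }
  avg <- function(w) mean(series[[value]][series$year %in% seq(w[1], w[2])])
  a <- avg(window_start); b <- avg(window_end)
  if (a == 0) stop_ns("start-window mean is zero; percent change undefined")
  100 * (b - a) / a
}
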