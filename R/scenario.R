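#' Named top-down scenario presets
#'
#' The five named input-reduction scenarios with their fertilizer and
#' manure reduction fractions: GD-F (Green Deal Fertilizer, 20% fertilizer
#' cut), FAO-F (43% fertilizer cut), FAO-FM (43% fertilizer + 4% manure),
#' BAF (Better Animal Feed, 20% fertilizer + 10% manure) and LAP (Less
#' Animal Products, 20% fertilizer + 20% manure). Deposition and fixation
#' are never reduced. The business-as-usual trend projection is handled
#' separately by [run_bau()].
#'
#' @return data.frame `name, r_fert, r_man`.
#' @export
scenario_presets <- function() {
  data.frame(
    name = c("GD-F", "FAO-F", "FAO-FM", "BAF", "LAP"),
    r_fert = c(0.20, 0.43, 0.43, 0.20, 0.20),
    r_man = c(0.00, 0.00, 0.04, 0.10, 0.20)
  )
}

#' Window means of the budget components
#'
#' Mean of each component (and of the derived totals) over a year window,
#' by scope and, when present, ensemble member. Used to form the baseline
#' state that scenarios are projected from.
#'
#' @param series an aggregated budget series.
#' @param window `c(start, end)` years, inclusive.
#' @return data.frame of means, one row per scope (x member).
#' @export
window_means <- function(series, window) {
  dt <- data.table::as.data.table(series)
  if (!all(seq(window[1], window[2]) %in% unique(dt$year)))
    stop_ns("window %d-%d not covered by the series", window[1], window[2])
  keys <- intersect(c("scope", "scope_id", "member_id"), names(dt))
  vals <- intersect(c(BUDGET_COMPONENTS, "total_in", "total_out", "surplus"),
                    names(dt))
  out <- dt[year >= window[1] & year <= window[2],
            lapply(.SD, mean), by = keys, .SDcols = vals]
  data.table::setDF(out)
  out
}

#' Fit the hyperbolic response per scope and window
#'
#' Fits the response coefficient on scope-aggregate (area-weighted) window
#' means of N input and output, for one or several windows.
#'
#' @param series member-mean aggregated budget series ([member_mean()] of
#'   an [aggregate_budget()] result, agricultural basis).
#' @param windows list of `c(start, end)` windows (default: the 2015-2019
#'   baseline window).
#' @return data.frame `scope_id, window_start, window_end, midpoint,
#'   mean_in, mean_out, c`.
#' @export
fit_response <- function(series, windows = list(c(2015, 2019))) {
  res <- list()
  for (w in windows) {
    wm <- window_means(series, w)
    for (i in seq_len(nrow(wm))) {
      cc <- fit_c(wm$total_in[i], wm$total_out[i])
      res[[length(res) + 1]] <- data.frame(
        scope_id = wm$scope_id[i], window_start = w[1], window_end = w[2],
        midpoint = mean(w), mean_in = wm$total_in[i],
        mean_out = wm$total_out[i], c = cc)
    }
  }
  do.call(rbind, res)
}

#' Fit the technology trend per scope
#'
#' Fits the response coefficient on each of the eight trend windows
#' (1981-1985 ... 2016-2019) and the baseline window (2015-2019), then the
#' linear extrapolation of c to the horizon with its 95% interval.
#'
#' @param series member-mean aggregated budget series (agricultural basis).
#' @param windows the eight trend windows (default [trend_windows()]).
#' @param baseline_window window for the baseline coefficient.
#' @param horizon projection year.
#' @return named list of `ns_trend`, one per `scope_id`.
#' @export
fit_trends <- function(series, windows = trend_windows(),
                       baseline_window = c(2015, 2019), horizon = 2030) {
  fits <- fit_response(series, windows)
  base <- fit_response(series, list(baseline_window))
  out <- list()
  for (sid in unique(fits$scope_id)) {
    f <- fits[fits$scope_id == sid, ]
    f <- f[order(f$midpoint), ]
    out[[sid]] <- fit_c_trend(f$c, midpoints = f$midpoint,
                              c_baseline = base$c[base$scope_id == sid],
                              horizon = horizon)
  }
  out
}

# core 2030 projection from baseline component means and a 2030 coefficient
project_2030 <- function(base, c2030, r_fert, r_man) {
  in2030 <- base$in_dep + base$in_bnf +
    (1 - r_fert) * base$in_fert + (1 - r_man) * base$in_man
  out2030 <- predict_output(c2030, in2030)
  surp2030 <- in2030 - out2030
  base_surp <- base$total_in - base$total_out
  list(
    in_2030 = in2030, out_2030 = out2030, surplus_2030 = surp2030,
    baseline_surplus = base_surp,
    surplus_reduction_pct = 100 * (base_surp - surp2030) / base_surp,
    output_reduction_pct = 100 * (base$total_out - out2030) / base$total_out
  )
}

#' Project one input-reduction scenario for one scope
#'
#' Reduces the baseline-window fertilizer and manure inputs by the scenario
#' fractions (deposition and fixation are untouched), resolves the 2030
#' response coefficient through [apply_tmp_mode()], predicts the 2030
#' output through the hyperbolic response and reports surplus and output
#' reductions against the baseline means. The NAT (natural landscapes)
#' typology is excluded from agricultural analysis and refused.
#'
#' @param base one-row data.frame of baseline component means for the scope
#'   (a row of [window_means()], needs `in_fert,in_man,in_dep,in_bnf,
#'   total_in,total_out` and optionally `scope_id`).
#' @param c_baseline baseline response coefficient for the scope.
#' @param trend `ns_trend` for the scope (required for improved TMPs).
#' @param r_fert,r_man reduction fractions in `[0, 1]`.
#' @param tmp_mode `"same"` or `"improved"`.
#' @param bound `"point"`, `"low"` or `"high"`.
#' @param name scenario name for the output row.
#' @return one-row data.frame: scope_id, scenario, tmp_mode, bound,
#'   r_fert, r_man, baseline_surplus, in_2030, out_2030, surplus_2030,
#'   surplus_reduction_pct, output_reduction_pct, target_met.
#' @export
run_scenario <- function(base, c_baseline, trend = NULL,
                         r_fert, r_man, tmp_mode = c("same", "improved"),
                         bound = c("point", "low", "high"),
                         name = NA_character_) {
  tmp_mode <- match.arg(tmp_mode)
  bound <- match.arg(bound)
  if (r_fert < 0 || r_fert > 1 || r_man < 0 || r_man > 1)
    stop_ns("reduction fractions must lie in [0, 1]")
  sid <- base$scope_id %||% NA_character_
  if (identical(as.character(sid), "NAT"))
    stop_ns("NAT typology is excluded from agricultural N surplus analysis")
  c2030 <- apply_tmp_mode(c_baseline, trend, tmp_mode, bound)
  pr <- project_2030(base, c2030, r_fert, r_man)
  data.frame(
    scope_id = sid, scenario = name, tmp_mode = tmp_mode, bound = bound,
    r_fert = r_fert, r_man = r_man, c_2030 = c2030,
    baseline_surplus = pr$baseline_surplus,
    in_2030 = pr$in_2030, out_2030 = pr$out_2030,
    surplus_2030 = pr$surplus_2030,
    surplus_reduction_pct = pr$surplus_reduction_pct,
    output_reduction_pct = pr$output_reduction_pct,
    target_met = pr$surplus_reduction_pct >= 50
  )
}

#' Run the named scenarios across scopes and TMP modes
#'
#' Convenience driver: fits the baseline response and technology trend per
#' scope from the member-mean series, then evaluates every preset scenario
#' under the requested TMP modes and interval bounds. NAT scopes are
#' dropped (excluded from agricultural analysis); scopes where the
#' response is undefined (output >= input) are dropped with a warning.
#'
#' @param series member-mean aggregated budget series (agricultural basis).
#' @param scenarios data.frame `name, r_fert, r_man`
#'   (default [scenario_presets()]).
#' @param tmp_modes subset of `c("same", "improved")`.
#' @param bounds subset of `c("point", "low", "high")` (improved mode; the
#'   same-TMP rows always use `"point"`).
#' @param baseline_window,windows,horizon see [fit_trends()].
#' @return data.frame of scenario results, one row per scope x scenario x
#'   mode (x bound).
#' @export
run_scenarios <- function(series, scenarios = scenario_presets(),
                          tmp_modes = c("same", "improved"),
                          bounds = "point",
                          baseline_window = c(2015, 2019),
                          windows = trend_windows(), horizon = 2030) {
  sids <- setdiff(unique(series$scope_id), "NAT")
  base_all <- window_means(series, baseline_window)
  need_trend <- "improved" %in% tmp_modes
  trends <- if (need_trend) fit_trends(series[series$scope_id %in% sids, ],
                                       windows, baseline_window, horizon)
  res <- list()
  for (sid in sids) {
    base <- base_all[base_all$scope_id == sid, ]
    c_base <- tryCatch(fit_c(base$total_in, base$total_out),
                       error = function(e) NA_real_)
    if (is.na(c_base)) {
      warn_ns("scope %s: response undefined (Out >= In); excluded", sid)
      next
    }
    tr <- if (need_trend) trends[[sid]]
    for (i in seq_len(nrow(scenarios))) {
      for (mode in tmp_modes) {
        bds <- if (mode == "improved") bounds else "point"
        for (bd in bds) {
          res[[length(res) + 1]] <- run_scenario(
            base, c_base, tr, scenarios$r_fert[i], scenarios$r_man[i],
            tmp_mode = mode, bound = bd, name = scenarios$name[i])
        }
      }
    }
  }
  do.call(rbind, res)
}

#' Business-as-usual trend projection
#'
#' Projects the agricultural N surplus to 2030 by extrapolating its
#' 1961-2019 trend with a penalized thin-plate regression spline GAM. The
#' count-data (negative-binomial, log link) family is applied to the
#' surplus rescaled to integer-like counts; a Gaussian identity-link fit is
#' used as fallback (and automatically whenever the series has non-positive
#' values, where the log link is undefined). An increase appears as a
#' negative reduction.
#'
#' @param series member-mean aggregated budget series for one scope with
#'   columns `year`, `surplus`.
#' @param fit_years years used for the trend fit.
#' @param horizon projection year.
#' @param family `"auto"` (nb when all values positive), `"nb"` or
#'   `"gaussian"`.
#' @param count_scale multiplier used to rescale surplus before rounding
#'   for the negative-binomial fit.
#' @param baseline_window window defining the baseline surplus the
#'   projection is compared against.
#' @return one-row data.frame: scope_id, scenario = "BAU", family,
#'   baseline_surplus, surplus_2030, surplus_reduction_pct, target_met.
#' @export
run_bau <- function(series, fit_years = 1961:2019, horizon = 2030,
                    family = c("auto", "nb", "gaussian"), count_scale = 100,
                    baseline_window = c(2015, 2019)) {
  family <- match.arg(family)
  dt <- series[series$year %in% fit_years, ]
  if (length(unique(dt$scope_id %||% "x")) > 1)
    stop_ns("run_bau expects a single scope")
  if (nrow(dt) < length(fit_years))
    stop_ns("series does not cover the BAU fit years %d-%d",
            min(fit_years), max(fit_years))
  y <- dt$surplus
  if (family == "auto") family <- if (all(y > 0)) "nb" else "gaussian"
  if (family == "nb" && any(y <= 0))
    stop_ns(paste0("non-positive surplus values are incompatible with the ",
                   "log link; use family = 'gaussian'"))
  df <- data.frame(year = dt$year, surplus = y)
  if (family == "nb") {
    df$cnt <- as.integer(round(y * count_scale))
    fit <- mgcv::gam(cnt ~ s(year, bs = "tp"), data = df,
                     family = mgcv::nb(link = "log"), method = "REML")
    proj <- as.numeric(predict(fit, newdata = data.frame(year = horizon),
                               type = "response")) / count_scale
  } else {
    fit <- mgcv::gam(surplus ~ s(year, bs = "tp"), data = df,
                     method = "REML")
    proj <- as.numeric(predict(fit, newdata = data.frame(year = horizon)))
  }
  base <- mean(series$surplus[series$year >= baseline_window[1] &
                                series$year <= baseline_window[2]])
  red <- 100 * (base - proj) / base
  data.frame(
    scope_id = series$scope_id[1] %||% NA_character_, scenario = "BAU",
    tmp_mode = NA_character_, bound = NA_character_, family = family,
    baseline_surplus = base, surplus_2030 = proj,
    surplus_reduction_pct = red, target_met = red >= 50
  )
}

#' Bottom-up reduction grid
#'
#' Evaluates the 2030 surplus and output reductions at every combination of
#' fertilizer and manure reduction fractions on a regular grid (default 1%
#' step, 101 x 101 cells), extracts the 50% surplus-reduction contour by
#' linear interpolation between bracketing cells, and marks the target
#' zone (fertilizer reduction >= 20% and surplus reduction in
#' `[50%, 100%]`). Both surfaces are monotone non-decreasing in both
#' reduction axes.
#'
#' @param base baseline component means for one scope (see
#'   [run_scenario()]).
#' @param c2030 the 2030 response coefficient (already resolved through
#'   [apply_tmp_mode()]).
#' @param step grid step in `(0, 0.5]`.
#' @param target target surplus reduction percent for the contour.
#' @return object of class `ns_grid`: list with `r_fert`, `r_man` (axes),
#'   `surplus_reduction`, `output_reduction` (matrices, fertilizer on
#'   rows), `contour` (data.frame `r_man, r_fert_required`), `target_zone`
#'   (logical matrix), `base`, `c2030`, `target`.
#' @export
run_grid <- function(base, c2030, step = 0.01, target = 50) {
  if (step <= 0 || step > 0.5) stop_ns("grid step must lie in (0, 0.5]")
  rf <- seq(0, 1, by = step)
  rm_ <- seq(0, 1, by = step)
  fixed <- base$in_dep + base$in_bnf
  in_grid <- outer((1 - rf) * base$in_fert, (1 - rm_) * base$in_man, "+") +
    fixed
  out_grid <- predict_output(c2030, in_grid)
  surp_grid <- in_grid - out_grid
  base_surp <- base$total_in - base$total_out
  surp_red <- 100 * (base_surp - surp_grid) / base_surp
  out_red <- 100 * (base$total_out - out_grid) / base$total_out

  contour <- data.frame(r_man = rm_, r_fert_required = NA_real_)
  for (j in seq_along(rm_)) {
    col <- surp_red[, j]
    idx <- which(col >= target)[1]
    if (!is.na(idx)) {
      if (idx == 1) {
        contour$r_fert_required[j] <- rf[1]
      } else {
        # linear interpolation between the bracketing cells
        f <- (target - col[idx - 1]) / (col[idx] - col[idx - 1])
        contour$r_fert_required[j] <- rf[idx - 1] + f * step
      }
    }
  }
  zone <- outer(rf >= 0.20, rep(TRUE, length(rm_))) &
    surp_red >= target & surp_red <= 100
  structure(list(r_fert = rf, r_man = rm_,
                 surplus_reduction = surp_red, output_reduction = out_red,
                 contour = contour, target_zone = zone,
                 base = base, c2030 = c2030, target = target),
            class = "ns_grid")
}

#' @export
print.ns_grid <- function(x, ...) {
  cat(sprintf("bottom-up reduction grid: %d x %d cells, target %.0f%%\n",
              length(x$r_fert), length(x$r_man), x$target))
  r0 <- x$contour$r_fert_required[x$contour$r_man == 0]
  if (!is.na(r0))
    cat(sprintf("fertilizer-only reduction for target: %.0f%%\n", 100 * r0))
  invisible(x)
}

#' Country-level scenario breakdown
#'
#' Runs the named scenarios on country aggregates under both TMP modes and
#' flags the countries meeting the 50% surplus-reduction target. Countries
#' with an undefined response (output >= input) are excluded with a
#' warning.
#'
#' @param series member-mean country-aggregated budget series
#'   (agricultural basis; `scope_id` = country code).
#' @param ... passed to [run_scenarios()].
#' @return data.frame of per-country scenario results.
#' @export
country_breakdown <- function(series, ...) {
  run_scenarios(series, ...)
}

#' Propagate a scenario through the 16-member ensemble
#'
#' Reruns the full response-fit + scenario projection independently for
#' every ensemble member (each member gets its own baseline means, baseline
#' coefficient and, under improved TMPs, its own technology trend) and
#' summarizes the per-member surplus reductions as mean, min and max. The
#' headline value is computed on the member-mean series, as used for the
#' single reported bars; the min-max band always contains it.
#'
#' @param series aggregated budget series for one scope with `member_id`
#'   retained (an [aggregate_budget()] result, agricultural basis).
#' @param r_fert,r_man reduction fractions.
#' @param tmp_mode,bound see [run_scenario()].
#' @param baseline_window,windows,horizon see [fit_trends()].
#' @param name scenario name.
#' @return list of class `ns_ensemble`: `headline` (one-row result from
#'   the member-mean series), `members` (per-member result rows), and
#'   `band` (`mean`, `min`, `max` of the member surplus reductions).
#' @export
ensemble_propagate <- function(series, r_fert, r_man,
                               tmp_mode = "same", bound = "point",
                               baseline_window = c(2015, 2019),
                               windows = trend_windows(), horizon = 2030,
                               name = NA_character_) {
  if (length(unique(series$scope_id %||% "x")) > 1)
    stop_ns("ensemble_propagate expects a single scope")
  run_one <- function(sub) {
    base <- window_means(sub, baseline_window)
    c_base <- fit_c(base$total_in, base$total_out)
    tr <- NULL
    if (tmp_mode == "improved") {
      f <- fit_response(sub, windows)
      f <- f[order(f$midpoint), ]
      tr <- fit_c_trend(f$c, midpoints = f$midpoint, c_baseline = c_base,
                        horizon = horizon)
    }
    run_scenario(base, c_base, tr, r_fert, r_man, tmp_mode, bound, name)
  }
  members <- sort(unique(series$member_id))
  rows <- list()
  failures <- character(0)
  for (m in members) {
    r <- tryCatch(run_one(series[series$member_id == m, ]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures <- c(failures, sprintf("member %d: %s", m, conditionMessage(r)))
    } else {
      r$member_id <- m
      rows[[length(rows) + 1]] <- r
    }
  }
  if (length(failures) > 0)
    warn_ns("ensemble members failed:\n%s", paste(failures, collapse = "\n"))
  member_res <- do.call(rbind, rows)
  headline <- run_one(member_mean(series))
  red <- member_res$surplus_reduction_pct
  structure(list(headline = headline, members = member_res,
                 band = c(mean = mean(red), min = min(red), max = max(red))),
            class = "ns_ensemble")
}

#' @export
print.ns_ensemble <- function(x, ...) {
  cat(sprintf(
    "scenario %s: headline surplus reduction %.1f%% (ensemble %.1f-%.1f%%)\n",
    x$headline$scenario, x$headline$surplus_reduction_pct,
    x$band["min"], x$band["max"]))
  invisible(x)
}
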