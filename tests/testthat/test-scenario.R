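# baseline used in several worked examples: total input 100 of which
# fertilizer 45, manure 30, deposition 15, fixation 10; c = 400 gives
# output 80 and surplus 20
example_base <- function() {
  data.frame(scope_id = "FERT", in_fert = 45, in_man = 30, in_dep = 15,
             in_bnf = 10, total_in = 100, total_out = 80)
}

test_that("a no-reduction scenario under same TMPs is the identity", {
  r <- run_scenario(example_base(), c_baseline = 400, r_fert = 0, r_man = 0,
                    tmp_mode = "same", name = "null")
  expect_equal(r$surplus_reduction_pct, 0, tolerance = 1e-12)
  expect_equal(r$output_reduction_pct, 0, tolerance = 1e-12)
  expect_equal(r$surplus_2030, 20, tolerance = 1e-12)
})

test_that("the 20% fertilizer cut follows the hyperbolic arithmetic", {
  # In' = 100 - 0.2*45 = 91; Out' = 400*91/491; Surp' = 91 - Out'
  r <- run_scenario(example_base(), 400, r_fert = 0.2, r_man = 0,
                    tmp_mode = "same", name = "GD-F")
  expect_equal(r$in_2030, 91)
  expect_equal(r$out_2030, 400 * 91 / 491, tolerance = 1e-12)
  expect_equal(r$surplus_2030, 91 - 400 * 91 / 491, tolerance = 1e-12)
  expect_equal(r$surplus_reduction_pct, 100 * (20 - 16.866) / 20,
               tolerance = 1e-3)
  expect_false(r$target_met)

  # improved TMPs with c' = 500 cuts the surplus about twice as much
  tr <- fit_c_trend(seq(100, 135, 5), c_baseline = 400)
  tr$delta_tmp <- 0.25  # c' = 500
  ri <- run_scenario(example_base(), 400, tr, r_fert = 0.2, r_man = 0,
                     tmp_mode = "improved", name = "GD-F")
  expect_equal(ri$out_2030, 500 * 91 / 591, tolerance = 1e-12)
  expect_equal(ri$surplus_reduction_pct, 29.95, tolerance = 0.01)
  expect_gt(ri$surplus_reduction_pct, r$surplus_reduction_pct)
})

test_that("scenario preconditions are enforced", {
  expect_error(run_scenario(example_base(), 400, r_fert = 1.2, r_man = 0),
               "\\[0, 1\\]")
  nat <- example_base()
  nat$scope_id <- "NAT"
  expect_error(run_scenario(nat, 400, r_fert = 0.2, r_man = 0),
               "NAT typology is excluded")
})

test_that("the reduction grid is monotone and consistent with the presets", {
  g <- run_grid(example_base(), c2030 = 400, step = 0.01)
  expect_equal(g$surplus_reduction[1, 1], 0, tolerance = 1e-12)
  # full reduction leaves irreducible deposition + fixation inputs
  expect_lt(g$surplus_reduction[101, 101], 100)
  expect_true(all(diff(g$surplus_reduction) >= -1e-12))       # in r_fert
  expect_true(all(diff(t(g$surplus_reduction)) >= -1e-12))    # in r_man
  expect_true(all(diff(g$output_reduction) >= -1e-12))
  expect_true(all(diff(t(g$output_reduction)) >= -1e-12))

  # named scenarios equal the corresponding grid cells exactly
  for (i in seq_len(nrow(scenario_presets()))) {
    sc <- scenario_presets()[i, ]
    r <- run_scenario(example_base(), 400, r_fert = sc$r_fert,
                      r_man = sc$r_man, tmp_mode = "same", name = sc$name)
    cell <- g$surplus_reduction[round(100 * sc$r_fert) + 1,
                                round(100 * sc$r_man) + 1]
    expect_identical(r$surplus_reduction_pct, cell)
  }

  # hyperbolic damping: output never falls by more than the input fraction
  in_red <- outer(g$r_fert * example_base()$in_fert,
                  g$r_man * example_base()$in_man, "+") /
    example_base()$total_in * 100
  expect_true(all(g$output_reduction <= in_red + 1e-9))

  expect_error(run_grid(example_base(), 400, step = 0.7), "\\(0, 0.5\\]")
})

test_that("the grid contour matches the analytic inversion", {
  base <- example_base()
  g <- run_grid(base, c2030 = 400, step = 0.01)
  # at r_man = 0: required input for half the baseline surplus
  target_in <- required_input_for_surplus(400, 10)
  rf_analytic <- (base$total_in - target_in) / base$in_fert
  rf_grid <- g$contour$r_fert_required[g$contour$r_man == 0]
  expect_equal(rf_grid, rf_analytic, tolerance = 0.01)  # one grid step
})

test_that("improved TMPs dominate same TMPs across the whole grid", {
  base <- example_base()
  g_same <- run_grid(base, c2030 = 400, step = 0.02)
  g_imp <- run_grid(base, c2030 = 480, step = 0.02)
  expect_true(all(g_imp$surplus_reduction >=
                    g_same$surplus_reduction - 1e-12))
})

test_that("BAU extrapolates the fitted surplus trend", {
  lin <- data.frame(scope_id = "X", year = 1961:2019,
                    surplus = 10 + 0.5 * (1961:2019 - 1961))
  r <- run_bau(lin)
  expect_gte(r$surplus_2030, max(lin$surplus))
  expect_lt(r$surplus_reduction_pct, 0)  # an increase is a negative reduction

  const <- data.frame(scope_id = "X", year = 1961:2019, surplus = 40)
  rc <- run_bau(const)
  expect_equal(rc$surplus_2030, 40, tolerance = 0.02)
  expect_equal(rc$surplus_reduction_pct, 0, tolerance = 0.1)

  # known gently curved trend + noise: projection within 5% of its value
  curve <- function(y) 70 - 0.004 * (y - 1990)^2
  set.seed(4)
  noisy <- data.frame(scope_id = "X", year = 1961:2019,
                      surplus = curve(1961:2019) + rnorm(59, 0, 1))
  rn <- run_bau(noisy)
  expect_equal(rn$surplus_2030, curve(2030), tolerance = 0.05)

  neg <- data.frame(scope_id = "X", year = 1961:2019,
                    surplus = seq(-5, 53, length.out = 59))
  expect_error(run_bau(neg, family = "nb"), "log link")
  rg <- suppressWarnings(run_bau(neg, family = "auto"))
  expect_equal(rg$family, "gaussian")  # identity-link fallback engaged
  expect_gt(rg$surplus_2030, max(neg$surplus))  # rising linear trend
})

test_that("country results are consistent with their typology aggregate", {
  # one-country scope identical to the typology aggregate gives identical
  # reductions
  fx <- get_fixture()
  b <- compute_surplus(fx$records)
  one_country <- b[b$country == b$country[b$region_id == "R001"][1] &
                     b$region_id %in%
                       fx$truth$region_id[fx$truth$label == "MAN"], ]
  cty <- member_mean(aggregate_budget(one_country, "country",
                                      basis = "agricultural"))
  eu <- cty
  eu$scope_id <- "EU27"
  r1 <- country_breakdown(cty, tmp_modes = "same")
  r2 <- run_scenarios(eu, tmp_modes = "same")
  expect_equal(r1$surplus_reduction_pct, r2$surplus_reduction_pct,
               tolerance = 1e-12)

  # threshold flagging and its brute-force recount
  series <- get_fixture_series()
  series <- series[series$scope_id != "NAT", ]
  res <- run_scenarios(series, tmp_modes = c("same", "improved"))
  expect_equal(res$target_met, res$surplus_reduction_pct >= 50)
  expect_equal(sum(res$target_met),
               sum(vapply(seq_len(nrow(res)), function(i)
                 res$surplus_reduction_pct[i] >= 50, logical(1))))
})

test_that("a scope with undefined response is excluded with a warning", {
  series <- get_fixture_series()
  bad <- series[series$scope_id == "MAN", ]
  bad$total_out <- bad$total_in + 1  # output exceeding input
  expect_warning(res <- run_scenarios(rbind(bad,
                                            series[series$scope_id == "MOD", ]),
                                      tmp_modes = "same"),
                 "response undefined")
  expect_false("MAN" %in% res$scope_id)
})

test_that("ensemble propagation brackets the member-mean headline", {
  fx <- get_fixture()
  b <- compute_surplus(fx$records)
  agg <- aggregate_budget(b, "typology", fx$truth, "agricultural")
  man <- agg[agg$scope_id == "FERT", ]
  ens <- ensemble_propagate(man, 0.2, 0, tmp_mode = "same", name = "GD-F")
  expect_equal(nrow(ens$members), 16)
  expect_lte(ens$band["min"], ens$headline$surplus_reduction_pct)
  expect_gte(ens$band["max"], ens$headline$surplus_reduction_pct)

  # identical members give a zero-width band
  flat <- man[man$member_id == 1, ]
  clones <- do.call(rbind, lapply(1:4, function(m) {
    x <- flat; x$member_id <- m; x
  }))
  e0 <- ensemble_propagate(clones, 0.2, 0, tmp_mode = "same")
  expect_equal(unname(e0$band["max"] - e0$band["min"]), 0, tolerance = 1e-12)

  # scaling all components scales inputs and outputs but not the reduction
  scaled <- do.call(rbind, lapply(1:4, function(m) {
    x <- flat
    x$member_id <- m
    f <- c(0.9, 0.95, 1.05, 1.1)[m]
    for (v in c("in_fert", "in_man", "in_dep", "in_bnf", "out_crops",
                "out_past", "total_in", "total_out", "surplus"))
      x[[v]] <- x[[v]] * f
    x
  }))
  es <- ensemble_propagate(scaled, 0.2, 0, tmp_mode = "same")
  expect_equal(unname(es$band["max"] - es$band["min"]), 0, tolerance = 1e-9)
})
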