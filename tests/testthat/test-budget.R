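test_that("surplus is the exact input-output balance per record", {
  b <- compute_surplus(one_record())
  expect_equal(b$surplus, 5)
  expect_equal(b$total_in, 20)
  expect_equal(b$nue, 75)

  zero <- compute_surplus(one_record(in_fert = 0, in_man = 0, in_dep = 0,
                                     in_bnf = 0, out_crops = 0, out_past = 0))
  expect_equal(zero$surplus, 0)
  expect_true(is.na(zero$nue))

  b2 <- compute_surplus(one_record(in_fert = 60, in_man = 20, in_dep = 10,
                                   in_bnf = 10, out_crops = 40, out_past = 5))
  expect_equal(b2$surplus, 55)
  expect_equal(b2$nue, 45)
})

test_that("invalid records are rejected with a pointer to the offender", {
  expect_error(compute_surplus(one_record(in_man = -1)), "negative in_man.*r1")
  expect_error(compute_surplus(one_record(out_crops = NA)), "missing out_crops")
  expect_error(compute_surplus(rbind(one_record(), one_record())), "duplicate")
  expect_error(compute_surplus(one_record(ag_area = 0, nonag_area = 0)),
               "must be positive")
})

test_that("negative surpluses are retained and flagged through NUE > 100", {
  b <- compute_surplus(one_record(out_crops = 25))
  expect_lt(b$surplus, 0)
  expect_gt(b$nue, 100)
})

test_that("aggregation is the area-weighted mean of per-ha fluxes", {
  two <- rbind(
    one_record(region_id = "a", ag_area = 1, nonag_area = 1,
               in_fert = 10, in_man = 0, in_dep = 0, in_bnf = 0,
               out_crops = 0, out_past = 0),
    one_record(region_id = "b", ag_area = 3, nonag_area = 1,
               in_fert = 20, in_man = 0, in_dep = 0, in_bnf = 0,
               out_crops = 0, out_past = 0))
  agg <- aggregate_budget(compute_surplus(two), "EU27",
                          basis = "agricultural")
  expect_equal(agg$surplus, 17.5)  # (1*10 + 3*20) / 4

  single <- aggregate_budget(compute_surplus(one_record()), "EU27",
                             basis = "agricultural")
  expect_equal(single$surplus, 5)  # identity

  three <- do.call(rbind, lapply(1:3, function(i)
    one_record(region_id = paste0("r", i), ag_area = 50,
               in_fert = 10 * i, in_man = 0, in_dep = 0, in_bnf = 0,
               out_crops = 0, out_past = 0)))
  agg3 <- aggregate_budget(compute_surplus(three), "EU27",
                           basis = "agricultural")
  expect_equal(agg3$surplus, 20)  # brute-force equal-weight mean
})

test_that("aggregation conserves mass and is order-invariant", {
  fx <- get_fixture()
  b <- compute_surplus(fx$records)
  for (sc in list(list("EU27", NULL), list("country", NULL),
                  list("typology", fx$truth))) {
    agg <- aggregate_budget(b, sc[[1]], sc[[2]], "agricultural")
    expect_equal(agg$surplus, agg$total_in - agg$total_out, tolerance = 1e-12)
  }
  # region -> country -> EU27 equals region -> EU27
  cty <- aggregate_budget(b, "country", basis = "agricultural")
  direct <- aggregate_budget(b, "EU27", basis = "agricultural")
  dt <- data.table::as.data.table(cty)
  two_step <- dt[, .(surplus = sum(surplus * area) / sum(area)),
                 by = .(year, member_id)]
  merged <- merge(two_step, direct, by = c("year", "member_id"))
  expect_equal(merged$surplus.x, merged$surplus.y, tolerance = 1e-12)
})

test_that("regions without a typology assignment are refused", {
  fx <- get_fixture()
  b <- compute_surplus(fx$records)
  expect_error(aggregate_budget(b, "typology", fx$truth[-1, ], "agricultural"),
               "without typology assignment")
})

test_that("ensemble statistics summarize the 16 members per year", {
  df <- data.frame(year = 2000, member_id = 1:16, surplus = 1:16)
  st <- ensemble_stats(df)
  expect_equal(st$mean, 8.5)
  expect_equal(st$min, 1)
  expect_equal(st$max, 16)
  expect_equal(st$sd, sd(1:16))

  same <- data.frame(year = 2000, member_id = 1:16, surplus = rep(7, 16))
  st2 <- ensemble_stats(same)
  expect_equal(unlist(st2[c("mean", "min", "max")]), c(mean = 7, min = 7,
                                                       max = 7))
  expect_equal(st2$sd, 0)

  lone <- ensemble_stats(data.frame(year = 2000, member_id = 1, surplus = 3))
  expect_true(is.na(lone$sd))
  expect_equal(lone$min, lone$max)

  set.seed(11)
  draws <- replicate(200, sd(rnorm(16, 28, 5)))
  st3 <- ensemble_stats(data.frame(year = 2000, member_id = 1:16,
                                   surplus = rnorm(16, 28, 5)))
  expect_lt(abs(st3$sd - 5), 3 * sd(draws))  # recovered within sampling error
})

test_that("ensemble mean of surplus equals surplus of mean components", {
  fx <- get_fixture()
  agg <- aggregate_budget(compute_surplus(fx$records), "EU27",
                          basis = "agricultural")
  mm <- member_mean(agg)
  st <- ensemble_stats(agg)
  merged <- merge(mm, st, by = "year")
  expect_equal(merged$total_in - merged$total_out, merged$mean,
               tolerance = 1e-12)
})

test_that("phase summaries report TgN component means, shares and NUE", {
  # constant composition matching the historical early-phase mix:
  # fert 6.1, man 7.2, dep+bnf 7.7 TgN/yr over a 1e9 ha domain
  yrs <- 1935:2019
  recs <- do.call(rbind, lapply(yrs, function(y)
    one_record(year = y, ag_area = 1e9, nonag_area = 1,
               in_fert = 6.1, in_man = 7.2, in_dep = 3.7, in_bnf = 4.0,
               out_crops = 8, out_past = 2)))
  agg <- aggregate_budget(compute_surplus(recs), "EU27",
                          basis = "agricultural")
  ps <- phase_summary(agg)
  early <- ps[ps$phase == "early", ]
  expect_equal(early$mean_tg[early$component == "in_fert"], 6.1,
               tolerance = 1e-9)
  expect_equal(early$share_pct[early$component == "in_fert"], 29,
               tolerance = 0.5)
  expect_equal(early$share_pct[early$component == "in_man"], 34.3,
               tolerance = 0.5)
  expect_equal(sum(early$share_pct, na.rm = TRUE), 100, tolerance = 1e-9)

  # one input component only -> share 100%
  solo <- do.call(rbind, lapply(yrs, function(y)
    one_record(year = y, in_man = 0, in_dep = 0, in_bnf = 0)))
  ps2 <- phase_summary(aggregate_budget(compute_surplus(solo), "EU27",
                                        basis = "agricultural"))
  expect_equal(ps2$share_pct[ps2$component == "in_fert" &
                               ps2$phase == "early"], 100)

  # step change between phases -> phase means equal the construction values
  step <- do.call(rbind, lapply(yrs, function(y)
    one_record(year = y, ag_area = 1e9, nonag_area = 1,
               in_fert = if (y <= 1985) 4 else 10)))
  ps3 <- phase_summary(aggregate_budget(compute_surplus(step), "EU27",
                                        basis = "agricultural"))
  expect_equal(ps3$mean_tg[ps3$component == "in_fert"], c(4, 10),
               tolerance = 1e-9)

  expect_error(phase_summary(agg, phases = list(p = c(1900, 1950))),
               "outside data range")
})

test_that("percent change uses 3-year window means", {
  s <- data.frame(year = 1986:2019,
                  surplus = c(rep(50, 3), rep(99, 28), rep(42, 3)))
  expect_equal(percent_change(s, c(1986, 1988), c(2017, 2019)), -16)
  expect_equal(percent_change(s, c(1986, 1988), c(1986, 1988)), 0)

  s2 <- data.frame(year = 1940:1985,
                   surplus = c(rep(10, 3), rep(0, 40), rep(67.1, 3)))
  expect_equal(percent_change(s2, c(1940, 1942), c(1983, 1985)), 571)

  s3 <- data.frame(year = 1940:1985, surplus = 0)
  expect_error(percent_change(s3, c(1940, 1942), c(1983, 1985)),
               "start-window mean is zero")
  expect_error(percent_change(s, c(1980, 1982), c(2017, 2019)),
               "not fully inside")
  expect_error(percent_change(s, c(1986, 1990), c(2017, 2019)),
               "exactly three years")
})
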