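# shared fixtures, generated once per test run (deterministic seeds)
.cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_fixture()
  .cache$fx
}

# 120-region simulation at the default noise conditions, for recovery tests
get_recovery_sim <- function() {
  if (is.null(.cache$rec))
    .cache$rec <- simulate_budget(generator_config(n_regions = 120L, seed = 7L))
  .cache$rec
}

# member-mean typology series (agricultural basis) from the fixture
get_fixture_series <- function() {
  if (is.null(.cache$series)) {
    fx <- get_fixture()
    b <- compute_surplus(fx$records)
    agg <- aggregate_budget(b, "typology", fx$truth, "agricultural")
    .cache$series <- member_mean(agg)
  }
  .cache$series
}

# minimal single wide record, overridable per field
one_record <- function(...) {
  rec <- data.frame(
    region_id = "r1", country = "DE", year = 2000, member_id = 1,
    sector = "agricultural", in_fert = 10, in_man = 5, in_dep = 2,
    in_bnf = 3, out_crops = 12, out_past = 3, ag_area = 1000,
    nonag_area = 500, stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) rec[[k]] <- over[[k]]
  rec
}
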