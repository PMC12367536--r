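#' Read a canonical long-format budget table
#'
#' The canonical interchange format is UTF-8 comma-delimited text with "."
#' decimal, a header row, and columns
#' `region_id,country,year,member_id,sector,variable,value` with `variable`
#' one of `in_fert,in_man,in_dep,in_bnf,out_crops,out_past,ag_area,
#' nonag_area`. Lines starting with `#` are provenance comments and are
#' skipped. Schema violations are reported with the offending row numbers.
#'
#' @param path file path.
#' @return a validated wide component-record table (one row per region x
#'   year x member x sector).
#' @export
read_budget_table <- function(path) {
  if (!file.exists(path)) stop_ns("no such file: %s", path)
  long <- data.table::fread(path, sep = ",", header = TRUE,
                            colClasses = list(character = c("region_id",
                                                            "country",
                                                            "sector",
                                                            "variable")))
  needed <- c("region_id", "country", "year", "member_id", "sector",
              "variable", "value")
  miss <- setdiff(needed, names(long))
  if (length(miss) > 0)
    stop_ns("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))

  bad <- which(!long$variable %in% BUDGET_VARIABLES)
  if (length(bad) > 0)
    stop_ns("unknown variable name(s) at row(s) %s: %s",
            paste(head(bad, 5), collapse = ", "),
            paste(unique(long$variable[head(bad, 5)]), collapse = ", "))
  bad <- which(!is.finite(long$value))
  if (length(bad) > 0)
    stop_ns("non-numeric or missing value at row(s) %s",
            paste(head(bad, 5), collapse = ", "))
  bad <- which(long$year < 1850 | long$year > 2030)
  if (length(bad) > 0)
    stop_ns("year outside 1850-2030 at row(s) %s",
            paste(head(bad, 5), collapse = ", "))
  bad <- which(!long$member_id %in% 1:16)
  if (length(bad) > 0)
    stop_ns("member_id outside 1-16 at row(s) %s",
            paste(head(bad, 5), collapse = ", "))
  dup <- which(duplicated(long[, c("region_id", "year", "member_id",
                                   "sector", "variable")]))
  if (length(dup) > 0)
    stop_ns("duplicate key at row(s) %s", paste(head(dup, 5), collapse = ", "))

  wide <- data.table::dcast(
    data.table::as.data.table(long),
    region_id + country + year + member_id + sector ~ variable,
    value.var = "value")
  miss_var <- setdiff(BUDGET_VARIABLES, names(wide))
  if (length(miss_var) > 0)
    stop_ns("table has no rows for variable(s): %s",
            paste(miss_var, collapse = ", "))
  data.table::setcolorder(wide, c(BUDGET_KEYS, BUDGET_VARIABLES))
  data.table::setorder(wide, region_id, year, member_id, sector)
  data.table::setDF(wide)
  validate_records(wide)
  wide
}

#' Write a budget table in the canonical long format
#'
#' @param records wide component-record table.
#' @param path output file path.
#' @param header optional provenance comment line(s) written as `#` lines.
#' @return `path`, invisibly.
#' @export
write_budget_table <- function(records, path, header = NULL) {
  validate_records(records)
  dt <- data.table::as.data.table(records)
  long <- data.table::melt(dt, id.vars = BUDGET_KEYS,
                           measure.vars = BUDGET_VARIABLES,
                           variable.name = "variable", value.name = "value",
                           variable.factor = FALSE)
  data.table::setorder(long, region_id, year, member_id, sector, variable)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a wide spreadsheet-layout table to canonical records
#'
#' Converter for the archived-data spreadsheet layout exported to delimited
#' text: one row per region x year x member x sector with one column per
#' variable (the same names as the canonical `variable` values). Returns
#' validated wide records; pair with [write_budget_table()] to produce the
#' canonical long file.
#'
#' @param x a data.frame in the wide layout, or a path to a delimited file.
#' @param sep field separator when `x` is a path.
#' @return validated wide component-record table.
#' @export
convert_wide_table <- function(x, sep = ",") {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.table(x, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  }
  miss <- setdiff(c(BUDGET_KEYS, BUDGET_VARIABLES), names(x))
  if (length(miss) > 0)
    stop_ns("wide layout is missing column(s): %s", paste(miss, collapse = ", "))
  x <- x[, c(BUDGET_KEYS, BUDGET_VARIABLES)]
  validate_records(x)
  x
}

#' Read or build a run configuration
#'
#' Run configurations are YAML files; values absent from the file fall
#' back to the package defaults. The configuration is fully serializable
#' and is echoed into the output directory of every CLI run.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied on top (e.g. from CLI flags).
#' @return a named list of class `ns_run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    input = NULL,
    output_dir = "nsurplus-out",
    seed = 1L,
    n_regions = 393L,
    baseline_window = c(2015L, 2019L),
    grid_step = 0.01,
    grid_tmp_mode = "improved",
    som = list(grid = c(2L, 2L), epochs = 500L, radius = c(1, 0.1),
               learning_rate = c(0.5, 0.01), init = "pca"),
    scenarios = scenario_presets(),
    scopes = "typology",
    log_level = "info"
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop_ns("no such config file: %s", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user$scenarios)) user$scenarios <-
        do.call(rbind, lapply(user$scenarios, as.data.frame))
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  class(cfg) <- "ns_run_config"
  cfg
}

# stable md5 of a configuration (used in output provenance headers)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  dump <- cfg
  class(dump) <- NULL
  if (is.data.frame(dump$scenarios))
    dump$scenarios <- lapply(seq_len(nrow(dump$scenarios)), function(i)
      as.list(dump$scenarios[i, ]))
  yaml::write_yaml(dump, tmp)
  unname(tools::md5sum(tmp))
}

# provenance header line carried by every output table
output_header <- function(cfg) {
  sprintf("nsurplus %s config_md5=%s",
          as.character(utils::packageVersion("nsurplus")), config_hash(cfg))
}

# write a data.frame as CSV with the provenance header
write_output <- function(df, path, cfg) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", output_header(cfg)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_output <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
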