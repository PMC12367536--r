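#' Ensemble member key
#'
#' The N budget is carried as a 16-member ensemble formed by crossing two
#' fertilizer-input reconstructions, four animal-manure reconstructions and
#' two pasture-removal reconstructions. This function enumerates the product
#' and fixes the member numbering used throughout the package (fertilizer
#' variant varies fastest, then manure, then pasture).
#'
#' @return a data.frame with columns `member_id` (1-16), `fert_variant` (1-2),
#'   `manure_variant` (1-4) and `pasture_variant` (1-2).
#' @export
#' @examples
#' ensemble_key()
ensemble_key <- function() {
  key <- expand.grid(
    fert_variant = 1:2, manure_variant = 1:4, pasture_variant = 1:2,
    KEEP.OUT.ATTRS = FALSE
  )
  key <- key[, c("fert_variant", "manure_variant", "pasture_variant")]
  data.frame(member_id = seq_len(nrow(key)), key)
}

# canonical component columns of a wide budget record table
BUDGET_COMPONENTS <- c("in_fert", "in_man", "in_dep", "in_bnf",
                       "out_crops", "out_past")
BUDGET_VARIABLES <- c(BUDGET_COMPONENTS, "ag_area", "nonag_area")
BUDGET_KEYS <- c("region_id", "country", "year", "member_id", "sector")
BUDGET_SECTORS <- c("agricultural", "non-agricultural")

# validate a wide component-record table; returns it invisibly
validate_records <- function(records, require_complete = TRUE) {
  miss <- setdiff(c(BUDGET_KEYS, BUDGET_VARIABLES), names(records))
  if (length(miss) > 0)
    stop_ns("budget records are missing columns: %s", paste(miss, collapse = ", "))
  bad_sector <- setdiff(unique(records$sector), BUDGET_SECTORS)
  if (length(bad_sector) > 0)
    stop_ns("unknown sector value(s): %s", paste(bad_sector, collapse = ", "))
  for (v in BUDGET_VARIABLES) {
    x <- records[[v]]
    if (anyNA(x)) {
      i <- which(is.na(x))[1L]
      stop_ns("missing %s for region %s, year %d, member %d",
              v, records$region_id[i], records$year[i], records$member_id[i])
    }
    if (any(x < 0)) {
      i <- which(x < 0)[1L]
      stop_ns("negative %s (%g) for region %s, year %d, member %d",
              v, x[i], records$region_id[i], records$year[i], records$member_id[i])
    }
  }
  if (any(records$ag_area + records$nonag_area <= 0))
    stop_ns("ag_area + nonag_area must be positive for every record")
  dt <- data.table::as.data.table(records)
  dup <- anyDuplicated(dt, by = BUDGET_KEYS)
  if (dup > 0)
    stop_ns("duplicate record for region %s, year %d, member %d, sector %s",
            records$region_id[dup], records$year[dup],
            records$member_id[dup], records$sector[dup])
  invisible(records)
}
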