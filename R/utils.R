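#' @importFrom stats coef lm predict prcomp qt sd setNames aggregate kmeans
#' @importFrom utils read.csv write.csv head tail
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ns <- function(...) stop(sprintf(...), call. = FALSE)
warn_ns <- function(...) warning(sprintf(...), call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Used to score how well the typology classification recovers the
#' generator's ground-truth archetype labels; 1 is perfect agreement,
#' values near 0 are chance-level.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single numeric value in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_ns("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # degenerate: single cluster both sides
  (sum_ij - expected) / (max_idx - expected)
}

# 3-year centred moving average; ends are left NA
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}
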