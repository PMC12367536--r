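#' Build the decadal feature matrix for typology classification
#'
#' For every region, computes decadal means (1850s-2010s, 17 decades by
#' default) of the twelve classification variables: the two fertilizer-input
#' reconstructions, the four manure-input reconstructions, biological
#' fixation, atmospheric deposition, the two N-output reconstructions
#' (pasture-removal variants), and the agricultural and non-agricultural
#' areas. Fluxes are taken on the total basis (both sectors combined, per
#' hectare of total area), mirroring the use of the total N surplus for
#' landscape classification. The matrix is then z-scored per column
#' (population standard deviation); all-constant columns are dropped with a
#' warning. Column centres and scales are stored for inversion.
#'
#' @param records wide component-record table (see [simulate_budget()]).
#' @param decades first years of the decades to use (default `seq(1850,
#'   2010, 10)`).
#' @return a numeric matrix (regions x features) of class `ns_features`
#'   with attributes `center`, `scale`, `region_id` and `raw` (the
#'   unscaled feature matrix).
#' @export
build_features <- function(records, decades = seq(1850, 2010, 10)) {
  dt <- data.table::as.data.table(records)
  dt[, decade := (year %/% 10L) * 10L]
  missing_dec <- setdiff(decades, unique(dt$decade))
  if (length(missing_dec) > 0)
    stop_ns("records do not cover decade(s): %s",
            paste(missing_dec, collapse = ", "))
  dt <- dt[decade %in% decades]
  key <- data.table::as.data.table(ensemble_key())
  dt <- merge(dt, key, by = "member_id")

  tot_area <- dt$ag_area + dt$nonag_area
  w <- data.table::fifelse(dt$sector == "agricultural", dt$ag_area,
                           dt$nonag_area)
  # per-ha-of-total-area contribution of each sector row; summing the two
  # sector rows of a (region, year, member) gives the total flux per total ha
  for (v in BUDGET_COMPONENTS)
    data.table::set(dt, j = paste0(v, "_c"), value = dt[[v]] * w / tot_area)

  rym <- dt[, .(
    in_fert = sum(in_fert_c), in_man = sum(in_man_c),
    in_dep = sum(in_dep_c), in_bnf = sum(in_bnf_c),
    out_tot = sum(out_crops_c + out_past_c),
    ag_area = ag_area[1], nonag_area = nonag_area[1],
    fert_variant = fert_variant[1], manure_variant = manure_variant[1],
    pasture_variant = pasture_variant[1]
  ), by = .(region_id, year, member_id, decade)]

  # the 12 variables: variant-resolved means over the relevant members
  per_region_decade <- rym[, {
    list(
      fert_v1 = mean(in_fert[fert_variant == 1]),
      fert_v2 = mean(in_fert[fert_variant == 2]),
      man_v1 = mean(in_man[manure_variant == 1]),
      man_v2 = mean(in_man[manure_variant == 2]),
      man_v3 = mean(in_man[manure_variant == 3]),
      man_v4 = mean(in_man[manure_variant == 4]),
      bnf = mean(in_bnf),
      dep = mean(in_dep),
      out_v1 = mean(out_tot[pasture_variant == 1]),
      out_v2 = mean(out_tot[pasture_variant == 2]),
      ag_area = mean(ag_area),
      nonag_area = mean(nonag_area)
    )
  }, by = .(region_id, decade)]

  vars <- c("fert_v1", "fert_v2", paste0("man_v", 1:4), "bnf", "dep",
            "out_v1", "out_v2", "ag_area", "nonag_area")
  wide <- data.table::dcast(per_region_decade, region_id ~ decade,
                            value.var = vars)
  regions <- wide$region_id
  m <- as.matrix(wide[, -1])
  if (anyNA(m)) stop_ns("missing feature values after decadal averaging")

  ctr <- colMeans(m)
  scl <- apply(m, 2, function(x) sqrt(mean((x - mean(x))^2)))  # population sd
  keep <- scl > 1e-10 * (abs(ctr) + 1e-10)  # constant up to rounding
  if (any(!keep))
    warn_ns("dropping %d all-constant feature column(s): %s",
            sum(!keep), paste(head(colnames(m)[!keep], 5), collapse = ", "))
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  rownames(z) <- regions
  structure(z, class = c("ns_features", class(z)),
            center = ctr[keep], scale = scl[keep],
            region_id = regions, raw = m)
}

# grid coordinates for a g1 x g2 node lattice
som_grid_coords <- function(g1, g2) {
  as.matrix(expand.grid(row = seq_len(g1), col = seq_len(g2)))
}

# squared Euclidean distances between rows of X and rows of W; clamped at
# zero against floating cancellation
cross_dist2 <- function(X, W) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(X)), rowSums(W^2)) - 2 * X %*% t(W)
  pmax(d2, 0)
}

#' Train a batch self-organizing map
#'
#' Deterministic batch-mode SOM on a small rectangular node lattice
#' (default 2x2). Each epoch assigns every region to its best-matching unit
#' (nearest node in Euclidean distance), forms the Gaussian
#' neighborhood-weighted mean of the data per node, and moves each node
#' toward that target by the current learning rate. Neighborhood radius and
#' learning rate decay linearly over the epochs. Node weights are
#' initialized on the plane of the first two principal components
#' (deterministic given the data), or randomly from the data range when
#' `init = "random"`.
#'
#' Batch updates are sums over data points, so the trained map is invariant
#' to the order of the rows.
#'
#' @param features numeric matrix (regions x features), typically from
#'   [build_features()].
#' @param grid `c(rows, cols)` of the node lattice (default `c(2, 2)`).
#' @param epochs number of batch epochs.
#' @param radius `c(initial, final)` Gaussian neighborhood radius in grid
#'   units; a radius of 0 restricts each update to the best-matching node.
#' @param learning_rate `c(initial, final)` blending weight of the batch
#'   target.
#' @param init `"pca"` (deterministic) or `"random"`.
#' @param seed integer seed, used only for random initialization.
#' @return an object of class `ns_som`: list with `weights` (nodes x
#'   features), `assignment` (data.frame `region_id,node`), `grid`,
#'   `coords`, and the training settings.
#' @export
train_som <- function(features, grid = c(2, 2), epochs = 500,
                      radius = c(1, 0.1), learning_rate = c(0.5, 0.01),
                      init = c("pca", "random"), seed = 1L) {
  init <- match.arg(init)
  X <- unclass(features)
  attr(X, "center") <- attr(X, "scale") <- attr(X, "raw") <- NULL
  X <- matrix(as.numeric(X), nrow = nrow(features),
              dimnames = dimnames(features))
  n <- nrow(X); p <- ncol(X)
  k <- prod(grid)
  if (n < k) stop_ns("need at least %d regions for a %dx%d map",
                     k, grid[1], grid[2])
  coords <- som_grid_coords(grid[1], grid[2])
  grid_d2 <- cross_dist2(coords, coords)

  if (init == "pca") {
    pc <- prcomp(X, center = FALSE, scale. = FALSE)
    u <- if (grid[1] > 1) seq(-1, 1, length.out = grid[1]) else 0
    v <- if (grid[2] > 1) seq(-1, 1, length.out = grid[2]) else 0
    sd1 <- pc$sdev[1]
    sd2 <- if (p >= 2 && length(pc$sdev) >= 2) pc$sdev[2] else 0
    dir1 <- pc$rotation[, 1]
    dir2 <- if (p >= 2 && ncol(pc$rotation) >= 2) pc$rotation[, 2] else
      rep(0, p)
    # spread nodes over the lattice axes along the two leading components;
    # for 1 x k grids only the first component is used
    W <- matrix(colMeans(X), k, p, byrow = TRUE)
    for (j in seq_len(k)) {
      a <- u[coords[j, 1]]; b <- v[coords[j, 2]]
      if (grid[1] == 1) { a <- 0; b <- v[coords[j, 2]] }
      axis1 <- if (grid[1] > 1) a else b
      axis2 <- if (grid[1] > 1) b else 0
      W[j, ] <- W[j, ] + axis1 * sd1 * dir1 + axis2 * sd2 * dir2
    }
  } else {
    set.seed(seed)
    W <- X[sample.int(n, k), , drop = FALSE]
  }

  for (e in seq_len(epochs)) {
    frac <- if (epochs == 1) 0 else (e - 1) / (epochs - 1)
    sigma <- radius[1] + frac * (radius[2] - radius[1])
    alpha <- learning_rate[1] + frac * (learning_rate[2] - learning_rate[1])
    if (alpha == 0) next
    d2 <- cross_dist2(X, W)
    bmu <- max.col(-d2, ties.method = "first")
    H <- if (sigma > 0) exp(-grid_d2 / (2 * sigma^2)) else diag(k)
    counts <- tabulate(bmu, nbins = k)
    S <- matrix(0, k, p)
    present <- which(counts > 0)
    rs <- rowsum(X, group = bmu)
    S[as.integer(rownames(rs)), ] <- rs
    numer <- H %*% S
    denom <- as.numeric(H %*% counts)
    ok <- denom > 0
    target <- W
    target[ok, ] <- numer[ok, , drop = FALSE] / denom[ok]
    W <- W + alpha * (target - W)
  }

  d2 <- cross_dist2(X, W)
  bmu <- max.col(-d2, ties.method = "first")
  if (length(unique(bmu)) < k)
    warn_ns("SOM converged with %d empty node(s); nodes retained",
            k - length(unique(bmu)))
  structure(list(
    weights = W,
    assignment = data.frame(region_id = rownames(X) %||%
                              as.character(seq_len(n)), node = bmu),
    grid = grid, coords = coords, epochs = epochs, radius = radius,
    learning_rate = learning_rate, init = init, seed = seed
  ), class = "ns_som")
}

#' @export
print.ns_som <- function(x, ...) {
  cat(sprintf("batch SOM: %dx%d nodes, %d epochs, %s init\n",
              x$grid[1], x$grid[2], x$epochs, x$init))
  print(table(node = x$assignment$node))
  invisible(x)
}

#' Davies-Bouldin index of a partition
#'
#' Cluster-validity score: the mean over clusters of the worst-case ratio
#' (S_i + S_j) / M_ij, where S is the mean Euclidean distance of a
#' cluster's points to its centroid and M is the distance between the two
#' centroids. Lower values indicate better-separated clusters; the optimal
#' node count is taken at the minimum.
#'
#' @param features numeric matrix (points x dims).
#' @param assignment integer/factor vector of cluster ids, one per row.
#' @return the DBI (single numeric).
#' @export
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' davies_bouldin(x, c(1, 1, 2, 2))  # ~0.0707
davies_bouldin <- function(features, assignment) {
  X <- as.matrix(features)
  g <- as.integer(factor(assignment))
  k <- max(g)
  if (k < 2) stop_ns("Davies-Bouldin index needs at least 2 clusters")
  centroids <- rowsum(X, g) / as.numeric(table(g))
  S <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums((X[g == i, , drop = FALSE] -
                         matrix(centroids[i, ], sum(g == i), ncol(X),
                                byrow = TRUE))^2)))
  }, numeric(1))
  M <- sqrt(cross_dist2(centroids, centroids))
  if (any(M[upper.tri(M)] == 0))
    stop_ns("identical cluster centroids; Davies-Bouldin undefined")
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

# lattice factorization used when scanning candidate node counts
grid_for_k <- function(k) {
  switch(as.character(k),
         "2" = c(1, 2), "3" = c(1, 3), "4" = c(2, 2),
         "5" = c(1, 5), "6" = c(2, 3),
         c(1, k))
}

#' Scan candidate typology counts with the Davies-Bouldin index
#'
#' Trains a SOM for each candidate node count (1xk or near-square lattice
#' factorizations) and reports the Davies-Bouldin index of the resulting
#' partition. The row attaining the minimum is flagged; the choice is
#' reported, not enforced.
#'
#' @param features feature matrix (see [build_features()]).
#' @param k_candidates candidate node counts (default 2:6).
#' @param ... passed to [train_som()].
#' @return data.frame `k, grid, n_nonempty, dbi, is_minimum`.
#' @export
select_k <- function(features, k_candidates = 2:6, ...) {
  res <- list()
  for (k in k_candidates) {
    if (k > nrow(features)) {
      warn_ns("skipping k = %d (> %d regions)", k, nrow(features))
      next
    }
    grid <- grid_for_k(k)
    som <- train_som(features, grid = grid, ...)
    nodes <- som$assignment$node
    n_nonempty <- length(unique(nodes))
    dbi <- if (n_nonempty >= 2)
      tryCatch(davies_bouldin(features, nodes), error = function(e) NA_real_)
    else NA_real_
    res[[length(res) + 1]] <- data.frame(
      k = k, grid = paste(grid, collapse = "x"),
      n_nonempty = n_nonempty, dbi = dbi)
  }
  out <- do.call(rbind, res)
  if (all(is.na(out$dbi))) {
    warn_ns("all candidate partitions degenerate; no DBI minimum")
    out$is_minimum <- FALSE
  } else {
    # flag the most parsimonious k attaining the minimum (ties can arise
    # when a larger map converges with empty nodes onto the same partition)
    out$is_minimum <- FALSE
    out$is_minimum[which(out$dbi <= min(out$dbi, na.rm = TRUE) + 1e-12)[1]] <-
      TRUE
  }
  out
}

#' Label SOM nodes as N-surplus typologies
#'
#' Rule-based mapping of the four trained nodes to the typology labels.
#' The cluster with the lowest mean agricultural-area fraction becomes NAT
#' (natural landscapes). Among the remaining agricultural clusters, the one
#' with the highest mean manure share of total N inputs becomes MAN, the
#' one with the highest fertilizer share becomes FERT, and the remainder is
#' MOD. If one cluster wins both the manure and the fertilizer rule the
#' tie is broken by surplus magnitude (the higher-surplus cluster is MAN)
#' when that resolves the collision, otherwise an error with diagnostics is
#' raised.
#'
#' @param som a trained `ns_som` with 4 non-empty nodes (see
#'   [train_som()]).
#' @param records the component-record table the features were built from.
#' @return a list of class `ns_typology`: `assignment` (data.frame
#'   `region_id,node,label`), `node_labels`, and `diagnostics` (per-node ag
#'   fraction, input shares, mean surplus).
#' @export
label_typologies <- function(som, records) {
  nodes <- som$assignment
  if (length(unique(nodes$node)) != 4)
    stop_ns("typology labelling requires 4 non-empty clusters (got %d)",
            length(unique(nodes$node)))
  dt <- data.table::as.data.table(records)
  dt <- merge(dt, data.table::as.data.table(nodes), by = "region_id")

  ag <- dt[sector == "agricultural"]
  stats <- ag[, {
    tot_in <- in_fert + in_man + in_dep + in_bnf
    list(ag_frac = mean(ag_area / (ag_area + nonag_area)),
         man_share = sum(in_man) / sum(tot_in),
         fert_share = sum(in_fert) / sum(tot_in),
         surplus = mean(tot_in - out_crops - out_past))
  }, by = node]
  data.table::setorder(stats, node)

  nat <- stats$node[which.min(stats$ag_frac)]
  rest <- stats[node != nat]
  man <- rest$node[which.max(rest$man_share)]
  fert <- rest$node[which.max(rest$fert_share)]
  if (man == fert) {
    # tie-break by surplus magnitude: the colliding node keeps MAN only if
    # it also has the highest surplus; FERT then falls to the runner-up
    alt_fert <- setdiff(rest$node[order(-rest$fert_share)], man)[1]
    if (rest$surplus[rest$node == man] >=
        max(rest$surplus[rest$node != man])) {
      fert <- alt_fert
    } else {
      stop_ns(paste0(
        "label rule collision: node %d wins both MAN and FERT ",
        "(man_share %.2f, fert_share %.2f); inspect diagnostics"),
        man, rest$man_share[rest$node == man],
        rest$fert_share[rest$node == man])
    }
  }
  mod <- setdiff(rest$node, c(man, fert))
  node_labels <- setNames(character(4), sort(stats$node))
  node_labels[as.character(nat)] <- "NAT"
  node_labels[as.character(man)] <- "MAN"
  node_labels[as.character(fert)] <- "FERT"
  node_labels[as.character(mod)] <- "MOD"

  assignment <- data.frame(
    region_id = nodes$region_id, node = nodes$node,
    label = unname(node_labels[as.character(nodes$node)]))
  stats <- data.table::setDF(stats)
  stats$label <- unname(node_labels[as.character(stats$node)])
  structure(list(assignment = assignment, node_labels = node_labels,
                 diagnostics = stats),
            class = "ns_typology")
}

#' @export
print.ns_typology <- function(x, ...) {
  cat("N-surplus typology assignment\n")
  print(table(x$assignment$label))
  invisible(x)
}
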