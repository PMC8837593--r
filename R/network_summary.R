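#' Region-to-network assignment table
#'
#' @param region integer region indices (one row per retained region).
#' @param network network label per region.
#' @param drop optional integer vector of region indices to exclude from all
#'   network-level summaries (e.g. brain-stem regions).
#' @return object of class `network_assignment`.
#' @export
network_assignment <- function(region, network, drop = NULL) {
  region <- as.integer(region)
  if (anyDuplicated(region)) stop_invalid("duplicated region id in assignment")
  if (anyNA(region) || anyNA(network)) stop_invalid("assignment must not contain NA")
  structure(list(table = data.frame(region = region,
                                    network = as.character(network)),
                 drop = as.integer(drop)),
            class = "network_assignment")
}

#' Round-robin synthetic network assignment
#'
#' Deals regions 1..n into `n_networks` labels `net01`, `net02`, ... in
#' order; a stand-in for an atlas-derived table when working with synthetic
#' cohorts.
#'
#' @param n_regions number of regions.
#' @param n_networks number of network labels (default 4).
#' @return a [network_assignment()].
#' @export
synthetic_network_assignment <- function(n_regions, n_networks = 4) {
  network_assignment(seq_len(n_regions),
                     sprintf("net%02d", rep(seq_len(n_networks),
                                            length.out = n_regions)))
}

#' Down-sample region-pair accuracies to a network-pair matrix
#'
#' Entry (A, B) of the output is the arithmetic mean of the chosen accuracy
#' over all region pairs with one region in network A and the other in B
#' (both in A for the diagonal). Regions on the assignment's drop list are
#' excluded before averaging; network pairs with no contributing region pair
#' are `NA`.
#'
#' @param results an `mtpa_results` from [run_all_connections()] (or any
#'   data.frame with columns `i`, `j` and the accuracy column).
#' @param assignment a [network_assignment()] covering every region present
#'   in the results (dropped regions excepted).
#' @param metric accuracy column to average, default `"test_accuracy"`.
#' @return object of class `network_accuracy`: list with `accuracy`
#'   (symmetric networks x networks matrix), `counts` (contributing pair
#'   counts), `networks`.
#' @export
downsample_accuracy <- function(results, assignment, metric = "test_accuracy") {
  stopifnot(inherits(assignment, "network_assignment"))
  res <- if (inherits(results, "mtpa_results")) results$results else results
  if (!metric %in% names(res)) stop_invalid("no column '%s' in results", metric)
  keep <- !(res$i %in% assignment$drop) & !(res$j %in% assignment$drop)
  res <- res[keep, , drop = FALSE]
  net_of <- stats::setNames(assignment$table$network, assignment$table$region)
  regions <- unique(c(res$i, res$j))
  missing <- regions[!regions %in% assignment$table$region]
  if (length(missing) > 0L)
    stop_invalid("region(s) without network assignment: %s",
                 paste(sort(missing), collapse = ", "))
  nets <- sort(unique(assignment$table$network))
  K <- length(nets)
  acc <- matrix(NA_real_, K, K, dimnames = list(nets, nets))
  cnt <- matrix(0L, K, K, dimnames = list(nets, nets))
  a <- net_of[as.character(res$i)]
  b <- net_of[as.character(res$j)]
  lo <- pmin(a, b); hi <- pmax(a, b)
  agg <- tapply(res[[metric]], list(lo, hi), mean)
  n_agg <- tapply(res[[metric]], list(lo, hi), length)
  for (x in rownames(agg)) for (y in colnames(agg)) {
    v <- agg[x, y]
    if (!is.na(v)) {
      acc[x, y] <- acc[y, x] <- v
      cnt[x, y] <- cnt[y, x] <- n_agg[x, y]
    }
  }
  structure(list(accuracy = acc, counts = cnt, networks = nets),
            class = "network_accuracy")
}

#' Threshold a network accuracy matrix into a binary configuration
#'
#' An entry of the configuration is 1 iff the mean accuracy reaches the
#' threshold; the convention is inclusive (`>=`), so e.g. an entry of exactly
#' 0.70 survives a 0.70 threshold. Missing (empty) entries become 0.
#'
#' @param netacc a `network_accuracy` from [downsample_accuracy()] (or a
#'   plain symmetric numeric matrix).
#' @param threshold accuracy cutoff in (0.5, 1); default 0.70.
#' @return object of class `thresholded_config`: list with binary `mask`
#'   and `threshold`.
#' @export
threshold_matrix <- function(netacc, threshold = 0.70) {
  if (!is_scalar_number(threshold) || threshold <= 0.5 || threshold >= 1)
    stop_invalid("threshold must be in (0.5, 1)")
  m <- if (inherits(netacc, "network_accuracy")) netacc$accuracy else as.matrix(netacc)
  mask <- (m >= threshold) * 1L
  mask[is.na(mask)] <- 0L
  structure(list(mask = mask, threshold = threshold),
            class = "thresholded_config")
}

#' Dice similarity of two thresholded network configurations
#'
#' `2 |A intersect B| / (|A| + |B|)` over the suprathreshold entries of the
#' upper triangle including the diagonal (so each symmetric entry and each
#' intranetwork entry counts once). A value of 0 means no overlapping
#' connections; 1 means identical nonempty configurations. When both
#' configurations are empty the coefficient is undefined and an error is
#' raised rather than silently returning 0.
#'
#' @param a,b `thresholded_config` objects (or binary matrices) of equal
#'   shape.
#' @return dice coefficient in \[0, 1\].
#' @export
dice_similarity <- function(a, b) {
  ma <- if (inherits(a, "thresholded_config")) a$mask else as.matrix(a)
  mb <- if (inherits(b, "thresholded_config")) b$mask else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop_invalid("configurations differ in shape")
  ut <- upper.tri(ma, diag = TRUE)
  A <- ma[ut] != 0
  B <- mb[ut] != 0
  if (!any(A) && !any(B))
    stop_invalid("dice undefined: both configurations are empty")
  2 * sum(A & B) / (sum(A) + sum(B))
}
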