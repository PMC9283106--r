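#' Nodal flexibility of a multilayer partition
#'
#' For every region, the fraction of consecutive layer pairs at which its
#' community label changes: `f_i = #\{s : g_is != g_i,s+1\} / (L - 1)`. Labels
#' are compared raw within the one supra-partition, which is valid because the
#' multilayer optimizer assigns labels jointly across layers.
#'
#' @param partition A `multilayer_partition` with a `labels_matrix`, or an
#'   N x L label matrix.
#' @return A `flexibility_profile`: list with `f` (named per-region vector in
#'   \[0, 1\]), `F` (global mean), `L`, plus feature-set/ordering identifiers
#'   when present on the partition.
#' @examples
#' labs <- rbind(c(1, 1, 2, 2, 3), c(1, 1, 1, 1, 1))
#' nodal_flexibility(labs)$f  # 0.5, 0
#' @export
nodal_flexibility <- function(partition) {
  g <- if (inherits(partition, "multilayer_partition")) {
    if (is.null(partition$labels_matrix))
      stop("partition carries no labels_matrix; use sample_best_partition()")
    partition$labels_matrix
  } else partition
  stopifnot(is.matrix(g))
  L <- ncol(g)
  if (L < 2L) stop("flexibility needs at least 2 layers")
  changes <- g[, -1L, drop = FALSE] != g[, -L, drop = FALSE]
  f <- rowMeans(changes)
  structure(list(f = f, F = mean(f), L = L,
                 feature_set = if (inherits(partition, "multilayer_partition"))
                   partition$feature_set else NULL,
                 ordering = if (inherits(partition, "multilayer_partition"))
                   partition$ordering else NULL),
            class = "flexibility_profile")
}

#' Global flexibility
#'
#' Arithmetic mean of nodal flexibility over all regions,
#' `F = (1/N) sum_i f_i`.
#'
#' @param f Numeric vector of nodal flexibilities (nonempty), or a
#'   `flexibility_profile`.
#' @return Global flexibility.
#' @export
global_flexibility <- function(f) {
  if (inherits(f, "flexibility_profile")) f <- f$f
  if (length(f) == 0L) stop("empty flexibility vector")
  mean(f)
}

#' Aggregate nodal flexibility over lobes or cognitive networks
#'
#' Averages nodal flexibility over the regions of each cortical lobe (6
#' divisions: cingulate, frontal, insular, occipital, parietal, temporal) or
#' of each cognitive network (DMN, SN, VIS, CEN; regions labeled `"none"` are
#' excluded from the cognitive-network aggregation).
#'
#' @param f Nodal flexibility vector (atlas region order) or
#'   `flexibility_profile`.
#' @param atlas The matching `atlas_spec`.
#' @param grouping `"lobe"` or `"cognitive_network"`.
#' @return Data frame with `group`, `n_regions`, `mean_f` (NA for an empty
#'   group).
#' @export
aggregate_flexibility <- function(f, atlas,
                                  grouping = c("lobe", "cognitive_network")) {
  if (inherits(f, "flexibility_profile")) f <- f$f
  grouping <- match.arg(grouping)
  stopifnot(inherits(atlas, "atlas_spec"), length(f) == atlas$N)
  if (grouping == "lobe") {
    labels <- atlas$lobe
    levels <- sort(unique(atlas$lobe))
  } else {
    labels <- atlas$cognitive_network
    levels <- c("DMN", "SN", "VIS", "CEN")
    keep <- labels != "none"
    f <- f[keep]
    labels <- labels[keep]
  }
  out <- data.frame(group = levels,
                    n_regions = vapply(levels, function(g) sum(labels == g), 0L),
                    mean_f = vapply(levels, function(g)
                      if (any(labels == g)) mean(f[labels == g]) else NA_real_,
                      0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank flexible and inflexible hubs across feature-set networks
#'
#' For each feature set, selects the `floor(pct * N)` regions with highest
#' (flexible hubs) and lowest (inflexible hubs) nodal flexibility — 7 regions
#' per tail at the default 5% of 148 — then merges the per-set lists into
#' de-duplicated union lists with per-region provenance. Ties in flexibility
#' are broken by region order.
#'
#' @param profiles Named list of `flexibility_profile`s (one per feature set),
#'   all on the same atlas.
#' @param pct Tail fraction (default 0.05).
#' @return A `hub_table`: list with `per_set` (flexible/inflexible region
#'   vectors per feature set), `flexible` and `inflexible` merged data frames
#'   (region, feature_sets), `k`, `pct`.
#' @export
rank_hubs <- function(profiles, pct = 0.05) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- paste0("set", seq_along(profiles))
  ns <- vapply(profiles, function(p) length(p$f), 0L)
  if (length(unique(ns)) != 1L)
    stop("all profiles must share an atlas (equal region counts)")
  N <- ns[[1]]
  k <- floor(pct * N)
  if (k < 1L) stop("pct * N < 1: no hubs selectable")
  per_set <- lapply(profiles, function(p) {
    f <- p$f
    idx <- seq_along(f)
    regions <- if (!is.null(names(f))) names(f) else as.character(idx)
    list(flexible = regions[order(-f, idx)[seq_len(k)]],
         inflexible = regions[order(f, idx)[seq_len(k)]])
  })
  merge_side <- function(side) {
    all <- unlist(lapply(names(per_set), function(s) per_set[[s]][[side]]))
    prov <- lapply(names(per_set), function(s)
      data.frame(region = per_set[[s]][[side]], feature_set = s,
                 stringsAsFactors = FALSE))
    prov <- do.call(rbind, prov)
    agg <- stats::aggregate(feature_set ~ region, prov,
                            function(x) paste(x, collapse = ","))
    agg <- agg[match(unique(all), agg$region), ]
    rownames(agg) <- NULL
    names(agg) <- c("region", "feature_sets")
    agg
  }
  structure(list(per_set = per_set, flexible = merge_side("flexible"),
                 inflexible = merge_side("inflexible"), k = k, pct = pct),
            class = "hub_table")
}

#' @export
print.hub_table <- function(x, ...) {
  cat(sprintf("<hub_table> top/bottom %d regions (pct = %g) over %d feature set(s)\n",
              x$k, x$pct, length(x$per_set)))
  cat("  merged flexible:  ", paste(x$flexible$region, collapse = ", "), "\n")
  cat("  merged inflexible:", paste(x$inflexible$region, collapse = ", "), "\n")
  invisible(x)
}

# Per-node flexibility table with atlas annotations (tidy export).
#' Tidy nodal flexibility table
#'
#' @param profile A `flexibility_profile` on `atlas`'s region order.
#' @param atlas The matching `atlas_spec`.
#' @param ... Extra constant columns (e.g. feature_set, ordering,
#'   bootstrap_id).
#' @return Data frame with region, f, lobe, cognitive_network and any extras.
#' @export
flexibility_table <- function(profile, atlas, ...) {
  stopifnot(inherits(atlas, "atlas_spec"))
  f <- if (inherits(profile, "flexibility_profile")) profile$f else profile
  stopifnot(length(f) == atlas$N)
  extras <- list(...)
  out <- data.frame(region = atlas$regions, f = unname(f), lobe = atlas$lobe,
                    cognitive_network = atlas$cognitive_network,
                    stringsAsFactors = FALSE)
  for (nm in names(extras)) out[[nm]] <- extras[[nm]]
  out
}
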