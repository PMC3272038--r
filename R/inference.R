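#' Null distribution of ALE under random spatial association
#'
#' The null hypothesis is a random spatial association between experiments:
#' a null ALE value arises by drawing one masked voxel independently and
#' uniformly from each MA map and taking the union of the drawn values,
#' exactly as for the spatially contingent voxels in the true analysis.
#' `null_from_sampling` estimates this distribution by Monte-Carlo draws;
#' `null_from_convolution` computes it exactly by iterative histogram
#' combination of the per-map value distributions on a common bin grid.
#'
#' @param ma_maps non-empty list of MA [probability_volume()]s.
#' @param mask an [analysis_mask()] on the same grid.
#' @param n_draws number of Monte-Carlo draws (>= 1).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param bin_width histogram bin width in ALE units, in (0, 0.01];
#'   default 1e-5.
#' @return an object of class `null_histogram` with fields `bin_width`,
#'   `weights` (per-bin mass or counts, bin i spanning value i*bin_width),
#'   `survival` (P(ALE_null >= bin value)), `total_mass` (draw count, or 1
#'   for the exact mode) and `mode`.
#' @export
null_from_sampling <- function(ma_maps, mask, n_draws = 1e5, seed = NULL,
                               bin_width = 1e-5) {
    if (n_draws < 1) stop("n_draws must be >= 1")
    check_bin_width(bin_width)
    if (!length(ma_maps)) stop("need at least one MA map")
    if (!is.null(seed)) set.seed(seed)
    keep <- mask$include
    prod_term <- rep(1, n_draws)
    for (m in ma_maps) {
        stop_if_grid_mismatch(m$grid, mask$grid, "MA map and mask")
        vals <- m$values[keep]
        prod_term <- prod_term * (1 - vals[sample.int(length(vals), n_draws,
                                                      replace = TRUE)])
    }
    draws <- 1 - prod_term
    idx <- as.integer(round(draws / bin_width))
    counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
    new_null_histogram(bin_width, counts, total_mass = n_draws,
                       mode = "sampling")
}

#' @rdname null_from_sampling
#' @export
null_from_convolution <- function(ma_maps, mask, bin_width = 1e-5) {
    check_bin_width(bin_width)
    if (!length(ma_maps)) stop("need at least one MA map")
    histos <- lapply(ma_maps, function(m) {
        stop_if_grid_mismatch(m$grid, mask$grid, "MA map and mask")
        ma_value_histogram(m$values[mask$include], bin_width)
    })
    null_from_histograms(histos, bin_width)
}

# Sparse (bin index, probability) histogram of one map's masked values.
ma_value_histogram <- function(values, bin_width) {
    idx <- as.integer(round(values / bin_width))
    counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
    nz <- which(counts > 0L)
    list(idx = nz - 1L, w = counts[nz] / length(values))
}

null_from_histograms <- function(histos, bin_width) {
    max_bins <- as.integer(ceiling(1 / bin_width)) + 2L
    w <- cpp_null_union(lapply(histos, `[[`, "idx"),
                        lapply(histos, `[[`, "w"), bin_width, max_bins)
    if (abs(sum(w) - 1) > 1e-9)
        stop("null_from_convolution: total mass deviates from 1")
    new_null_histogram(bin_width, w, total_mass = 1, mode = "convolution")
}

new_null_histogram <- function(bin_width, weights, total_mass, mode) {
    surv <- rev(cumsum(rev(weights)))
    structure(list(bin_width = bin_width, weights = weights,
                   survival = surv, total_mass = total_mass, mode = mode),
              class = "null_histogram")
}

#' @export
print.null_histogram <- function(x, ...) {
    cat(sprintf("null_histogram (%s): %d bins of width %g, mass %g\n",
                x$mode, length(x$weights), x$bin_width, x$total_mass))
    invisible(x)
}

check_bin_width <- function(bin_width) {
    if (bin_width <= 0 || bin_width > 0.01)
        stop("bin_width must be in (0, 0.01]")
    invisible(bin_width)
}

#' Survival function of a null histogram
#'
#' `P(ALE_null >= a)`, evaluated with the same binning used to build the
#' histogram so that ties ("equal or higher") count toward the exceedance.
#'
#' @param null a `null_histogram`.
#' @param a ALE value(s).
#' @return survival probabilities (for sampling mode, exceedance counts
#'   divided by the number of draws).
#' @export
null_survival <- function(null, a) {
    idx <- as.integer(round(a / null$bin_width)) + 1L
    idx[idx < 1L] <- 1L
    out <- numeric(length(idx))
    inside <- idx <= length(null$survival)
    out[inside] <- null$survival[idx[inside]] / null$total_mass
    out
}

# Exceedance counts for sampling-mode nulls (before the add-one rule).
null_exceed_count <- function(null, a) {
    idx <- as.integer(round(a / null$bin_width)) + 1L
    idx[idx < 1L] <- 1L
    out <- numeric(length(idx))
    inside <- idx <= length(null$survival)
    out[inside] <- null$survival[idx[inside]]
    out
}

#' Voxel-wise p-values of an ALE map
#'
#' The p-value of an observed ALE score is the proportion of equal or higher
#' values under the null distribution. In sampling mode the add-one rule
#' `p = (k + 1) / (n_draws + 1)` keeps p strictly positive; in the exact
#' convolution mode `p = S(ALE)`, with ALE clamped to the null's support so
#' that binning drift cannot produce p = 0.
#'
#' @param ale an ALE [probability_volume()].
#' @param null a `null_histogram`.
#' @return a volume (list with `grid`, `values`) of p-values in (0, 1].
#' @export
voxel_p <- function(ale, null) {
    a <- ale$values
    if (null$mode == "sampling") {
        k <- null_exceed_count(null, a)
        p <- (k + 1) / (null$total_mass + 1)
    } else {
        amax <- (length(null$weights) - 1L) * null$bin_width
        p <- null_survival(null, pmin(a, amax))
        # guard the floating-point mass sum: p must stay in (0, 1]
        p <- pmin(pmax(p, .Machine$double.xmin), 1)
    }
    structure(list(grid = ale$grid, values = array(p, dim = ale$grid$shape)),
              class = "probability_volume")
}

#' Transform p-values to Z-scores for display
#'
#' `z = qnorm(1 - p)`, clamped to +/- 8.2 (beyond which double-precision
#' normal quantiles are unreliable) so maps stay finite.
#'
#' @param p a p-value volume (from [voxel_p()]) or numeric array.
#' @return matching volume (or array) of Z-scores.
#' @export
z_transform <- function(p) {
    vol <- inherits(p, "probability_volume")
    vals <- if (vol) p$values else p
    z <- qnorm(vals, lower.tail = FALSE)
    z[z > 8.2] <- 8.2
    z[z < -8.2] <- -8.2
    if (!vol) return(z)
    structure(list(grid = p$grid, values = z), class = "probability_volume")
}

# Smallest ALE value (on the bin grid) whose null p falls below p_thresh;
# voxels with ALE >= the returned value are exactly those with p < p_thresh.
ale_threshold_for_p <- function(null, p_thresh) {
    if (null$mode == "sampling")
        pvals <- (null$survival + 1) / (null$total_mass + 1)
    else
        pvals <- null$survival / null$total_mass
    i <- which(pvals < p_thresh)
    if (!length(i)) return(Inf)
    (min(i) - 1L - 0.5) * null$bin_width
}

#' Relocate a pool's foci uniformly within the mask
#'
#' One permutation draw of the random-spatial-association null: every
#' experiment keeps its identity, subject count and focus count, but each
#' focus is moved to a masked voxel centre drawn independently and
#' uniformly. Mainly useful for inspecting the permutation scheme; the
#' permutation loop of [cluster_fwe_threshold()] performs the same
#' relocation in compiled code.
#'
#' @param pool an [experiment_pool()].
#' @param mask an [analysis_mask()].
#' @return a relocated [experiment_pool()].
#' @export
permute_pool <- function(pool, mask) {
    centers <- mask_voxel_centers(mask)
    exps <- lapply(pool$experiments, function(e) {
        pick <- sample.int(nrow(centers), nrow(e$foci), replace = TRUE)
        experiment(e$id, e$n_subjects, centers[pick, , drop = FALSE],
                   space = e$space, effect_sign = e$effect_sign, tags = e$tags)
    })
    experiment_pool(pool$name, unname(exps))
}

#' Cluster-extent threshold controlling family-wise error
#'
#' Estimates the null distribution of the maximum supra-threshold cluster
#' extent by permutation: in each permutation every experiment's foci are
#' relocated to voxels drawn independently and uniformly within the mask
#' (per-experiment focus and subject counts preserved), the ALE map is
#' recomputed, thresholded at the cluster-forming p (translated once, via
#' the exact convolution null of the observed MA maps, into its ALE
#' equivalent), and the largest surviving component recorded. The returned
#' extent is the smallest cluster size whose null exceedance probability is
#' at most `alpha` — the (1 - alpha) quantile of the max-extent null,
#' rounded up through ties, and at least 1.
#'
#' @param pool an [experiment_pool()].
#' @param grid a [grid_spec()].
#' @param mask an [analysis_mask()] on `grid`.
#' @param params a [kernel_params()].
#' @param cluster_forming_p voxel-level cluster-forming threshold in (0, 1);
#'   default 0.001, the field-standard companion of cluster-level FWE.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha family-wise error level in (0, 0.5); default 0.05.
#' @param seed integer seed (deterministic permutations when given).
#' @param combine per-experiment focus combination rule.
#' @param connectivity cluster connectivity, one of 6, 18, 26.
#' @param bin_width null histogram bin width.
#' @param null optional precomputed convolution `null_histogram` of the
#'   observed MA maps (avoids recomputation inside [run_meta_analysis()]).
#' @return integer minimum cluster extent (voxels), with attributes
#'   `null_max_extents` (the permutation distribution) and `crit_ale`.
#' @export
cluster_fwe_threshold <- function(pool, grid, mask, params = kernel_params(),
                                  cluster_forming_p = 0.001, n_perm = 1000,
                                  alpha = 0.05, seed = NULL,
                                  combine = c("union", "max"),
                                  connectivity = 26, bin_width = 1e-5,
                                  null = NULL) {
    combine <- match.arg(combine)
    if (cluster_forming_p <= 0 || cluster_forming_p >= 1)
        stop("cluster_forming_p must be in (0, 1)")
    if (n_perm < 100) stop("n_perm must be >= 100")
    if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
    connectivity <- match_connectivity(connectivity)
    stop_if_grid_mismatch(grid, mask$grid, "grid and mask")
    if (is.null(null)) {
        ma <- lapply(pool$experiments, compute_ma_map, grid = grid,
                     params = params, combine = combine)
        null <- null_from_convolution(ma, mask, bin_width)
    }
    crit <- ale_threshold_for_p(null, cluster_forming_p)
    kernels <- kernels_for_pool(pool, grid, params)
    if (!is.null(seed)) set.seed(seed)
    max_ext <- cpp_fwe_perm(grid$shape, mask_flat0(mask),
                            as.logical(mask$include),
                            vapply(pool$experiments,
                                   function(e) nrow(e$foci), 0L),
                            kernels$values, kernels$index0, crit,
                            connectivity, as.integer(n_perm),
                            combine == "union")
    thr <- min_extent_for_alpha(max_ext, alpha)
    structure(thr, null_max_extents = max_ext, crit_ale = crit)
}

# Smallest integer extent c with P_null(max extent >= c) <= alpha, at
# least 1. The observed arrangement is itself one realisation of the
# relocation scheme, so it is counted into the exceedance with the standard
# add-one permutation correction: (k + 1) / (n_perm + 1) <= alpha.
min_extent_for_alpha <- function(max_extents, alpha) {
    n <- length(max_extents)
    cand <- sort(unique(c(1L, max_extents + 1L, max_extents[max_extents > 0])))
    for (c in cand)
        if ((sum(max_extents >= c) + 1) / (n + 1) <= alpha)
            return(as.integer(c))
    as.integer(max(max_extents) + 1L)
}

# Unique kernels (flattened values) plus a per-experiment 0-based index,
# for the compiled permutation loop.
kernels_for_pool <- function(pool, grid, params) {
    ns <- vapply(pool$experiments, `[[`, 0L, "n_subjects")
    uniq <- sort(unique(ns))
    built <- lapply(uniq, function(n)
        build_kernel(combined_sigma(n, params), grid$spacing, params))
    list(values = lapply(built, function(k) as.numeric(k$values)),
         index0 = match(ns, uniq) - 1L)
}

match_connectivity <- function(connectivity) {
    connectivity <- as.integer(connectivity)
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("connectivity must be one of 6, 18, 26")
    connectivity
}

#' Apply cluster-forming and extent thresholds
#'
#' Voxels with `p < cluster_forming_p` are grouped into connected
#' components; components with at least `min_cluster_extent` voxels survive.
#' Surviving voxels keep their Z-score, everything else is background.
#'
#' @param ale,p,z volumes on one grid (ALE scores, p-values, Z-scores).
#' @param cluster_forming_p voxel-level threshold.
#' @param min_cluster_extent minimum surviving component size, voxels.
#' @param connectivity one of 6, 18, 26.
#' @param fwe_alpha the FWE level the extent was calibrated at (recorded in
#'   the result).
#' @return an object of class `significance_maps`: the input maps, the
#'   thresholds, and `thresholded`, a `thresholded_map` (Z on significant
#'   voxels, NA background, plus the logical `significant` array).
#' @export
threshold_maps <- function(ale, p, z, cluster_forming_p = 0.001,
                           min_cluster_extent = 1, connectivity = 26,
                           fwe_alpha = NA_real_) {
    stop_if_grid_mismatch(ale$grid, p$grid, "ALE and p maps")
    stop_if_grid_mismatch(ale$grid, z$grid, "ALE and z maps")
    connectivity <- match_connectivity(connectivity)
    supra <- p$values < cluster_forming_p
    labels <- label_clusters(supra, connectivity, grid = ale$grid)
    keep_ids <- which(tabulate(labels$values[labels$values > 0]) >=
                      min_cluster_extent)
    significant <- array(labels$values %in% keep_ids, dim = ale$grid$shape)
    zsig <- z$values
    zsig[!significant] <- NA_real_
    thr <- structure(list(grid = ale$grid, z = zsig,
                          significant = significant),
                     class = "thresholded_map")
    structure(list(ale = ale, p = p, z = z, thresholded = thr,
                   cluster_forming_p = cluster_forming_p,
                   min_cluster_extent = as.integer(min_cluster_extent),
                   connectivity = connectivity, fwe_alpha = fwe_alpha),
              class = "significance_maps")
}

#' @export
print.thresholded_map <- function(x, ...) {
    cat(sprintf("thresholded_map: %d significant voxels\n",
                sum(x$significant)))
    invisible(x)
}
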