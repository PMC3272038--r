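#' Build the analysis mask from a tissue-probability volume
#'
#' Neuronal effects are expected in grey matter, so the analysis is
#' restricted to voxels with at least the given grey-matter probability
#' ("at least" — the threshold is inclusive).
#'
#' @param gm a [probability_volume()] of grey-matter probabilities.
#' @param threshold inclusion threshold in (0, 1); default 0.10.
#' @return an [analysis_mask()].
#' @export
mask_from_probability <- function(gm, threshold = 0.10) {
    stopifnot(inherits(gm, "probability_volume"))
    if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
    include <- gm$values >= threshold
    if (!any(include)) stop("empty mask: no voxel reaches the threshold")
    analysis_mask(gm$grid, include)
}

#' Modelled activation (MA) map of one experiment
#'
#' Each focus is assigned to its nearest voxel centre and stamped with the
#' experiment's discretised Gaussian uncertainty kernel; per-voxel
#' probabilities are combined across the experiment's foci by the chosen
#' rule — `"union"` (default): \eqn{1 - \prod_f (1 - p_f(v))}, the
#' probability that at least one of the foci's true activations lies in the
#' voxel; `"max"`: the non-additive alternative that caps the contribution
#' of nearby foci from the same experiment.
#'
#' Foci whose kernel support only partly overlaps the grid are stamped
#' clipped (with a warning); an experiment whose foci all fall entirely
#' outside the grid is an error.
#'
#' @param exp an [experiment()].
#' @param grid a [grid_spec()]; must be in the experiment's reference space.
#' @param params a [kernel_params()].
#' @param combine `"union"` or `"max"`.
#' @return a [probability_volume()].
#' @export
compute_ma_map <- function(exp, grid, params = kernel_params(),
                           combine = c("union", "max")) {
    combine <- match.arg(combine)
    kern <- build_kernel(combined_sigma(exp$n_subjects, params),
                         grid$spacing, params)
    ijk0 <- nearest_voxel0(grid, exp$foci)
    r <- kern$radius_voxels
    touches <- ijk0[, 1] >= -r & ijk0[, 1] < grid$shape[1] + r &
               ijk0[, 2] >= -r & ijk0[, 2] < grid$shape[2] + r &
               ijk0[, 3] >= -r & ijk0[, 3] < grid$shape[3] + r
    if (!any(touches))
        stop(sprintf("experiment '%s': all foci outside the grid", exp$id))
    if (!all(in_bounds0(ijk0, grid$shape)))
        warning(sprintf("experiment '%s': focus outside grid bounds; kernel stamped clipped",
                        exp$id))
    vals <- cpp_stamp_foci(grid$shape, ijk0[touches, , drop = FALSE],
                           as.numeric(kern$values), r, combine == "union")
    probability_volume(grid, vals, check = FALSE)
}

#' Voxel-wise ALE scores from a set of MA maps
#'
#' The ALE score is the union of the modelled activation probabilities
#' across experiments,
#' \deqn{ALE(v) = 1 - \prod_i (1 - MA_i(v)),}
#' i.e. the probability that at least one experiment's true activation lies
#' at the voxel — the convergence of reported results at each location.
#' Values are computed on the analysis mask and 0 elsewhere.
#'
#' @param ma_maps non-empty list of [probability_volume()] MA maps on one
#'   grid.
#' @param mask an [analysis_mask()] on the same grid.
#' @return a [probability_volume()] of ALE scores.
#' @export
compute_ale <- function(ma_maps, mask) {
    if (!length(ma_maps)) stop("need at least one MA map")
    for (m in ma_maps) stop_if_grid_mismatch(m$grid, mask$grid, "MA map and mask")
    one_minus <- lapply(ma_maps, function(m) 1 - m$values)
    ale <- 1 - Reduce(`*`, one_minus)
    ale[!mask$include] <- 0
    probability_volume(mask$grid, ale, check = FALSE)
}
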