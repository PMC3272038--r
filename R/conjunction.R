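#' Minimum-statistic conjunction of thresholded maps
#'
#' The conjunction of independently thresholded statistical maps is their
#' voxel-wise minimum statistic, which for already-thresholded inputs is
#' computationally the intersection: a voxel is significant iff it is
#' significant in every input, and its Z is the minimum of the inputs' Z.
#' The operation is commutative, associative and idempotent, so the triple
#' conjunction can be built by pairwise application in any order.
#'
#' @param maps list of at least two `thresholded_map`s on one grid.
#' @return a `thresholded_map`.
#' @export
min_conjunction <- function(maps) {
    if (length(maps) < 2) stop("need at least two maps")
    for (m in maps) stop_if_grid_mismatch(m$grid, maps[[1]]$grid,
                                          "conjunction inputs")
    grid <- maps[[1]]$grid
    significant <- Reduce(`&`, lapply(maps, `[[`, "significant"))
    # min over inputs; +Inf stands in for background so it never wins where
    # the conjunction is significant (all inputs defined there)
    zmin <- Reduce(pmin, lapply(maps, function(m) {
        z <- m$z
        z[is.na(z)] <- Inf
        z
    }))
    zmin[!significant] <- NA_real_
    structure(list(grid = grid, z = array(zmin, dim = grid$shape),
                   significant = array(significant, dim = grid$shape)),
              class = "thresholded_map")
}

#' Intersect a thresholded result with an external statistical map
#'
#' Tests anatomical overlap between the package's (conjunction) result and a
#' thresholded statistical parametric map produced elsewhere (e.g. a VBM
#' analysis): the external volume is resampled onto the result grid, voxels
#' where the result is significant and the external statistic reaches its
#' threshold form the overlap, and one peak (maximal external statistic,
#' ties by smallest flat voxel index) is reported per overlap component.
#' The threshold the external map was built with is not knowable from the
#' file, so it is a required explicit argument.
#'
#' @param own a `thresholded_map`.
#' @param external an external statistic volume: a path to a NIfTI file or a
#'   volume object (list with `grid`, `values`).
#' @param external_threshold statistic value; external voxels >= this count.
#' @param resample `"nearest"` (default; avoids manufacturing
#'   supra-threshold voxels by interpolation) or `"trilinear"`.
#' @param connectivity component connectivity for the peak list.
#' @return list with `overlap` (logical array on `own$grid`), `labels`
#'   (component label array) and `peaks` (data.frame with `x`, `y`, `z`,
#'   `statistic`, `extent`, `cluster_id`; empty overlap gives zero rows).
#' @export
intersect_with_external <- function(own, external, external_threshold,
                                    resample = c("nearest", "trilinear"),
                                    connectivity = 26) {
    resample <- match.arg(resample)
    if (is.character(external)) external <- read_volume(external,
                                                        probability = FALSE)
    ext <- resample_to_grid(external, own$grid, method = resample)
    overlap <- own$significant & !is.na(ext) & ext >= external_threshold
    labels <- label_clusters(array(overlap, dim = own$grid$shape),
                             connectivity, grid = own$grid)
    ids <- sort(unique(labels$values[labels$values > 0]))
    peaks <- lapply(ids, function(id) {
        vox <- which(labels$values == id)
        peak_flat <- vox[which.max(ext[vox])]
        mm <- voxel0_to_world(own$grid, flat_to_ijk0(peak_flat - 1L,
                                                     own$grid$shape))
        data.frame(x = mm[1], y = mm[2], z = mm[3],
                   statistic = ext[peak_flat], extent = length(vox),
                   cluster_id = id, stringsAsFactors = FALSE)
    })
    peaks <- if (length(peaks)) do.call(rbind, peaks)
             else data.frame(x = numeric(), y = numeric(), z = numeric(),
                             statistic = numeric(), extent = integer(),
                             cluster_id = integer(), stringsAsFactors = FALSE)
    peaks <- peaks[order(-peaks$statistic), , drop = FALSE]
    rownames(peaks) <- NULL
    list(overlap = array(overlap, dim = own$grid$shape),
         labels = labels$values, peaks = peaks)
}

# Resample a volume onto a target grid by nearest-neighbour or trilinear
# interpolation of its own affine; voxels falling outside the source volume
# become NA.
resample_to_grid <- function(vol, grid, method = c("nearest", "trilinear")) {
    method <- match.arg(method)
    if (same_grid(vol$grid, grid)) return(vol$values)
    n <- prod(grid$shape)
    mm <- voxel0_to_world(grid, flat_to_ijk0(seq_len(n) - 1L, grid$shape))
    src <- world_to_voxel0(vol$grid, mm)
    out <- rep(NA_real_, n)
    if (method == "nearest") {
        ijk <- round_half_away(src)
        ok <- in_bounds0(ijk, vol$grid$shape)
        out[ok] <- vol$values[flat_index0(ijk[ok, , drop = FALSE],
                                          vol$grid$shape) + 1L]
    } else {
        f <- floor(src)
        w <- src - f
        ok <- in_bounds0(f, vol$grid$shape) &
              in_bounds0(f + 1, vol$grid$shape)
        acc <- numeric(sum(ok))
        fo <- f[ok, , drop = FALSE]
        wo <- w[ok, , drop = FALSE]
        for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
            corner <- sweep(fo, 2, c(dx, dy, dz), `+`)
            wt <- (ifelse(dx == 1, wo[, 1], 1 - wo[, 1]) *
                   ifelse(dy == 1, wo[, 2], 1 - wo[, 2]) *
                   ifelse(dz == 1, wo[, 3], 1 - wo[, 3]))
            acc <- acc + wt * vol$values[flat_index0(corner, vol$grid$shape) + 1L]
        }
        out[ok] <- acc
    }
    array(out, dim = grid$shape)
}
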