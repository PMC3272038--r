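#' Analysis grid specification
#'
#' Defines the common voxel grid all maps in an analysis live on: integer
#' shape, an invertible 4x4 affine mapping 0-based voxel indices to world
#' millimetre (RAS) coordinates, and the isotropic voxel spacing.
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param spacing isotropic voxel size in mm (default 2, the standard grid
#'   for this analysis class).
#' @param origin world mm coordinate of voxel (0,0,0). Defaults to centring
#'   the volume on the world origin.
#' @param affine optional full 4x4 affine; overrides `spacing`/`origin`
#'   diagonal construction (spacing is then taken from the affine and must be
#'   isotropic).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing = 2, origin = NULL, affine = NULL) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3, all(shape >= 1))
    if (is.null(affine)) {
        stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
        if (is.null(origin)) origin <- -spacing * (shape - 1) / 2
        affine <- rbind(cbind(diag(spacing, 3), origin), c(0, 0, 0, 1))
    } else {
        stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
        sp <- sqrt(colSums(affine[1:3, 1:3]^2))
        if (max(abs(sp - sp[1])) > 1e-6)
            stop("grid_spec: affine must have isotropic spacing")
        spacing <- sp[1]
    }
    if (abs(det(affine)) < 1e-12) stop("grid_spec: affine is not invertible")
    structure(list(shape = shape, affine = unname(affine), spacing = spacing),
              class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
    cat(sprintf("grid_spec: %d x %d x %d voxels, %.3g mm spacing\n",
                x$shape[1], x$shape[2], x$shape[3], x$spacing))
    invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
    identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
    if (!same_grid(a, b)) stop(sprintf("grid mismatch between %s", what))
    invisible(TRUE)
}

# Round half away from zero; R's round() would go half-to-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert between world mm and voxel coordinates
#'
#' `world_to_voxel0` returns continuous 0-based voxel indices;
#' `nearest_voxel0` rounds them (half away from zero) to the nearest voxel
#' centre; `voxel0_to_world` maps 0-based indices back to mm.
#'
#' @param grid a [grid_spec()].
#' @param xyz numeric matrix (n x 3) of mm coordinates, or a length-3 vector.
#' @return n x 3 numeric (or integer) matrix.
#' @export
world_to_voxel0 <- function(grid, xyz) {
    xyz <- to_coord_matrix(xyz)
    inv <- solve(grid$affine)
    out <- t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
    unname(out)
}

#' @rdname world_to_voxel0
#' @export
nearest_voxel0 <- function(grid, xyz) {
    v <- round_half_away(world_to_voxel0(grid, xyz))
    storage.mode(v) <- "integer"
    v
}

#' @rdname world_to_voxel0
#' @param ijk0 n x 3 matrix of 0-based voxel indices.
#' @export
voxel0_to_world <- function(grid, ijk0) {
    ijk0 <- to_coord_matrix(ijk0)
    unname(t(grid$affine %*% rbind(t(ijk0), 1))[, 1:3, drop = FALSE])
}

to_coord_matrix <- function(xyz) {
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
    stopifnot(ncol(xyz) == 3)
    xyz
}

# 0-based flat (column-major) index of 0-based ijk triples.
flat_index0 <- function(ijk0, shape) {
    ijk0[, 1] + shape[1] * (ijk0[, 2] + shape[2] * ijk0[, 3])
}

in_bounds0 <- function(ijk0, shape) {
    ijk0[, 1] >= 0 & ijk0[, 1] < shape[1] &
    ijk0[, 2] >= 0 & ijk0[, 2] < shape[2] &
    ijk0[, 3] >= 0 & ijk0[, 3] < shape[3]
}

#' Per-voxel probability volume on an analysis grid
#'
#' Container for MA maps, ALE maps, grey-matter probability maps and other
#' volumes whose values are probabilities in \[0, 1\].
#'
#' @param grid a [grid_spec()].
#' @param values numeric array with dim equal to `grid$shape`.
#' @param check validate the \[0,1\] range (default TRUE).
#' @return an object of class `probability_volume`.
#' @export
probability_volume <- function(grid, values, check = TRUE) {
    stopifnot(inherits(grid, "grid_spec"))
    values <- array(as.numeric(values), dim = grid$shape)
    if (check) {
        rng <- range(values, na.rm = TRUE)
        if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
            stop("probability_volume: values must lie in [0, 1]")
        values[values < 0] <- 0
        values[values > 1] <- 1
    }
    structure(list(grid = grid, values = values), class = "probability_volume")
}

#' @export
print.probability_volume <- function(x, ...) {
    cat(sprintf("probability_volume on %d x %d x %d grid, range [%.4g, %.4g]\n",
                x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
                min(x$values), max(x$values)))
    invisible(x)
}

#' Analysis mask
#'
#' The set of voxels inference is restricted to (typically grey matter with
#' tissue probability at least 10%).
#'
#' @param grid a [grid_spec()].
#' @param include logical array with dim `grid$shape`; must include at least
#'   one voxel.
#' @return an object of class `analysis_mask`.
#' @export
analysis_mask <- function(grid, include) {
    stopifnot(inherits(grid, "grid_spec"))
    include <- array(as.logical(include), dim = grid$shape)
    if (!any(include)) stop("analysis_mask: no voxels included")
    structure(list(grid = grid, include = include), class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
    cat(sprintf("analysis_mask: %d of %d voxels included\n",
                sum(x$include), length(x$include)))
    invisible(x)
}

# 0-based flat indices of masked voxels (column-major order).
mask_flat0 <- function(mask) which(mask$include) - 1L

# mm coordinates of the centres of all masked voxels.
mask_voxel_centers <- function(mask) {
    idx0 <- mask_flat0(mask)
    voxel0_to_world(mask$grid, flat_to_ijk0(idx0, mask$grid$shape))
}

flat_to_ijk0 <- function(flat0, shape) {
    i <- flat0 %% shape[1]
    j <- (flat0 %/% shape[1]) %% shape[2]
    k <- flat0 %/% (shape[1] * shape[2])
    cbind(i, j, k)
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes are exchanged with other neuroimaging tools as NIfTI-1, with the
#' world coordinates interpreted as RAS mm via the NIfTI affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `probability_volume` (values clamped to
#'   \[0,1\] only when `probability = TRUE`); `write_volume` invisibly returns
#'   the path.
#' @param probability validate/clamp values into \[0,1\].
#' @export
read_volume <- function(path, probability = TRUE) {
    img <- RNifti::readNifti(path)
    aff <- unname(structure(RNifti::xform(img), dimnames = NULL))
    grid <- grid_spec(dim(img)[1:3], affine = matrix(aff, 4, 4))
    vals <- array(as.numeric(img), dim = grid$shape)
    if (probability) probability_volume(grid, vals)
    else structure(list(grid = grid, values = vals),
                   class = "probability_volume")
}

#' @rdname read_volume
#' @param vol a `probability_volume` (or list with `grid` and `values`).
#' @export
write_volume <- function(vol, path) {
    vals <- vol$values
    vals[is.na(vals)] <- 0
    img <- RNifti::asNifti(array(vals, dim = vol$grid$shape))
    img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    # temp-then-rename keeps partial writes invisible; keep the extension so
    # RNifti picks the right (compressed) writer
    tmp <- file.path(dirname(path),
                     sprintf(".tmp%d_%s", Sys.getpid(), basename(path)))
    RNifti::writeNifti(img, tmp)
    file.rename(tmp, path)
    invisible(path)
}
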