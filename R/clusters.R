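#' Label connected components of a binary volume
#'
#' Components under the chosen neighbourhood (6 = faces, 18 = faces+edges,
#' 26 = faces+edges+corners) are numbered with distinct positive integers in
#' order of their first voxel in array scan order; background is 0.
#'
#' @param binary logical array, or a volume/mask object with one.
#' @param connectivity one of 6, 18, 26 (default 26, the most inclusive and
#'   the common choice in this tool family).
#' @param grid optional [grid_spec()] (taken from `binary` when it is a
#'   volume object).
#' @return list with `values` (integer label array) and `grid`.
#' @export
label_clusters <- function(binary, connectivity = 26, grid = NULL) {
    if (inherits(binary, "analysis_mask")) {
        grid <- binary$grid; binary <- binary$include
    } else if (inherits(binary, "thresholded_map")) {
        grid <- binary$grid; binary <- binary$significant
    }
    connectivity <- match_connectivity(connectivity)
    stopifnot(length(dim(binary)) == 3)
    labs <- cpp_label_components(as.logical(binary), dim(binary), connectivity)
    list(values = array(labs, dim = dim(binary)), grid = grid)
}

#' Cluster table of a thresholded map
#'
#' One row per cluster: peak coordinates in mm (the voxel of maximal Z; ties
#' broken deterministically by the smallest flat voxel index in array order),
#' extent in voxels, maximum Z, and an optional anatomical label read from a
#' user-supplied integer-labelled atlas volume at the peak. Rows are sorted
#' by extent (descending), then maximum Z (descending), then lexicographic
#' peak coordinate — the shape of the standard reporting tables for this
#' analysis.
#'
#' @param labels label volume from [label_clusters()] (or an integer array).
#' @param z Z-score array or volume on the same grid.
#' @param grid a [grid_spec()] (needed when `labels` carries none).
#' @param atlas optional integer-labelled volume on the same grid.
#' @param atlas_names optional named character vector, or a data.frame with
#'   columns `value` and `name`, mapping atlas integers to region names.
#' @return a data.frame of class `cluster_table` with columns `cluster_id`,
#'   `label`, `x`, `y`, `z`, `extent`, `max_z`.
#' @export
cluster_table <- function(labels, z, grid = NULL, atlas = NULL,
                          atlas_names = NULL) {
    if (is.list(labels) && !is.null(labels$values)) {
        if (is.null(grid)) grid <- labels$grid
        labels <- labels$values
    }
    if (inherits(z, "probability_volume") || (is.list(z) && !is.null(z$values)))
        z <- z$values
    if (is.null(grid)) stop("cluster_table: a grid_spec is required")
    if (!all(dim(labels) == grid$shape) || !all(dim(z) == grid$shape))
        stop("cluster_table: labels/z do not match the grid")
    atlas_vals <- NULL
    if (!is.null(atlas)) {
        stop_if_grid_mismatch(atlas$grid, grid, "atlas and result grids")
        atlas_vals <- atlas$values
    }
    if (is.data.frame(atlas_names))
        atlas_names <- stats::setNames(as.character(atlas_names$name),
                                       atlas_names$value)
    ids <- sort(unique(labels[labels > 0]))
    rows <- lapply(ids, function(id) {
        vox <- which(labels == id)            # ascending flat index
        zz <- z[vox]
        peak_flat <- vox[which.max(zz)]       # which.max: first max = tie rule
        ijk0 <- flat_to_ijk0(peak_flat - 1L, grid$shape)
        mm <- voxel0_to_world(grid, ijk0)
        lab <- ""
        if (!is.null(atlas_vals)) {
            av <- as.character(as.integer(atlas_vals[peak_flat]))
            lab <- if (!is.null(atlas_names) && av %in% names(atlas_names))
                       unname(atlas_names[av]) else av
        }
        data.frame(cluster_id = id, label = lab, x = mm[1], y = mm[2],
                   z = mm[3], extent = length(vox), max_z = max(zz),
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(cluster_id = integer(), label = character(),
                           x = numeric(), y = numeric(), z = numeric(),
                           extent = integer(), max_z = numeric(),
                           stringsAsFactors = FALSE)
    ord <- order(-out$extent, -out$max_z, out$x, out$y, out$z)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("cluster_table", "data.frame")
    out
}

#' Write a cluster table as TSV
#'
#' Columns mirror the standard reporting layout: location label, x, y, z,
#' cluster_size, max_z.
#'
#' @param table a `cluster_table`.
#' @param path output path.
#' @export
write_cluster_table <- function(table, path) {
    df <- data.frame(label = table$label, x = table$x, y = table$y,
                     z = table$z, cluster_size = table$extent,
                     max_z = table$max_z, stringsAsFactors = FALSE)
    tmp <- file.path(dirname(path),
                     sprintf(".tmp%d_%s", Sys.getpid(), basename(path)))
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
    invisible(path)
}
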