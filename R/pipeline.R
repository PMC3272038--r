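#' Configuration of a full meta-analysis run
#'
#' Collects every tunable of the pipeline: the grey-matter volume and its
#' inclusion threshold, kernel parameters, the per-experiment combination
#' rule, null construction mode, cluster-forming threshold, FWE level,
#' permutation count, connectivity, seed, and an optional output directory.
#'
#' @param gm grey-matter [probability_volume()], or a path to a NIfTI file.
#' @param gm_threshold grey-matter inclusion threshold (default 0.10).
#' @param kernel a [kernel_params()].
#' @param combine per-experiment focus combination rule, `"union"` or
#'   `"max"`.
#' @param null_mode `"convolution"` (exact; default) or `"sampling"`.
#' @param bin_width null histogram bin width (default 1e-5).
#' @param n_draws Monte-Carlo draws when `null_mode = "sampling"`.
#' @param cluster_forming_p voxel-level cluster-forming threshold (default
#'   0.001).
#' @param fwe_alpha cluster-level FWE level (default 0.05).
#' @param n_perm permutations for the max-extent null (default 1000).
#' @param connectivity cluster connectivity, one of 6, 18, 26.
#' @param seed integer seed recorded in, and reproducing, all outputs.
#' @param out_dir optional output directory; when given, NIfTI maps, TSV
#'   tables and a provenance JSON are written.
#' @param atlas optional integer-labelled atlas volume (or path) for
#'   cluster labelling.
#' @param atlas_names optional value->name mapping (data.frame or TSV path
#'   with columns `value`, `name`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(gm, gm_threshold = 0.10, kernel = kernel_params(),
                       combine = c("union", "max"),
                       null_mode = c("convolution", "sampling"),
                       bin_width = 1e-5, n_draws = 1e5,
                       cluster_forming_p = 0.001, fwe_alpha = 0.05,
                       n_perm = 1000, connectivity = 26, seed = 1,
                       out_dir = NULL, atlas = NULL, atlas_names = NULL) {
    combine <- match.arg(combine)
    null_mode <- match.arg(null_mode)
    if (is.character(gm)) gm <- read_volume(gm)
    if (is.character(atlas)) atlas <- read_volume(atlas, probability = FALSE)
    if (is.character(atlas_names)) atlas_names <- read.delim(atlas_names,
                                                             stringsAsFactors = FALSE)
    structure(list(gm = gm, gm_threshold = gm_threshold, kernel = kernel,
                   combine = combine, null_mode = null_mode,
                   bin_width = bin_width, n_draws = n_draws,
                   cluster_forming_p = cluster_forming_p,
                   fwe_alpha = fwe_alpha, n_perm = as.integer(n_perm),
                   connectivity = match_connectivity(connectivity),
                   seed = as.integer(seed), out_dir = out_dir,
                   atlas = atlas, atlas_names = atlas_names),
              class = "run_config")
}

#' Run one complete ALE meta-analysis
#'
#' Executes the full pipeline on one pool of experiments: MA maps ->
#' grey-matter mask -> ALE -> null distribution -> voxel p-values ->
#' Z-transform -> permutation-based cluster-extent FWE threshold ->
#' thresholded maps -> cluster table. When `cfg$out_dir` is set, writes
#' `ale.nii.gz`, `p.nii.gz`, `z.nii.gz`, `thresh_z.nii.gz`, `clusters.tsv`
#' and `provenance.json` (seed, thresholds, kernel parameters, package
#' version, config hash) into `out_dir/<pool name>/`, each file atomically
#' (temp-then-rename).
#'
#' @param pool an [experiment_pool()].
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list with `ale`, `p`, `z` (volumes), `maps` (the
#'   `significance_maps`), `table` (a `cluster_table`), `null`,
#'   `min_cluster_extent`, `crit_ale`, `mask`, and `provenance`.
#' @export
run_meta_analysis <- function(pool, cfg, quiet = TRUE) {
    stopifnot(inherits(pool, "experiment_pool"), inherits(cfg, "run_config"))
    if (!length(pool$experiments)) stop("pool is empty")
    say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    }
    t0 <- Sys.time()
    grid <- cfg$gm$grid
    mask <- stage("mask", mask_from_probability(cfg$gm, cfg$gm_threshold))
    say("mask: %d voxels", sum(mask$include))

    say("MA maps for %d experiments ...", length(pool$experiments))
    one_minus <- array(1, dim = grid$shape)
    histos <- vector("list", length(pool$experiments))
    masked_vals <- if (cfg$null_mode == "sampling")
                       vector("list", length(pool$experiments)) else NULL
    stage("ma_maps", for (i in seq_along(pool$experiments)) {
        m <- compute_ma_map(pool$experiments[[i]], grid, cfg$kernel,
                            cfg$combine)
        one_minus <- one_minus * (1 - m$values)
        histos[[i]] <- ma_value_histogram(m$values[mask$include],
                                          cfg$bin_width)
        if (!is.null(masked_vals)) masked_vals[[i]] <- m$values[mask$include]
    })
    ale_vals <- 1 - one_minus
    ale_vals[!mask$include] <- 0
    ale <- probability_volume(grid, ale_vals, check = FALSE)

    null <- stage("null", {
        if (cfg$null_mode == "sampling") {
            set.seed(cfg$seed)
            vols <- lapply(masked_vals, function(v) {
                arr <- array(0, dim = grid$shape)
                arr[mask$include] <- v
                probability_volume(grid, arr, check = FALSE)
            })
            null_from_sampling(vols, mask, n_draws = cfg$n_draws,
                               bin_width = cfg$bin_width)
        } else {
            null_from_histograms(histos, cfg$bin_width)
        }
    })
    p <- stage("voxel_p", voxel_p(ale, null))
    z <- stage("z_transform", z_transform(p))

    say("permutation null: %d permutations ...", cfg$n_perm)
    conv_null <- if (null$mode == "convolution") null
                 else null_from_histograms(histos, cfg$bin_width)
    min_ext <- stage("cluster_fwe_threshold",
        cluster_fwe_threshold(pool, grid, mask, cfg$kernel,
                              cluster_forming_p = cfg$cluster_forming_p,
                              n_perm = cfg$n_perm, alpha = cfg$fwe_alpha,
                              seed = cfg$seed, combine = cfg$combine,
                              connectivity = cfg$connectivity,
                              bin_width = cfg$bin_width, null = conv_null))
    maps <- stage("threshold_maps",
        threshold_maps(ale, p, z, cfg$cluster_forming_p,
                       as.integer(min_ext), cfg$connectivity,
                       fwe_alpha = cfg$fwe_alpha))
    labels <- label_clusters(maps$thresholded, cfg$connectivity, grid = grid)
    table <- stage("cluster_table",
        cluster_table(labels, z, grid, atlas = cfg$atlas,
                      atlas_names = cfg$atlas_names))
    say("done in %.1f s: %d significant cluster(s)",
        as.numeric(difftime(Sys.time(), t0, units = "secs")), nrow(table))

    prov <- list(pool = pool$name, n_experiments = length(pool$experiments),
                 seed = cfg$seed, n_perm = cfg$n_perm,
                 null_mode = cfg$null_mode, bin_width = cfg$bin_width,
                 gm_threshold = cfg$gm_threshold,
                 cluster_forming_p = cfg$cluster_forming_p,
                 fwe_alpha = cfg$fwe_alpha,
                 min_cluster_extent = as.integer(min_ext),
                 crit_ale = attr(min_ext, "crit_ale"),
                 connectivity = cfg$connectivity, combine = cfg$combine,
                 kernel = unclass(cfg$kernel),
                 package_version = as.character(packageVersion("alemeta")))
    result <- list(ale = ale, p = p, z = z, maps = maps, table = table,
                   null = null, min_cluster_extent = as.integer(min_ext),
                   crit_ale = attr(min_ext, "crit_ale"), mask = mask,
                   provenance = prov)
    if (!is.null(cfg$out_dir))
        write_run_outputs(result, file.path(cfg$out_dir, pool$name))
    result
}

write_run_outputs <- function(result, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(result$ale, file.path(dir, "ale.nii.gz"))
    write_volume(result$p, file.path(dir, "p.nii.gz"))
    write_volume(result$z, file.path(dir, "z.nii.gz"))
    thr <- result$maps$thresholded
    write_volume(list(grid = thr$grid, values = thr$z),
                 file.path(dir, "thresh_z.nii.gz"))
    write_cluster_table(result$table, file.path(dir, "clusters.tsv"))
    prov <- result$provenance
    prov$config_hash <- provenance_hash(prov)
    write_json_atomic(prov, file.path(dir, "provenance.json"))
    invisible(dir)
}

# Content hash of the serialised provenance (md5 of the canonical JSON).
provenance_hash <- function(prov) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
}

write_json_atomic <- function(x, path) {
    tmp <- file.path(dirname(path),
                     sprintf(".tmp%d_%s", Sys.getpid(), basename(path)))
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, path)
    invisible(path)
}

#' Conjunctions across a suite of meta-analysis results
#'
#' Computes every pairwise minimum-statistic conjunction of the named
#' results, the full conjunction across all of them (for three inputs, the
#' triple conjunction), and optionally the intersection with an external
#' thresholded statistical map, each with its cluster table.
#'
#' @param results named list (unique names; >= 2 entries) of
#'   [run_meta_analysis()] results or `thresholded_map`s, all on one grid.
#' @param external optional external statistic volume or NIfTI path.
#' @param external_threshold statistic threshold for the external map
#'   (required with `external`).
#' @param connectivity cluster connectivity.
#' @param out_dir optional output directory for maps/tables.
#' @return list with `conjunctions` (named list of
#'   `list(map, table)`; pairwise entries named `A_and_B`, the full one
#'   `all`) and `external_overlap` (`NULL`, or the
#'   [intersect_with_external()] result).
#' @export
run_conjunction_suite <- function(results, external = NULL,
                                  external_threshold = NULL,
                                  connectivity = 26, out_dir = NULL) {
    if (length(results) < 2) stop("need at least two named results")
    nms <- names(results)
    if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
        stop("results must carry unique non-empty names")
    maps <- lapply(results, function(r)
        if (inherits(r, "thresholded_map")) r
        else if (!is.null(r$maps)) r$maps$thresholded
        else stop("results must be thresholded maps or run results"))
    grid <- maps[[1]]$grid
    combos <- if (length(maps) > 2) utils::combn(nms, 2, simplify = FALSE)
              else list()
    entries <- list()
    conj_one <- function(sel) {
        m <- min_conjunction(maps[sel])
        zarr <- m$z
        zarr[is.na(zarr)] <- 0
        labels <- label_clusters(m, connectivity, grid = grid)
        list(map = m, table = cluster_table(labels, zarr, grid))
    }
    for (pair in combos)
        entries[[paste(pair, collapse = "_and_")]] <- conj_one(pair)
    entries[["all"]] <- conj_one(nms)
    if (!is.null(out_dir)) {
        for (nm in names(entries)) {
            d <- file.path(out_dir, paste0("conj_", nm))
            dir.create(d, recursive = TRUE, showWarnings = FALSE)
            thr <- entries[[nm]]$map
            write_volume(list(grid = grid, values = thr$z),
                         file.path(d, "conj_z.nii.gz"))
            write_cluster_table(entries[[nm]]$table,
                                file.path(d, "clusters.tsv"))
        }
    }
    overlap <- NULL
    if (!is.null(external)) {
        if (is.null(external_threshold))
            stop("external_threshold is required with an external map")
        overlap <- intersect_with_external(entries[["all"]]$map, external,
                                           external_threshold,
                                           connectivity = connectivity)
        if (!is.null(out_dir)) {
            d <- file.path(out_dir, "external_overlap")
            dir.create(d, recursive = TRUE, showWarnings = FALSE)
            tmp <- file.path(d, sprintf(".tmp%d_peaks.tsv", Sys.getpid()))
            write.table(overlap$peaks, tmp, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            file.rename(tmp, file.path(d, "peaks.tsv"))
        }
    }
    list(conjunctions = entries, external_overlap = overlap)
}
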