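#' Family-wise error calibration under pure noise
#'
#' Simulates replicate datasets with no planted convergence (all foci
#' uniform over masked voxel centres), runs the full pipeline on each, and
#' records whether any cluster survives the FWE-corrected threshold. With a
#' calibrated procedure the rejection fraction should match the nominal
#' FWE level.
#'
#' @param n_replicates number of independent synthetic datasets.
#' @param mask an [analysis_mask()] (default: [make_test_mask()]).
#' @param gm matching grey-matter volume (default: the test head's).
#' @param n_experiments experiments per dataset.
#' @param n_perm permutations per dataset.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param fwe_alpha nominal FWE level.
#' @param ... further [run_config()] overrides.
#' @return logical vector: per replicate, did any cluster survive?
#' @export
fwe_calibration <- function(n_replicates = 200, mask = NULL, gm = NULL,
                            n_experiments = 40, n_perm = 200, seed = 1,
                            fwe_alpha = 0.05, ...) {
    if (is.null(mask) || is.null(gm)) {
        head <- make_test_mask()
        mask <- head$mask; gm <- head$gm
    }
    vapply(seq_len(n_replicates), function(r) {
        cfg <- simulation_config(pools = list(list(name = "NULLPOOL",
                                                   n_experiments = n_experiments)),
                                 true_centers = list(), mask = mask,
                                 seed = seed + r)
        pool <- simulate_pools(cfg)$pools[[1]]
        rc <- run_config(gm = gm, n_perm = n_perm, seed = seed + r,
                         fwe_alpha = fwe_alpha, ...)
        res <- run_meta_analysis(pool, rc)
        nrow(res$table) > 0
    }, logical(1))
}

#' Recovery of planted convergence centres
#'
#' Simulates replicate three-pool studies from
#' [default_simulation_config()] (two centres shared by all pools,
#' inclusion probability 0.6, jitter sigma 5 mm, 40 experiments per pool),
#' runs the three meta-analyses and their triple conjunction, and records
#' per replicate: the distance from each pool's top-cluster peak to the
#' nearest planted centre, and whether each planted centre's voxel is in
#' the triple conjunction's significant set.
#'
#' @param n_replicates number of replicate studies.
#' @param mask,gm analysis mask and grey-matter volume (default: test head).
#' @param n_perm permutations per meta-analysis.
#' @param seed base seed; replicate r uses `seed + 1000 + r`.
#' @param ... further [run_config()] overrides.
#' @return data.frame with one row per replicate: `top_peak_dist_mm`
#'   (worst over the three pools of the distance from the top peak to the
#'   nearest planted centre; `Inf` when a pool has no surviving cluster),
#'   `dist_SOC`/`dist_EMO`/`dist_DMN` (the per-pool distances) and
#'   `conj_centers_hit` (how many of the planted centres are significant
#'   in the triple conjunction).
#' @export
recovery_study <- function(n_replicates = 50, mask = NULL, gm = NULL,
                           n_perm = 200, seed = 1, ...) {
    if (is.null(mask) || is.null(gm)) {
        head <- make_test_mask()
        mask <- head$mask; gm <- head$gm
    }
    rows <- lapply(seq_len(n_replicates), function(r) {
        cfg <- default_simulation_config(mask = mask, seed = seed + 1000 + r)
        sim <- simulate_pools(cfg)
        rc <- run_config(gm = gm, n_perm = n_perm, seed = seed + 1000 + r,
                         ...)
        results <- lapply(sim$pools, run_meta_analysis, cfg = rc)
        centers <- do.call(rbind, lapply(sim$truth$centers, `[[`,
                                         "voxel_center"))
        dists <- vapply(results, function(res) {
            if (!nrow(res$table)) return(Inf)
            top <- res$table[1, ]
            min(sqrt(rowSums(sweep(centers, 2,
                                   c(top$x, top$y, top$z))^2)))
        }, numeric(1))
        conj <- run_conjunction_suite(results)$conjunctions$all$map
        hits <- vapply(sim$truth$centers, function(tc) {
            ijk <- nearest_voxel0(mask$grid, tc$voxel_center)
            conj$significant[flat_index0(ijk, mask$grid$shape) + 1L]
        }, logical(1))
        row <- data.frame(top_peak_dist_mm = max(dists),
                          conj_centers_hit = sum(hits))
        for (nm in names(dists)) row[[paste0("dist_", nm)]] <- dists[[nm]]
        row
    })
    do.call(rbind, rows)
}
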