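#' Count distributions for the foci generator
#'
#' Small declarative samplers used by [simulation_config()]: `"fixed"`
#' (always `value`), `"poisson"` (mean `value`) and `"uniform_int"`
#' (integers `min..max` inclusive).
#'
#' @param kind one of `"fixed"`, `"poisson"`, `"uniform_int"`.
#' @param value the fixed value or Poisson mean.
#' @param min,max bounds for `"uniform_int"`.
#' @return an object of class `count_distribution`.
#' @export
count_distribution <- function(kind = c("fixed", "poisson", "uniform_int"),
                               value = NULL, min = NULL, max = NULL) {
    kind <- match.arg(kind)
    if (kind %in% c("fixed", "poisson") && is.null(value))
        stop("'value' is required for fixed/poisson distributions")
    if (kind == "uniform_int" && (is.null(min) || is.null(max)))
        stop("'min' and 'max' are required for uniform_int")
    structure(list(kind = kind, value = value, min = min, max = max),
              class = "count_distribution")
}

sample_counts <- function(dist, n) {
    switch(dist$kind,
           fixed = rep(as.integer(dist$value), n),
           poisson = rpois(n, dist$value),
           uniform_int = dist$min + (sample.int(dist$max - dist$min + 1L, n,
                                                replace = TRUE) - 1L))
}

#' Synthetic test head: ellipsoidal grey-matter field and mask
#'
#' Builds a smooth ellipsoidal tissue-probability field (1 at the volume
#' centre, falling quadratically to 0 at the ellipsoid surface inscribed in
#' the volume) and the analysis mask of voxels with probability >= 0.10.
#' A stand-in for a real tissue-probability map, adequate for correctness
#' and calibration testing.
#'
#' @param shape voxel counts, each >= 20; default `c(40, 48, 40)`.
#' @param spacing voxel size, mm (default 2).
#' @return list with `gm` (a [probability_volume()]), `mask` (an
#'   [analysis_mask()]) and `grid`.
#' @export
make_test_mask <- function(shape = c(40, 48, 40), spacing = 2) {
    shape <- as.integer(shape)
    if (any(shape < 20)) stop("shape components must be >= 20")
    grid <- grid_spec(shape, spacing)
    semi <- spacing * (shape - 1) / 2            # ellipsoid touches the faces
    ax <- lapply(1:3, function(d) ((0:(shape[d] - 1)) - (shape[d] - 1) / 2) *
                                   spacing / semi[d])
    s2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    gm_vals <- pmax(0, 1 - s2)
    gm <- probability_volume(grid, gm_vals)
    list(gm = gm, mask = mask_from_probability(gm, 0.10), grid = grid)
}

#' Configuration of a synthetic multi-pool foci study
#'
#' Describes pools of simulated experiments with planted convergence
#' centres (optionally shared across pools — the synthetic analogue of a
#' locus recruited by several task domains) plus uniform noise foci within
#' the mask. Defaults are the package's reference study conditions: three
#' pools of 40 experiments, planted centres included with probability 0.6
#' and jittered with sigma 5 mm, noise foci ~ Poisson(3) (the noise level
#' scaled to the 40-experiment pools; real studies report more foci, but at
#' full database scale they also contribute hundreds more experiments), and
#' subject counts uniform on 8..25 (typical fMRI group sizes, exercising
#' the sqrt(n) kernel weighting across a realistic range).
#'
#' @param pools list of `list(name=, n_experiments=)` entries.
#' @param true_centers list of `list(xyz=, pools=, inclusion_prob=)`
#'   entries; `xyz` in mm (must lie inside the mask), `pools` the pool
#'   names the centre is planted in, `inclusion_prob` the per-experiment
#'   probability of contributing a focus there.
#' @param focus_jitter_sigma isotropic Gaussian jitter (sd, mm) applied to
#'   planted foci, >= 0.
#' @param noise_foci a [count_distribution()] for per-experiment noise foci.
#' @param n_subjects a [count_distribution()] over integers >= 1.
#' @param mask an [analysis_mask()].
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(pools = list(list(name = "SOC", n_experiments = 40),
                                           list(name = "EMO", n_experiments = 40),
                                           list(name = "DMN", n_experiments = 40)),
                              true_centers = list(),
                              focus_jitter_sigma = 5,
                              noise_foci = count_distribution("poisson", 3),
                              n_subjects = count_distribution("uniform_int",
                                                              min = 8, max = 25),
                              mask, seed = 1) {
    stopifnot(inherits(mask, "analysis_mask"), focus_jitter_sigma >= 0)
    for (tc in true_centers) {
        if (!is.null(tc$inclusion_prob) &&
            (tc$inclusion_prob < 0 || tc$inclusion_prob > 1))
            stop("inclusion probabilities must lie in [0, 1]")
        ijk <- nearest_voxel0(mask$grid, tc$xyz)
        if (!all(in_bounds0(ijk, mask$grid$shape)) ||
            !mask$include[flat_index0(ijk, mask$grid$shape) + 1L])
            stop("true centre outside the mask: ",
                 paste(tc$xyz, collapse = ", "))
    }
    structure(list(pools = pools, true_centers = true_centers,
                   focus_jitter_sigma = focus_jitter_sigma,
                   noise_foci = noise_foci, n_subjects = n_subjects,
                   mask = mask, seed = as.integer(seed)),
              class = "simulation_config")
}

#' Default demonstration study: two centres shared by all three pools
#'
#' Plants two convergence centres — one frontal-midline-like, one
#' parietal-midline-like — in every pool, emulating a core network
#' recruited across task domains and recoverable by the triple conjunction.
#'
#' @param mask an [analysis_mask()] (default: [make_test_mask()]).
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
default_simulation_config <- function(mask = make_test_mask()$mask, seed = 1,
                                      ...) {
    centers <- list(list(xyz = c(-2, 30, 14), pools = c("SOC", "EMO", "DMN"),
                         inclusion_prob = 0.6),
                    list(xyz = c(2, -26, 18), pools = c("SOC", "EMO", "DMN"),
                         inclusion_prob = 0.6))
    simulation_config(true_centers = centers, mask = mask, seed = seed, ...)
}

#' Simulate experiment pools with planted convergence
#'
#' Per experiment: the subject count is drawn from the configured
#' distribution; each planted centre assigned to the pool contributes, with
#' its inclusion probability, one focus at centre + isotropic Gaussian
#' jitter, re-sampled until it lands inside the mask and snapped to the
#' nearest voxel centre; noise foci are drawn uniformly over masked voxel
#' centres. Experiments that end up with zero foci are redrawn. Pools get
#' disjoint id namespaces (`<pool>_001`, ...). Fully deterministic given
#' the config seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with `pools` (list of [experiment_pool()]s) and `truth`
#'   (ground-truth record: centres in mm, their snapped voxel centres, pool
#'   assignments, inclusion probabilities, and the seed).
#' @export
simulate_pools <- function(cfg) {
    stopifnot(inherits(cfg, "simulation_config"))
    set.seed(cfg$seed)
    mask <- cfg$mask
    grid <- mask$grid
    centers_mm <- mask_voxel_centers(mask)
    truth_centers <- lapply(cfg$true_centers, function(tc) {
        ijk <- nearest_voxel0(grid, tc$xyz)
        list(xyz = tc$xyz,
             voxel_center = drop(voxel0_to_world(grid, ijk)),
             pools = tc$pools, inclusion_prob = tc$inclusion_prob)
    })
    jitter_into_mask <- function(center) {
        repeat {
            f <- center + rnorm(3, sd = cfg$focus_jitter_sigma)
            ijk <- nearest_voxel0(grid, f)
            if (all(in_bounds0(ijk, grid$shape)) &&
                mask$include[flat_index0(ijk, grid$shape) + 1L])
                return(drop(voxel0_to_world(grid, ijk)))
        }
    }
    pools <- lapply(cfg$pools, function(p) {
        assigned <- Filter(function(tc) p$name %in% tc$pools, cfg$true_centers)
        exps <- vector("list", p$n_experiments)
        for (i in seq_len(p$n_experiments)) {
            repeat {
                foci <- list()
                for (tc in assigned)
                    if (rbinom(1, 1, tc$inclusion_prob) == 1)
                        foci[[length(foci) + 1L]] <- jitter_into_mask(tc$xyz)
                n_noise <- sample_counts(cfg$noise_foci, 1)
                if (n_noise > 0) {
                    pick <- sample.int(nrow(centers_mm), n_noise,
                                       replace = TRUE)
                    for (r in pick)
                        foci[[length(foci) + 1L]] <- centers_mm[r, ]
                }
                if (length(foci)) break
            }
            exps[[i]] <- experiment(sprintf("%s_%03d", p$name, i),
                                    max(1L, sample_counts(cfg$n_subjects, 1)),
                                    do.call(rbind, foci), space = "MNI")
        }
        experiment_pool(p$name, exps)
    })
    names(pools) <- vapply(cfg$pools, `[[`, "", "name")
    list(pools = pools,
         truth = list(centers = truth_centers, seed = cfg$seed))
}
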