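make_const_maps <- function(grid, values) {
    lapply(values, function(v)
        probability_volume(grid, array(v, dim = grid$shape)))
}

test_that("degenerate and constant-map nulls behave analytically", {
    st <- small_setup(c(12, 12, 12))
    zero <- make_const_maps(st$grid, c(0, 0))
    ns <- null_from_sampling(zero, st$mask, n_draws = 1000, seed = 1)
    expect_equal(null_survival(ns, 0), 1)
    expect_equal(null_survival(ns, 0.001), 0)

    cmaps <- make_const_maps(st$grid, c(0.01, 0.01))
    u <- 1 - (1 - 0.01)^2
    ns2 <- null_from_sampling(cmaps, st$mask, n_draws = 1000, seed = 1)
    expect_equal(null_survival(ns2, u), 1)          # point mass at the union
    expect_equal(null_survival(ns2, u + 2e-5), 0)
})

test_that("convolution null of one map is the histogram of its values", {
    st <- small_setup(c(12, 12, 12))
    e <- pool_on_grid(st$grid, 1, seed = 21)$experiments[[1]]
    ma <- compute_ma_map(e, st$grid, kernel_params())
    null <- null_from_convolution(list(ma), st$mask)
    vals <- ma$values[st$mask$include]
    for (a in quantile(vals[vals > 0], c(0, 0.5, 0.9, 1)))
        expect_equal(null_survival(null, a),
                     mean(round(vals / null$bin_width) >=
                          round(a / null$bin_width)),
                     tolerance = 1e-12)
    expect_equal(sum(null$weights), 1, tolerance = 1e-9)
})

test_that("two two-point maps give the enumerable three-atom union null", {
    grid <- grid_spec(c(2, 1, 1), 2)
    mask <- analysis_mask(grid, array(TRUE, dim = c(2, 1, 1)))
    maps <- lapply(1:2, function(i)
        probability_volume(grid, array(c(0, 0.01), dim = c(2, 1, 1))))
    null <- null_from_convolution(maps, mask)
    w <- null$weights
    binw <- null$bin_width
    expect_equal(w[0 / binw + 1], 0.25)
    expect_equal(w[round(0.01 / binw) + 1], 0.5)
    expect_equal(w[round(0.0199 / binw) + 1], 0.25)
    expect_equal(sum(w != 0), 3)
})

test_that("convolution null matches exhaustive enumeration on a tiny mask", {
    grid <- grid_spec(c(6, 1, 1), 2)
    mask <- analysis_mask(grid, array(TRUE, dim = c(6, 1, 1)))
    set.seed(13)
    maps <- lapply(1:4, function(i)
        probability_volume(grid, array(sample(seq(0, 0.04, by = 0.001), 6),
                                       dim = c(6, 1, 1))))
    null <- null_from_convolution(maps, mask)
    enum <- oracle_null_enumerate(lapply(maps, `[[`, "values"),
                                  mask$include)
    u <- sort(unique(enum))
    mid <- (u[-1] + u[-length(u)]) / 2
    mid <- mid[diff(u) > 4e-5]           # probes clear of binning drift
    for (a in mid)
        expect_equal(null_survival(null, a), mean(enum >= a),
                     tolerance = 1e-9)
})

test_that("sampling null agrees with the exact null within Monte-Carlo error", {
    st <- small_setup(c(14, 14, 14))
    kp <- kernel_params()
    pool <- pool_on_grid(st$grid, 3, seed = 31)
    maps <- lapply(pool$experiments, compute_ma_map, grid = st$grid,
                   params = kp)
    exact <- null_from_convolution(maps, st$mask)
    n <- 1e5
    samp <- null_from_sampling(maps, st$mask, n_draws = n, seed = 99)
    probes <- quantile(unlist(lapply(maps, function(m)
        m$values[st$mask$include & m$values > 0])),
        probs = seq(0.01, 0.99, length.out = 20))
    for (a in probes) {
        S <- null_survival(exact, a)
        tol <- 3 * sqrt(S * (1 - S) / n) + 1e-12
        expect_lt(abs(null_survival(samp, a) - S), tol + 1e-6)
    }
})

test_that("sampling null converges to the convolution null with more draws", {
    st <- small_setup(c(12, 12, 12))
    maps <- lapply(pool_on_grid(st$grid, 3, seed = 41)$experiments,
                   compute_ma_map, grid = st$grid, params = kernel_params())
    exact <- null_from_convolution(maps, st$mask)
    probes <- seq(0, 0.05, by = 0.002)
    err <- sapply(c(1e4, 1e6), function(n) {
        s <- null_from_sampling(maps, st$mask, n_draws = n, seed = 7)
        max(abs(null_survival(s, probes) - null_survival(exact, probes)))
    })
    expect_lt(err[2], err[1])
    expect_lt(err[2], 0.002)
})

test_that("p-values implement 'equal or higher' with the add-one rule", {
    st <- small_setup(c(8, 8, 8))
    # ALE of 0 has p = 1
    zero_ale <- probability_volume(st$grid, array(0, dim = st$grid$shape))
    cm <- make_const_maps(st$grid, 0.01)
    null <- null_from_sampling(cm, st$mask, n_draws = 999, seed = 2)
    expect_equal(voxel_p(zero_ale, null)$values[1], 1)

    # an ALE above all 999 draws gets p = 1/1000
    hi <- probability_volume(st$grid, array(0.5, dim = st$grid$shape))
    expect_equal(voxel_p(hi, null)$values[1], 1 / 1000)

    # ties count toward the null: at a point-mass null, ALE equal to the
    # mass point keeps p = 1 (direct counting oracle)
    at <- probability_volume(st$grid, array(0.01, dim = st$grid$shape))
    expect_equal(voxel_p(at, null)$values[1], (999 + 1) / (999 + 1))

    # p is antitone in ALE
    set.seed(3)
    a <- sort(runif(50, 0, 0.05))
    avol <- probability_volume(st$grid,
                               array(rep_len(a, prod(st$grid$shape)),
                                     dim = st$grid$shape))
    pv <- voxel_p(avol, null)$values[1:50]
    expect_true(all(diff(pv) <= 0))
})

test_that("the Z transform is the standard normal quantile with clamping", {
    st <- small_setup(c(4, 4, 4))
    pvol <- function(p) structure(list(grid = st$grid,
                                       values = array(p, st$grid$shape)),
                                  class = "probability_volume")
    expect_equal(z_transform(pvol(0.5))$values[1], 0)
    expect_equal(z_transform(pvol(0.025))$values[1], 1.959964,
                 tolerance = 1e-6)
    # p = 1 maps to the documented floor, never -Inf
    expect_equal(z_transform(pvol(1))$values[1], -8.2)
    expect_equal(z_transform(pvol(1e-300))$values[1], 8.2)
    # z is antitone in p
    p <- seq(0.001, 0.999, length.out = 30)
    z <- z_transform(p)
    expect_true(all(diff(z) < 0))
})

test_that("cluster thresholding keeps exactly the large-enough components", {
    grid <- grid_spec(c(20, 20, 20), 2)
    parr <- array(1, dim = grid$shape)
    # one 5-voxel and one 50-voxel component of low p
    parr[2:6, 2, 2] <- 1e-4
    parr[10:19, 10:14, 10] <- 1e-4
    p <- structure(list(grid = grid, values = parr),
                   class = "probability_volume")
    z <- z_transform(p)
    ale <- probability_volume(grid, array(0, dim = grid$shape))
    sm <- threshold_maps(ale, p, z, cluster_forming_p = 0.001,
                         min_cluster_extent = 10)
    expect_equal(sum(sm$thresholded$significant), 50)
    expect_true(all(is.na(sm$thresholded$z[parr == 1])))

    # component below the forming threshold nowhere -> empty mask
    sm0 <- threshold_maps(ale, structure(list(grid = grid,
                                              values = array(1, grid$shape)),
                                         class = "probability_volume"),
                          z, 0.001, 1)
    expect_equal(sum(sm0$thresholded$significant), 0)

    # a 300-voxel component passes a 251 extent threshold intact
    parr2 <- array(1, dim = grid$shape)
    parr2[3:12, 3:12, 3:5] <- 1e-4
    p2 <- structure(list(grid = grid, values = parr2),
                    class = "probability_volume")
    sm2 <- threshold_maps(ale, p2, z_transform(p2), 0.001, 251)
    expect_equal(sum(sm2$thresholded$significant), 300)
})

test_that("the permutation scheme preserves focus and subject counts", {
    st <- small_setup(c(14, 14, 14))
    pool <- pool_on_grid(st$grid, 8, seed = 51)
    set.seed(1)
    for (i in 1:5) {
        perm <- permute_pool(pool, st$mask)
        expect_equal(vapply(perm$experiments, function(e) nrow(e$foci), 0L),
                     vapply(pool$experiments, function(e) nrow(e$foci), 0L))
        expect_equal(vapply(perm$experiments, `[[`, 0L, "n_subjects"),
                     vapply(pool$experiments, `[[`, 0L, "n_subjects"))
        # relocated foci are masked voxel centres
        vox <- nearest_voxel0(st$grid, perm$experiments[[1]]$foci)
        flat <- vox[, 1] + st$grid$shape[1] *
                (vox[, 2] + st$grid$shape[2] * vox[, 3]) + 1
        expect_true(all(st$mask$include[flat]))
    }
})

test_that("the FWE extent threshold is the upper quantile of the max-extent null", {
    st <- small_setup(c(16, 16, 16))
    pool <- pool_on_grid(st$grid, 6, max_foci = 5, seed = 61)
    thr <- cluster_fwe_threshold(pool, st$grid, st$mask, kernel_params(),
                                 cluster_forming_p = 0.01, n_perm = 100,
                                 alpha = 0.05, seed = 5)
    null <- attr(thr, "null_max_extents")
    expect_length(null, 100)
    # add-one exceedance at the threshold is within alpha, and the next
    # smaller extent would exceed it
    expect_lte((sum(null >= thr) + 1) / 101, 0.05)
    if (thr > 1) expect_gt((sum(null >= thr - 1) + 1) / 101, 0.05)

    # ultra-strict forming threshold: no permutation forms any cluster,
    # extent 1 suffices
    thr0 <- cluster_fwe_threshold(pool, st$grid, st$mask, kernel_params(),
                                  cluster_forming_p = 1e-12, n_perm = 100,
                                  alpha = 0.05, seed = 5)
    expect_identical(as.integer(thr0), 1L)
    expect_true(all(attr(thr0, "null_max_extents") == 0))

    expect_error(cluster_fwe_threshold(pool, st$grid, st$mask,
                                       cluster_forming_p = 1.5), "cluster_forming_p")
    expect_error(cluster_fwe_threshold(pool, st$grid, st$mask, n_perm = 10),
                 "n_perm")
})

test_that("voxel-wise p-values are super-uniform under spatial randomness", {
    head <- make_test_mask(c(24, 28, 24), 2)
    kp <- kernel_params()
    fracs <- sapply(1:50, function(r) {
        cfg <- simulation_config(pools = list(list(name = "U",
                                                   n_experiments = 10)),
                                 true_centers = list(),
                                 noise_foci = count_distribution("fixed", 5),
                                 mask = head$mask, seed = 770 + r)
        pool <- simulate_pools(cfg)$pools$U
        maps <- lapply(pool$experiments, compute_ma_map, grid = head$grid,
                       params = kp)
        ale <- compute_ale(maps, head$mask)
        p <- voxel_p(ale, null_from_convolution(maps, head$mask))
        mean(p$values[head$mask$include] < 0.05)
    })
    expect_lte(mean(fracs), 0.06)
})
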