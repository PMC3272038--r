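test_that("the test head is a smooth ellipsoid thresholded at 10%", {
    head <- make_test_mask(c(24, 28, 24), 2)
    ctr <- (head$grid$shape - 1) / 2 + 1
    # centre has full probability, corners none
    expect_equal(head$gm$values[12, 14, 12], 1, tolerance = 0.05)
    expect_equal(head$gm$values[1, 1, 1], 0)
    expect_false(head$mask$include[1, 1, 1])
    # mask equals direct thresholding of the gm field
    expect_equal(head$mask$include, head$gm$values >= 0.10)
    expect_error(make_test_mask(c(10, 24, 24)), "20")
})

test_that("pure-noise configs yield exactly the configured focus counts", {
    head <- make_test_mask(c(24, 24, 24), 2)
    cfg <- simulation_config(pools = list(list(name = "N", n_experiments = 12)),
                             true_centers = list(),
                             noise_foci = count_distribution("fixed", 3),
                             mask = head$mask, seed = 5)
    sim <- simulate_pools(cfg)
    counts <- vapply(sim$pools$N$experiments, function(e) nrow(e$foci), 0L)
    expect_true(all(counts == 3))
    # all foci on masked voxel centres
    for (e in sim$pools$N$experiments) {
        vox <- nearest_voxel0(head$grid, e$foci)
        flat <- vox[, 1] + head$grid$shape[1] *
                (vox[, 2] + head$grid$shape[2] * vox[, 3]) + 1
        expect_true(all(head$mask$include[flat]))
        expect_lt(max(abs(e$foci - voxel0_to_world(head$grid, vox))), 1e-9)
    }
})

test_that("the noiseless regime plants foci exactly on centre voxels", {
    head <- make_test_mask(c(24, 24, 24), 2)
    center <- c(-2, 8, 6)
    cfg <- simulation_config(pools = list(list(name = "P", n_experiments = 8)),
                             true_centers = list(list(xyz = center,
                                                      pools = "P",
                                                      inclusion_prob = 1)),
                             focus_jitter_sigma = 0,
                             noise_foci = count_distribution("fixed", 0),
                             mask = head$mask, seed = 5)
    sim <- simulate_pools(cfg)
    want <- drop(voxel0_to_world(head$grid,
                                 nearest_voxel0(head$grid, center)))
    for (e in sim$pools$P$experiments) {
        expect_equal(nrow(e$foci), 1)
        expect_equal(unname(e$foci[1, ]), want)
    }
})

test_that("generation is deterministic given the seed", {
    head <- make_test_mask(c(24, 24, 24), 2)
    cfg <- simulation_config(pools = list(list(name = "A", n_experiments = 40),
                                          list(name = "B", n_experiments = 40)),
                             true_centers = list(list(xyz = c(0, 0, 0),
                                                      pools = c("A", "B"),
                                                      inclusion_prob = 0.6)),
                             mask = head$mask, seed = 7)
    s1 <- simulate_pools(cfg)
    s2 <- simulate_pools(cfg)
    expect_identical(s1$pools, s2$pools)
    # and the serialised form is byte-identical
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_foci_text(s1$pools$A, f1)
    write_foci_text(s2$pools$A, f2)
    expect_identical(readLines(f1), readLines(f2))
    # pools use disjoint id namespaces
    expect_equal(nrow(validate_pools_disjoint(s1$pools)), 0)
})

test_that("noise focus counts follow the configured distribution", {
    head <- make_test_mask(c(24, 24, 24), 2)
    lambda <- 8
    cfg <- simulation_config(pools = list(list(name = "C",
                                               n_experiments = 500)),
                             true_centers = list(),
                             noise_foci = count_distribution("poisson",
                                                             lambda),
                             mask = head$mask, seed = 13)
    counts <- vapply(simulate_pools(cfg)$pools$C$experiments,
                     function(e) nrow(e$foci), 0L)
    # experiments are redrawn on zero foci, so compare against the
    # zero-truncated Poisson by chi-square goodness of fit
    kmax <- max(counts)
    expected <- dpois(1:kmax, lambda) / (1 - dpois(0, lambda))
    expected <- expected / sum(expected)
    obs <- tabulate(counts, nbins = kmax)
    keep <- expected * length(counts) >= 5
    chi <- suppressWarnings(chisq.test(c(obs[keep], sum(obs[!keep])),
                                       p = c(expected[keep],
                                             sum(expected[!keep]))))
    expect_gt(chi$p.value, 0.001)
    # subject counts stay within the configured uniform range
    ns <- vapply(simulate_pools(cfg)$pools$C$experiments, `[[`, 0L,
                 "n_subjects")
    expect_true(all(ns >= 8 & ns <= 25))
})

test_that("misconfigured simulations are rejected", {
    head <- make_test_mask(c(24, 24, 24), 2)
    expect_error(simulation_config(true_centers =
                                       list(list(xyz = c(90, 0, 0),
                                                 pools = "SOC",
                                                 inclusion_prob = 0.5)),
                                   mask = head$mask),
                 "outside the mask")
    expect_error(simulation_config(true_centers =
                                       list(list(xyz = c(0, 0, 0),
                                                 pools = "SOC",
                                                 inclusion_prob = 1.5)),
                                   mask = head$mask),
                 "probabilities")
    expect_error(count_distribution("poisson"), "value")
})
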