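# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity with plain loops and closed forms,
# sharing no code path with the package internals they check.

# Random experiment pool with coordinates on a 0.25 mm lattice (so text
# round-trips at two decimals are exact).
random_pool <- function(n_exp, name = "P", space = "MNI", max_foci = 6,
                        coord_range = 60) {
    exps <- lapply(seq_len(n_exp), function(i) {
        nf <- sample.int(max_foci, 1)
        foci <- matrix(sample(seq(-coord_range, coord_range, by = 0.25),
                              3 * nf, replace = TRUE), ncol = 3)
        experiment(sprintf("%s_s%02d", name, i), sample(5:30, 1), foci,
                   space = space)
    })
    experiment_pool(name, exps)
}

pools_equal <- function(a, b, tol = 0.005) {
    if (length(a$experiments) != length(b$experiments)) return(FALSE)
    for (i in seq_along(a$experiments)) {
        ea <- a$experiments[[i]]; eb <- b$experiments[[i]]
        if (ea$id != eb$id || ea$n_subjects != eb$n_subjects ||
            ea$space != eb$space) return(FALSE)
        if (nrow(ea$foci) != nrow(eb$foci)) return(FALSE)
        if (max(abs(ea$foci - eb$foci)) > tol) return(FALSE)
    }
    TRUE
}

# Direct evaluation of the truncated, renormalised Gaussian kernel by three
# explicit loops.
oracle_kernel <- function(sigma, spacing, trunc_sigmas = 5) {
    r_mm <- trunc_sigmas * sigma
    r <- ceiling(r_mm / spacing)
    side <- 2 * r + 1
    vals <- array(0, dim = c(side, side, side))
    for (i in -r:r) for (j in -r:r) for (k in -r:r) {
        d2 <- (i^2 + j^2 + k^2) * spacing^2
        if (d2 <= r_mm^2)
            vals[i + r + 1, j + r + 1, k + r + 1] <- exp(-d2 / (2 * sigma^2))
    }
    vals / sum(vals)
}

# Per-voxel brute-force MA map: for every grid voxel, combine the kernel
# values of all foci by the union (or max) rule.
oracle_ma_map <- function(exp, grid, params, combine = "union") {
    sigma <- sqrt(params$sigma_template^2 +
                  params$sigma_subject^2 / exp$n_subjects)
    kern <- oracle_kernel(sigma, grid$spacing, params$truncation_sigmas)
    r <- (dim(kern)[1] - 1) / 2
    centers <- round_half_away_oracle(t(solve(grid$affine) %*%
                                        rbind(t(exp$foci), 1))[, 1:3,
                                                               drop = FALSE])
    out <- array(0, dim = grid$shape)
    for (i in 0:(grid$shape[1] - 1))
        for (j in 0:(grid$shape[2] - 1))
            for (k in 0:(grid$shape[3] - 1)) {
                acc <- if (combine == "union") 1 else 0
                for (f in seq_len(nrow(centers))) {
                    di <- i - centers[f, 1]; dj <- j - centers[f, 2]
                    dk <- k - centers[f, 3]
                    if (abs(di) > r || abs(dj) > r || abs(dk) > r) next
                    kv <- kern[di + r + 1, dj + r + 1, dk + r + 1]
                    if (combine == "union") acc <- acc * (1 - kv)
                    else acc <- max(acc, kv)
                }
                out[i + 1, j + 1, k + 1] <-
                    if (combine == "union") 1 - acc else acc
            }
    out
}

round_half_away_oracle <- function(x) sign(x) * floor(abs(x) + 0.5)

# Per-voxel product-rule ALE oracle.
oracle_ale <- function(ma_values_list, include) {
    out <- array(0, dim = dim(include))
    for (v in which(include)) {
        acc <- 1
        for (m in ma_values_list) acc <- acc * (1 - m[v])
        out[v] <- 1 - acc
    }
    out
}

# Flood-fill connected components (recursive frontier, plain R).
oracle_label <- function(binary, connectivity) {
    dm <- dim(binary)
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[rowSums(abs(offs)) > 0, ]
    if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
    if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
    labels <- array(0L, dim = dm)
    nextl <- 0L
    for (s in which(binary)) {
        if (labels[s] != 0L) next
        nextl <- nextl + 1L
        frontier <- s
        labels[s] <- nextl
        while (length(frontier)) {
            newf <- integer()
            for (v in frontier) {
                v0 <- v - 1L
                i <- v0 %% dm[1]; j <- (v0 %/% dm[1]) %% dm[2]
                k <- v0 %/% (dm[1] * dm[2])
                for (o in seq_len(nrow(offs))) {
                    ii <- i + offs$dx[o]; jj <- j + offs$dy[o]
                    kk <- k + offs$dz[o]
                    if (ii < 0 || ii >= dm[1] || jj < 0 || jj >= dm[2] ||
                        kk < 0 || kk >= dm[3]) next
                    w <- ii + dm[1] * (jj + dm[2] * kk) + 1L
                    if (binary[w] && labels[w] == 0L) {
                        labels[w] <- nextl
                        newf <- c(newf, w)
                    }
                }
            }
            frontier <- newf
        }
    }
    labels
}

# Exhaustive union-null: enumerate every tuple of masked values, one per
# map, and union them.
oracle_null_enumerate <- function(ma_values_list, include) {
    vals <- lapply(ma_values_list, function(m) m[include])
    grids <- do.call(expand.grid, vals)
    apply(grids, 1, function(row) 1 - prod(1 - row))
}

# Small analysis setup shared by several tests.
small_setup <- function(shape = c(20, 20, 20), spacing = 2) {
    grid <- grid_spec(shape, spacing)
    gm <- probability_volume(grid, array(1, dim = shape))
    list(grid = grid, gm = gm, mask = mask_from_probability(gm, 0.10))
}

# A pool whose foci all sit inside the given grid.
pool_on_grid <- function(grid, n_exp, name = "G", max_foci = 4, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    half <- grid$spacing * (grid$shape - 1) / 2 - 2
    exps <- lapply(seq_len(n_exp), function(i) {
        nf <- sample.int(max_foci, 1)
        foci <- cbind(runif(nf, -half[1], half[1]),
                      runif(nf, -half[2], half[2]),
                      runif(nf, -half[3], half[3]))
        experiment(sprintf("%s_e%02d", name, i), sample(8:25, 1), foci)
    })
    experiment_pool(name, exps)
}
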