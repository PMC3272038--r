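test_that("a single-record foci file parses into one experiment", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("// Reference=MNI", "// StudyA: n=12", "-2 48 28"), f)
    pool <- read_foci_text(f)
    expect_length(pool$experiments, 1)
    e <- pool$experiments[[1]]
    expect_equal(e$id, "StudyA")
    expect_equal(e$n_subjects, 12L)
    expect_equal(unname(e$foci[1, ]), c(-2, 48, 28))
    expect_equal(e$space, "MNI")
    expect_equal(pool$name, sub("\\.txt$", "", basename(f)))
})

test_that("malformed input is rejected with an informative message", {
    dup <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("// Reference=MNI",
                 "// StudyA: n=12", "-2 48 28",
                 "", "// StudyA: n=9", "0 0 0"), dup)
    expect_error(read_foci_text(dup), "duplicate experiment id.*StudyA")

    nospace <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("// StudyA: n=12", "-2 48 28"), nospace)
    expect_error(read_foci_text(nospace), "[Rr]eference space")

    badcoord <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("// Reference=MNI", "// StudyA: n=12", "-2 48"), badcoord)
    expect_error(read_foci_text(badcoord), "line 3")

    nofoci <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("// Reference=MNI", "// StudyA: n=12", "",
                 "// StudyB: n=9", "0 0 0"), nofoci)
    expect_error(read_foci_text(nofoci), "no foci")
})

test_that("write/read round trip reproduces random pools", {
    set.seed(42)
    for (n_exp in c(1, 7, 50)) {
        pool <- random_pool(n_exp, name = sprintf("rt%d", n_exp))
        f <- withr::local_tempfile(fileext = ".txt")
        write_foci_text(pool, f)
        back <- read_foci_text(f, name = pool$name)
        expect_true(pools_equal(pool, back), info = sprintf("n=%d", n_exp))
    }
})

test_that("an empty pool round-trips through a header-only file", {
    pool <- experiment_pool("empty")
    f <- withr::local_tempfile(fileext = ".txt")
    write_foci_text(pool, f)
    back <- read_foci_text(f)
    expect_length(back$experiments, 0)
})

test_that("unwritable paths raise an I/O error", {
    pool <- random_pool(1)
    expect_error(write_foci_text(pool, "/nonexistent-dir/x/y.txt"),
                 "cannot write")
})

test_that("TSV round trip preserves pools including effect sign", {
    set.seed(7)
    pool <- random_pool(5, name = "tsv")
    pool$experiments[[2]]$effect_sign <- "deactivation"
    f <- withr::local_tempfile(fileext = ".tsv")
    write_foci_tsv(pool, f)
    back <- read_foci_tsv(f, name = "tsv")
    expect_true(pools_equal(pool, back))
    expect_equal(back$experiments[[2]]$effect_sign, "deactivation")
})

test_that("experiment invariants are enforced", {
    expect_error(experiment("a", 0, c(0, 0, 0)), "n_subjects")
    expect_error(experiment("a", 5, matrix(numeric(), ncol = 3)), "focus")
    expect_error(experiment("a", 5, c(250, 0, 0)), "200 mm")
    expect_error(experiment("a", 5, c(NA, 0, 0)), "finite")
})

test_that("space conversion is identity-, inverse- and matrix-consistent", {
    set.seed(3)
    pool <- random_pool(4, space = "TAL")
    # identity transform leaves coordinates untouched
    same <- convert_space(pool, "MNI", diag(4))
    expect_equal(same$experiments[[1]]$foci, pool$experiments[[1]]$foci)
    expect_equal(same$experiments[[1]]$space, "MNI")

    # registered default transform, then its inverse, recovers the input
    mni <- convert_space(pool, "MNI")
    back <- convert_space(mni, "TAL")
    expect_lt(max(abs(back$experiments[[1]]$foci -
                      pool$experiments[[1]]$foci)), 1e-9)

    # a configured affine acts as the plain matrix-vector product
    m <- matrix(c(0.9, 0, 0, 1.2,
                  0.05, 1.1, 0, -2,
                  0, 0, 0.95, 3,
                  0, 0, 0, 1), 4, 4, byrow = TRUE)
    p1 <- experiment_pool("one", list(experiment("e", 10, c(10, -20, 30),
                                                 space = "TAL")))
    got <- convert_space(p1, "MNI", m)$experiments[[1]]$foci
    expect_equal(unname(got[1, ]),
                 as.numeric((m %*% c(10, -20, 30, 1))[1:3]))
})

test_that("experiments already in the target space pass through unchanged", {
    pool <- experiment_pool("mixed", list(
        experiment("t", 10, c(10, 10, 10), space = "MNI")))
    out <- convert_space(pool, "MNI")
    expect_identical(out$experiments[[1]]$foci, pool$experiments[[1]]$foci)
})

test_that("unknown transforms raise a configuration error", {
    pool <- random_pool(1, space = "TAL")
    expect_error(convert_space(pool, "MNI", "no-such-transform"),
                 "unknown transform")
})

test_that("pool disjointness report equals brute-force set intersection", {
    a <- experiment_pool("A", list(experiment("e1", 5, c(0, 0, 0)),
                                   experiment("e2", 5, c(1, 1, 1))))
    b <- experiment_pool("B", list(experiment("e3", 5, c(2, 2, 2))))
    expect_equal(nrow(validate_pools_disjoint(list(a, b))), 0)

    b2 <- experiment_pool("B", list(experiment("e1", 5, c(2, 2, 2))))
    rep2 <- validate_pools_disjoint(list(a, b2))
    expect_equal(rep2$id, "e1")
    expect_equal(rep2$pools, "A,B")

    # planted overlaps across three random pools
    set.seed(9)
    for (k in 0:3) {
        mk <- function(nm, ids) experiment_pool(nm, lapply(ids, function(i)
            experiment(i, 5, c(0, 0, 0))))
        shared <- if (k > 0) sprintf("sh%d", seq_len(k)) else character()
        p1 <- mk("P1", c(sprintf("a%d", 1:5), shared))
        p2 <- mk("P2", c(sprintf("b%d", 1:4), shared))
        p3 <- mk("P3", sprintf("c%d", 1:6))
        got <- validate_pools_disjoint(list(p1, p2, p3))
        expect_equal(sort(got$id), sort(shared))
        ids_of <- function(p) names(p$experiments)
        brute <- unique(c(intersect(ids_of(p1), ids_of(p2)),
                          intersect(ids_of(p1), ids_of(p3)),
                          intersect(ids_of(p2), ids_of(p3))))
        expect_setequal(got$id, brute)
    }
})
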