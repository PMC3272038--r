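#' Register and look up reference-space transforms
#'
#' Coordinate conversion between stereotaxic spaces is configuration, not
#' code: each direction is a single user-registered invertible 4x4 affine in
#' homogeneous mm coordinates. A Lancaster-style Talairach<->MNI pair ships
#' as a default configuration entry (see `extdata/transforms.yaml`); its
#' matrix entries are documented as approximate and can be overridden.
#'
#' @param name transform name (e.g. `"tal2mni"`).
#' @param from,to space names (`"TAL"`, `"MNI"`).
#' @param matrix invertible 4x4 affine; bottom row must be (0,0,0,1).
#' @return `register_space_transform` invisibly returns the name;
#'   `get_space_transform` returns a list with `from`, `to`, `matrix`.
#' @export
register_space_transform <- function(name, from, to, matrix) {
    stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)))
    if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
        stop("transform matrix must be affine (bottom row 0 0 0 1)")
    if (abs(det(matrix)) < 1e-12)
        stop("transform matrix must be invertible")
    reg <- get0("transforms", envir = .alemeta_env, ifnotfound = list())
    reg[[name]] <- list(from = toupper(from), to = toupper(to),
                        matrix = unname(matrix))
    assign("transforms", reg, envir = .alemeta_env)
    invisible(name)
}

#' @rdname register_space_transform
#' @export
get_space_transform <- function(name = NULL, from = NULL, to = NULL) {
    reg <- get0("transforms", envir = .alemeta_env, ifnotfound = list())
    if (!is.null(name)) {
        if (is.null(reg[[name]]))
            stop(sprintf("unknown transform '%s'; registered: %s", name,
                         paste(names(reg), collapse = ", ")))
        return(reg[[name]])
    }
    stopifnot(!is.null(from), !is.null(to))
    for (tr in reg)
        if (tr$from == toupper(from) && tr$to == toupper(to)) return(tr)
    stop(sprintf("no transform registered for %s -> %s", from, to))
}

#' Convert a pool's foci to another reference space
#'
#' All foci are mapped through the affine and the space field is updated.
#' Experiments already in the target space pass through unchanged.
#'
#' @param pool an [experiment_pool()].
#' @param target target space name (`"MNI"` or `"TAL"`).
#' @param transform a 4x4 affine, a registered transform name, or `NULL` to
#'   look one up by (pool space -> target).
#' @return the converted [experiment_pool()].
#' @export
convert_space <- function(pool, target, transform = NULL) {
    target <- toupper(target)
    exps <- lapply(pool$experiments, function(e) {
        if (e$space == target) return(e)
        m <- transform
        if (is.null(m)) m <- get_space_transform(from = e$space, to = target)$matrix
        else if (is.character(m)) m <- get_space_transform(m)$matrix
        stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
        xyz <- t(m %*% rbind(t(e$foci), 1))[, 1:3, drop = FALSE]
        experiment(e$id, e$n_subjects, xyz, space = target,
                   effect_sign = e$effect_sign, tags = e$tags)
    })
    experiment_pool(pool$name, unname(exps))
}
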