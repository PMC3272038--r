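#' A single neuroimaging experiment (study contrast)
#'
#' One experiment contributes a subject count and a set of reported peak
#' coordinates (foci) in a named stereotaxic reference space. Duplicate foci
#' are kept: under the union combination rule they legitimately sharpen the
#' experiment's modelled activation map, and under the max rule they are
#' idempotent.
#'
#' @param id unique experiment identifier.
#' @param n_subjects number of scanned subjects (integer >= 1); controls the
#'   width of the spatial-uncertainty kernel.
#' @param foci numeric matrix (n x 3) of x/y/z mm coordinates, n >= 1.
#' @param space reference space, `"MNI"` or `"TAL"`.
#' @param effect_sign `"activation"` or `"deactivation"`; recorded as
#'   metadata only — deactivation foci are treated as convergence evidence
#'   identically to activation foci.
#' @param tags free-form named list of metadata (behavioural domain,
#'   paradigm class, ...).
#' @return an object of class `experiment`.
#' @export
experiment <- function(id, n_subjects, foci, space = c("MNI", "TAL"),
                       effect_sign = c("activation", "deactivation"),
                       tags = list()) {
    space <- match.arg(space)
    effect_sign <- match.arg(effect_sign)
    foci <- to_coord_matrix(foci)
    if (!is.character(id) || length(id) != 1 || !nzchar(id))
        stop("experiment: id must be a non-empty string")
    n_subjects <- as.integer(n_subjects)
    if (is.na(n_subjects) || n_subjects < 1)
        stop("experiment: n_subjects must be an integer >= 1")
    if (nrow(foci) < 1) stop("experiment: at least one focus is required")
    if (any(!is.finite(foci))) stop("experiment: foci must be finite")
    if (any(abs(foci) > 200))
        stop("experiment: |coordinate| > 200 mm fails the sanity bound")
    colnames(foci) <- c("x", "y", "z")
    structure(list(id = id, n_subjects = n_subjects, foci = foci,
                   space = space, effect_sign = effect_sign, tags = tags),
              class = "experiment")
}

#' A pool of experiments entering one meta-analysis
#'
#' @param name pool name (e.g. `"SOC"`, `"EMO"`, `"DMN"`).
#' @param experiments list of [experiment()] objects with unique ids.
#' @return an object of class `experiment_pool`.
#' @export
experiment_pool <- function(name, experiments = list()) {
    stopifnot(is.character(name), length(name) == 1)
    if (!all(vapply(experiments, inherits, TRUE, "experiment")))
        stop("experiment_pool: all elements must be experiment objects")
    ids <- vapply(experiments, `[[`, "", "id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop(sprintf("experiment_pool '%s': duplicate experiment id(s): %s",
                     name, paste(dup, collapse = ", ")))
    names(experiments) <- ids
    structure(list(name = name, experiments = experiments),
              class = "experiment_pool")
}

#' @export
print.experiment_pool <- function(x, ...) {
    nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), 0L))
    cat(sprintf("experiment_pool '%s': %d experiments, %d foci\n",
                x$name, length(x$experiments), nf))
    invisible(x)
}

#' @export
length.experiment_pool <- function(x) length(x$experiments)

pool_ids <- function(pool) vapply(pool$experiments, `[[`, "", "id")

pool_space <- function(pool) {
    sp <- unique(vapply(pool$experiments, `[[`, "", "space"))
    if (length(sp) > 1)
        stop(sprintf("pool '%s' mixes reference spaces: %s",
                     pool$name, paste(sp, collapse = ", ")))
    sp
}

#' Report experiment ids shared between pools
#'
#' Meta-analyses to be compared by conjunction must be based on independent
#' pools of experiments; any id occurring in more than one pool violates
#' that.
#'
#' @param pools list of at least two [experiment_pool()] objects.
#' @return data.frame with columns `id` and `pools` (comma-separated pool
#'   names); zero rows iff the pools are pairwise disjoint.
#' @export
validate_pools_disjoint <- function(pools) {
    if (length(pools) < 2) stop("need at least two pools")
    ids <- lapply(pools, pool_ids)
    names(ids) <- vapply(pools, `[[`, "", "name")
    tab <- data.frame(id = unlist(ids, use.names = FALSE),
                      pool = rep(names(ids), lengths(ids)),
                      stringsAsFactors = FALSE)
    shared <- unique(tab$id[duplicated(tab$id)])
    if (!length(shared))
        return(data.frame(id = character(), pools = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(sort(shared), function(s) {
        data.frame(id = s,
                   pools = paste(sort(unique(tab$pool[tab$id == s])),
                                 collapse = ","),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
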