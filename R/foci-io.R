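#' Read a foci table in the community text dialect
#'
#' Parses the de-facto foci exchange format: `//`-prefixed header lines, a
#' file-level `// Reference=<SPACE>` header, one `// <id>: n=<N>` header per
#' study block, whitespace-separated `x y z` mm coordinates (one focus per
#' line), and blank lines between studies. Real GingerALE-style exports load
#' unchanged.
#'
#' @param path path to the text file.
#' @param name pool name; defaults to the file stem.
#' @return an [experiment_pool()].
#' @export
read_foci_text <- function(path, name = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    space <- NULL
    experiments <- list()
    cur_id <- NULL; cur_n <- NULL; cur_foci <- list()
    flush <- function() {
        if (is.null(cur_id)) return()
        if (!length(cur_foci))
            stop(sprintf("experiment '%s' has no foci", cur_id))
        experiments[[length(experiments) + 1L]] <<-
            experiment(cur_id, cur_n, do.call(rbind, cur_foci), space = space)
        cur_id <<- NULL; cur_n <<- NULL; cur_foci <<- list()
    }
    for (ln in seq_along(lines)) {
        line <- trimws(lines[ln])
        if (!nzchar(line)) next
        if (startsWith(line, "//")) {
            body <- trimws(sub("^//", "", line))
            if (grepl("^Reference", body, ignore.case = TRUE)) {
                m <- regmatches(body, regexec("^Reference\\s*=\\s*(\\S+)\\s*$",
                                              body, ignore.case = TRUE))[[1]]
                if (length(m) < 2)
                    stop(sprintf("line %d: malformed reference header: '%s'",
                                 ln, lines[ln]))
                sp <- toupper(m[2])
                if (grepl("^TAL", sp)) sp <- "TAL"
                else if (grepl("^MNI", sp)) sp <- "MNI"
                else stop(sprintf("line %d: unknown reference space '%s'",
                                  ln, m[2]))
                space <- sp
            } else {
                m <- regmatches(body,
                                regexec("^(.*?)\\s*:\\s*[nN]\\s*=\\s*(\\d+)\\s*$",
                                        body))[[1]]
                if (length(m) == 3) {
                    flush()
                    if (is.null(space))
                        stop(sprintf(paste0("line %d: study header before a ",
                                            "'// Reference=' header; the ",
                                            "reference space must be declared"),
                                     ln))
                    cur_id <- m[2]; cur_n <- as.integer(m[3])
                }
                # other // lines are free comments
            }
        } else {
            parts <- strsplit(line, "[\\s,;]+", perl = TRUE)[[1]]
            xyz <- suppressWarnings(as.numeric(parts))
            if (length(xyz) != 3 || any(is.na(xyz)))
                stop(sprintf("line %d: expected 'x y z' coordinates, got '%s'",
                             ln, lines[ln]))
            if (is.null(cur_id))
                stop(sprintf("line %d: coordinates before any study header", ln))
            cur_foci[[length(cur_foci) + 1L]] <- xyz
        }
    }
    flush()
    if (is.null(space) && length(experiments))
        stop("missing '// Reference=' header")
    if (is.null(space)) space <- "MNI"   # header-only/empty file round trip
    experiment_pool(name, experiments)
}

#' Write a foci table in the community text dialect
#'
#' Output is re-readable by [read_foci_text()]; coordinates are serialised
#' with two decimal places.
#'
#' @param pool an [experiment_pool()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_foci_text <- function(pool, path) {
    stopifnot(inherits(pool, "experiment_pool"))
    space <- if (length(pool$experiments)) pool_space(pool) else "MNI"
    out <- c(sprintf("// Reference=%s", space), "")
    for (e in pool$experiments) {
        out <- c(out, sprintf("// %s: n=%d", e$id, e$n_subjects),
                 sprintf("%.2f %.2f %.2f", e$foci[, 1], e$foci[, 2],
                         e$foci[, 3]),
                 "")
    }
    ok <- tryCatch({
        writeLines(out, path)
        TRUE
    }, error = function(err) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path))
        stop(sprintf("cannot write foci table to '%s'", path))
    invisible(path)
}

#' Read/write a foci pool as TSV
#'
#' Long format with one row per focus and columns `id`, `n_subjects`,
#' `space`, `effect_sign`, `x`, `y`, `z`. Per-experiment fields must be
#' constant within an id.
#'
#' @param path file path.
#' @param name pool name; defaults to the file stem.
#' @return an [experiment_pool()] (reader), or invisibly the path (writer).
#' @export
read_foci_tsv <- function(path, name = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "n_subjects", "space", "effect_sign", "x", "y", "z")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop(sprintf("TSV is missing column(s): %s",
                     paste(missing, collapse = ", ")))
    exps <- lapply(split(df, factor(df$id, levels = unique(df$id))),
                   function(d) {
        for (col in c("n_subjects", "space", "effect_sign"))
            if (length(unique(d[[col]])) != 1)
                stop(sprintf("experiment '%s': column '%s' is not constant",
                             d$id[1], col))
        experiment(as.character(d$id[1]), d$n_subjects[1],
                   as.matrix(d[, c("x", "y", "z")]),
                   space = d$space[1], effect_sign = d$effect_sign[1])
    })
    experiment_pool(name, unname(exps))
}

#' @rdname read_foci_tsv
#' @param pool an [experiment_pool()].
#' @export
write_foci_tsv <- function(pool, path) {
    rows <- lapply(pool$experiments, function(e) {
        data.frame(id = e$id, n_subjects = e$n_subjects, space = e$space,
                   effect_sign = e$effect_sign,
                   x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
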