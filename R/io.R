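# Delimited-text I/O for the pipeline's standard formats. All floats are
# written with 6 significant digits; all files are plain TSV/CSV/JSON.

fmt_num <- function(x) signif(x, 6)

#' Read and write pipeline files
#'
#' Time series are `frames x ROIs` TSV with a header row of ROI labels;
#' motion is a 7-column TSV (tx ty tz rx ry rz outlier_fraction);
#' connectivity matrices are square labeled TSV; graphs are 2-column
#' 0-based edge lists.
#'
#' @param path file path.
#' @param ts,motion,M,g objects to write.
#' @name neonet_io
NULL

#' @rdname neonet_io
#' @export
write_timeseries <- function(ts, path) {
    write.table(fmt_num(as.matrix(ts)), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname neonet_io
#' @export
read_timeseries <- function(path) {
    as.matrix(read.table(path, header = TRUE, sep = "\t", check.names = FALSE))
}

#' @rdname neonet_io
#' @export
write_motion <- function(motion, path) {
    df <- cbind(as.data.frame(fmt_num(motion$params)),
                outlier_fraction = fmt_num(motion$outlier_fraction))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname neonet_io
#' @export
read_motion <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t")
    structure(list(params = as.matrix(df[, 1:6]),
                   outlier_fraction = df$outlier_fraction),
              class = "motion_trace")
}

#' @rdname neonet_io
#' @export
write_connectivity <- function(M, path) {
    write.table(fmt_num(M), path, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
    invisible(path)
}

#' @rdname neonet_io
#' @export
read_connectivity <- function(path) {
    m <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                              check.names = FALSE))
    check_connectivity_matrix(m)
}

#' @rdname neonet_io
#' @export
write_edge_list <- function(g, path) {
    e <- edge_list(g) - 1L # 0-based on disk
    write.table(e, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a cohort to a directory
#'
#' Per-subject time series and motion TSVs plus a JSON manifest recording
#' the generator settings.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    spec <- attr(cohort, "spec")
    files <- lapply(names(cohort), function(id) {
        ts_path <- file.path(dir, paste0(id, "_timeseries.tsv"))
        mo_path <- file.path(dir, paste0(id, "_motion.tsv"))
        write_timeseries(cohort[[id]]$ts, ts_path)
        write_motion(cohort[[id]]$motion, mo_path)
        list(subject = id, timeseries = basename(ts_path),
             motion = basename(mo_path))
    })
    manifest <- list(spec = unclass(spec), subjects = files)
    manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest_path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `cohort` list (see [generate_cohort()]).
#' @export
read_cohort <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    subs <- manifest$subjects
    cohort <- lapply(seq_len(nrow(subs)), function(i) {
        list(ts = read_timeseries(file.path(dir, subs$timeseries[i])),
             motion = read_motion(file.path(dir, subs$motion[i])))
    })
    names(cohort) <- subs$subject
    structure(cohort, class = "cohort")
}
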