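## File formats: expression TSV (with a "#scale=" metadata line),
## clinical CSV, pipeline configuration (YAML), and the bundled
## transcribed count-table fixtures.

#' Write a gene-by-sample expression matrix to TSV
#'
#' First line is a metadata comment \code{#scale=counts|log2}
#' \code{platform=<tag>}; then a header row \code{id<TAB>sample...} and
#' one row per gene.  Values are written at 17 significant digits so a
#' round trip is lossless.
#'
#' @param expr a \linkS4class{PlatformExpression}
#' @param path output path
#' @export
writeExpressionTsv <- function(expr, path) {
    stopifnot(is(expr, "PlatformExpression"))
    v <- exprValues(expr)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#scale=%s platform=%s", exprScale(expr),
                       platformName(expr)), con)
    writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
    body <- apply(v, 1L, function(r)
        paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)),
              collapse = "\t"))
    writeLines(paste(rownames(v), body, sep = "\t"), con)
    invisible(path)
}

#' Read a gene-by-sample expression TSV
#'
#' Inverse of \code{\link{writeExpressionTsv}}.  Ragged rows, duplicate
#' IDs and non-numeric cells are hard errors naming the location.
#'
#' @param path path to the TSV
#' @return a \linkS4class{PlatformExpression}
#' @export
readExpressionTsv <- function(path) {
    lines <- readLines(path)
    scale <- "log2"; platform <- "generic"
    if (length(lines) && startsWith(lines[1L], "#")) {
        meta <- lines[1L]
        m <- regmatches(meta, regexec("scale=(counts|log2)", meta))[[1L]]
        if (length(m) == 2L) scale <- m[2L]
        m <- regmatches(meta, regexec("platform=(\\S+)", meta))[[1L]]
        if (length(m) == 2L) platform <- m[2L]
        lines <- lines[-1L]
    }
    if (length(lines) < 2L) stop("expression TSV has no data rows")
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1L]]
    samples <- header[-1L]
    dupS <- samples[duplicated(samples)]
    if (length(dupS))
        stop("duplicate sample column(s): ",
             paste(unique(dupS), collapse = ", "))
    nc <- length(header)
    body <- cells[-1L]
    width <- lengths(body)
    if (any(width != nc))
        stop("ragged row at line ", which(width != nc)[1L] + 2L,
             " (expected ", nc, " fields, got ",
             width[width != nc][1L], ")")
    ids <- vapply(body, `[[`, character(1), 1L)
    dupG <- ids[duplicated(ids)]
    if (length(dupG))
        stop("duplicate row ID(s): ", paste(unique(dupG), collapse = ", "))
    v <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(ids, samples))
    for (i in seq_along(body)) {
        cell <- body[[i]][-1L]
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(num) & !cell %in% c("NA", ""))
        if (length(bad))
            stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                         ids[i], samples[bad[1L]], cell[bad[1L]]))
        v[i, ] <- num
    }
    PlatformExpression(v, platform = platform, scale = scale)
}

#' Read a clinical annotation CSV
#'
#' Required columns: sample_id, hr_status, her2_status (each one of
#' "positive", "negative", "missing"), followup_time (non-negative,
#' years), event_death and event_bc (TRUE/FALSE or 1/0).
#'
#' @param path path to the CSV
#' @return validated clinical data.frame
#' @export
readClinicalCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("sample_id", "hr_status", "her2_status", "followup_time",
             "event_death", "event_bc")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("clinical CSV lacks column(s): ", paste(miss, collapse = ", "))
    for (col in c("hr_status", "her2_status")) {
        bad <- setdiff(unique(df[[col]]),
                       c("positive", "negative", "missing"))
        if (length(bad))
            stop(sprintf("unknown %s token(s): %s", col,
                         paste(bad, collapse = ", ")))
    }
    if (any(df$followup_time < 0))
        stop("negative followup_time for sample(s): ",
             paste(df$sample_id[df$followup_time < 0], collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in clinical CSV")
    df$event_death <- as.logical(df$event_death)
    df$event_bc <- as.logical(df$event_bc)
    if (anyNA(df$event_death) || anyNA(df$event_bc))
        stop("event flags must be TRUE/FALSE or 1/0")
    df[req]
}

#' Write a clinical annotation CSV
#' @param clinical clinical data.frame
#' @param path output path
#' @export
writeClinicalCsv <- function(clinical, path) {
    utils::write.table(clinical, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---------------------------------------------------------------------------
## transcribed count-table fixtures
## ---------------------------------------------------------------------------

## expected totals guarding against transcription typos:
## body sum + unclassified bookkeeping must reproduce the printed totals
.fixtureChecks <- list(
    T1 = list(total = 109L, unclassified = 1L),
    T2 = list(total = 24L,  unclassified = 0L),
    T3 = list(total = 144L, unclassified = 1L),
    T4 = list(total = 64L,  unclassified = 1L))

#' Load a bundled transcribed count-table fixture
#'
#' Four published count tables ship with the package as reviewable TSV
#' files under \code{inst/extdata}:
#' \describe{
#'   \item{T1}{IHC phenotype x SSP2 subtype counts, microarray cohort
#'     (109 cancers; 1 unclassified).}
#'   \item{T2}{matched tumor subtype x normal-tissue SSP5 call counts
#'     (24 normal breast tissues).}
#'   \item{T3}{IHC phenotype x SSP2 subtype counts, digital-count cohort
#'     (144 cancers; 6 missing IHC, 1 unclassified).}
#'   \item{T4}{paired SSP2 calls, microarray (rows) vs digital counts
#'     (columns), 64 cancers of which 1 was unclassified by microarray.}
#' }
#' Each file carries an \code{Unclassified} column holding the
#' footnoted unclassified counts; the body excludes them.  Totals are
#' validated at load and a mismatch is a hard error.
#'
#' @param tableId one of "T1", "T2", "T3", "T4"
#' @return list with \code{counts} (integer matrix, the body),
#'   \code{unclassified} (integer vector per row), \code{total}
#' @export
loadFixture <- function(tableId = c("T1", "T2", "T3", "T4")) {
    tableId <- match.arg(tableId)
    path <- system.file("extdata", paste0("table_", tableId, ".tsv"),
                        package = "PAM50concord", mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    m <- as.matrix(df)
    storage.mode(m) <- "integer"
    if ("Unclassified" %in% colnames(m)) {
        uncl <- m[, "Unclassified"]
        body <- m[, setdiff(colnames(m), "Unclassified"), drop = FALSE]
    } else if ("Unclassified" %in% rownames(m)) {
        uncl <- m["Unclassified", ]
        body <- m[setdiff(rownames(m), "Unclassified"), , drop = FALSE]
    } else {
        uncl <- rep(0L, nrow(m))
        body <- m
    }
    chk <- .fixtureChecks[[tableId]]
    if (sum(body) + sum(uncl) != chk$total)
        stop(sprintf("fixture %s total %d != expected %d (transcription error?)",
                     tableId, sum(body) + sum(uncl), chk$total))
    if (sum(uncl) != chk$unclassified)
        stop(sprintf("fixture %s unclassified count %d != expected %d",
                     tableId, sum(uncl), chk$unclassified))
    list(counts = body, unclassified = uncl, total = chk$total)
}

## ---------------------------------------------------------------------------
## pipeline configuration
## ---------------------------------------------------------------------------

.configDefaults <- function() list(
    housekeepers = DEFAULT_HOUSEKEEPERS,
    count_floor = 1,
    background_method = "mean",
    center_method = "mean",
    unclassified_threshold = 0.1,
    min_genes = 40,
    mode = "SSP5",
    knn_k = 10,
    dwd_penalty = NULL,
    seed = 1)

#' Build a validated pipeline configuration
#'
#' Houses the pipeline constants (unclassified threshold 0.1, KNN k =
#' 10, the six-gene housekeeper panel, ...).  Unknown keys and
#' out-of-range values are rejected.
#'
#' @param ... overrides of the default keys (see
#'   \code{\link{readPipelineConfig}} for the list)
#' @return named list of validated settings
#' @export
pipelineConfig <- function(...) {
    cfg <- .configDefaults()
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    if (!(cfg$unclassified_threshold > 0 && cfg$unclassified_threshold < 1))
        stop("unclassified_threshold must be in (0, 1)")
    if (cfg$min_genes < 2) stop("min_genes must be >= 2")
    if (cfg$knn_k < 1) stop("knn_k must be >= 1")
    if (!cfg$mode %in% c("SSP5", "SSP2")) stop("mode must be SSP5 or SSP2")
    if (!cfg$center_method %in% c("mean", "median"))
        stop("center_method must be mean or median")
    if (!cfg$background_method %in% c("mean", "mean2sd"))
        stop("background_method must be mean or mean2sd")
    if (cfg$count_floor <= 0) stop("count_floor must be positive")
    if (!is.null(cfg$dwd_penalty) && cfg$dwd_penalty <= 0)
        stop("dwd_penalty must be positive or NULL (auto)")
    if (!length(cfg$housekeepers)) stop("housekeepers must be non-empty")
    cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path path to the YAML file
#' @return validated configuration list
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param cfg configuration list from \code{\link{pipelineConfig}}
#' @param path output path
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(cfg, path)
    invisible(path)
}
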