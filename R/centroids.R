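## Centroid table IO and KNN completion.

#' Read a subtype centroid table from TSV
#'
#' Expects a tab-delimited file whose first column (header \code{"gene"})
#' holds gene symbols and whose remaining columns are subtype labels.
#' Empty cells or \code{"."} are recorded as missing.  Gene symbols are
#' uppercased; file row order is preserved.
#'
#' @param path path to the TSV file
#' @param expectedSubtypes character vector of subtype labels that must
#'   all be present (default: none enforced); columns are reordered to
#'   this order when given
#' @return a \linkS4class{CentroidSet}, possibly with missing entries
#' @seealso \code{\link{imputeMissingKnn}} to complete missing entries
#' @export
readCentroids <- function(path, expectedSubtypes = character()) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE, na.strings = NULL)
    if (ncol(raw) < 2L)
        stop("centroid TSV needs a gene column plus at least one subtype column")
    gene <- toupper(trimws(raw[[1L]]))
    dup <- gene[duplicated(gene)]
    if (length(dup))
        stop("duplicate gene symbol(s) in centroid table: ",
             paste(unique(dup), collapse = ", "))
    labels <- colnames(raw)[-1L]
    vals <- matrix(NA_real_, nrow(raw), length(labels),
                   dimnames = list(gene, labels))
    for (j in seq_along(labels)) {
        cell <- trimws(raw[[j + 1L]])
        empty <- cell == "" | cell == "."
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(!empty & is.na(num))
        if (length(bad))
            stop(sprintf(
                "non-numeric centroid cell at row %d ('%s'), column '%s': '%s'",
                bad[1L], gene[bad[1L]], labels[j], cell[bad[1L]]))
        num[empty] <- NA_real_
        vals[, j] <- num
    }
    if (length(expectedSubtypes)) {
        missing <- setdiff(expectedSubtypes, labels)
        if (length(missing))
            stop("centroid table lacks expected subtype(s): ",
                 paste(missing, collapse = ", "))
        vals <- vals[, expectedSubtypes, drop = FALSE]
    }
    CentroidSet(vals)
}

#' Write a centroid table to TSV
#'
#' Inverse of \code{\link{readCentroids}}: missing entries are written as
#' empty cells.
#'
#' @param centroids a \linkS4class{CentroidSet}
#' @param path output path
#' @export
writeCentroids <- function(centroids, path) {
    v <- centroidValues(centroids)
    df <- data.frame(gene = rownames(v),
                     format(v, digits = 12, trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
    df[-1L] <- lapply(df[-1L], function(col) {
        col[col == "NA"] <- ""
        col
    })
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Complete a matrix with missing entries by gene-wise KNN
#'
#' Troyanskaya-style K-nearest-neighbour imputation on the rows of a
#' genes x columns matrix.  For each missing cell (g, c) the k rows
#' nearest to g — by Euclidean distance over the columns observed in both
#' rows, scaled by the number of shared columns — among rows observed at
#' column c contribute an inverse-distance-weighted mean of their values
#' at c.  Distance ties are broken by row order.  Observed cells are
#' never changed.
#'
#' @param x numeric matrix with \code{NA} for missing entries (a
#'   \linkS4class{CentroidSet} is also accepted and returned)
#' @param k number of neighbours (default 10)
#' @return same-shape object with no missing entries
#' @details If fewer than \code{k} eligible neighbours exist for a cell,
#'   all eligible ones are used with a warning.  A row with no observed
#'   entry is an error.  Zero-distance neighbours share the weight
#'   equally (their values are averaged unweighted, overriding the
#'   positive-distance neighbours, as an exact-match row determines the
#'   value).
#' @examples
#' m <- matrix(c(1, 2, NA, 1.1, 2.1, 3.1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
#' imputeMissingKnn(m, k = 1)   # A/c3 imputed from B
#' @export
imputeMissingKnn <- function(x, k = 10) {
    if (is(x, "CentroidSet"))
        return(CentroidSet(imputeMissingKnn(centroidValues(x), k = k)))
    stopifnot(is.matrix(x), is.numeric(x))
    if (k < 1) stop("k must be >= 1")
    if (k >= nrow(x)) stop("k must be smaller than the number of rows")
    if (!anyNA(x)) return(x)
    nObs <- rowSums(!is.na(x))
    if (any(nObs == 0L))
        stop("row(s) with zero observed entries cannot be imputed: ",
             paste(utils::head(rownames(x)[nObs == 0L], 5), collapse = ", "))
    out <- x
    needs <- which(rowSums(is.na(x)) > 0L)
    shortWarned <- FALSE
    for (g in needs) {
        target <- x[g, ]
        obsT <- !is.na(target)
        ## distance to every other row over co-observed columns,
        ## normalized by the number of shared columns
        d <- rep(NA_real_, nrow(x))
        for (h in seq_len(nrow(x))) {
            if (h == g) next
            shared <- obsT & !is.na(x[h, ])
            ns <- sum(shared)
            if (ns == 0L) next
            d[h] <- sqrt(sum((target[shared] - x[h, shared])^2) / ns)
        }
        for (cc in which(is.na(target))) {
            elig <- which(!is.na(d) & !is.na(x[, cc]))
            if (!length(elig))
                stop(sprintf("no eligible neighbour for cell (%s, %s)",
                             rownames(x)[g], colnames(x)[cc]))
            if (length(elig) < k && !shortWarned) {
                warning(sprintf(
                    "fewer than k = %d eligible neighbours for some cells; using all available",
                    k))
                shortWarned <- TRUE
            }
            ord <- elig[order(d[elig], elig)]
            nb <- ord[seq_len(min(k, length(ord)))]
            dn <- d[nb]
            vn <- x[nb, cc]
            if (any(dn == 0)) {
                out[g, cc] <- mean(vn[dn == 0])
            } else {
                w <- 1 / dn
                out[g, cc] <- sum(w * vn) / sum(w)
            }
        }
    }
    out
}
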