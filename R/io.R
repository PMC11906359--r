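# Readers, writers and design-matrix construction. Supported on-disk formats
# are dense CSV and MatrixMarket MTX with gene/barcode TSVs; the internal
# orientation is always genes x cells.

#' Read a cell dataset from disk
#'
#' Builds a [SingleCellExperiment-class] from a dense CSV (genes in rows,
#' cells in columns, gene ids in the first column) or a MatrixMarket
#' directory containing \code{matrix.mtx}, \code{genes.tsv} and
#' \code{barcodes.tsv}. A cell-by-gene CSV is transposed (with a message)
#' when \code{orientation = "cells_by_genes"}. Cell metadata (TSV/CSV with a
#' \code{cell_id} column, including \code{sample_id}) is joined by cell
#' identifier.
#'
#' @param path CSV file or MTX directory.
#' @param format \code{"csv"} or \code{"mtx"}.
#' @param metaFile optional path to per-cell metadata.
#' @param orientation matrix orientation of a CSV input.
#' @param assayType whether the values are raw \code{"counts"} (validated to
#'   be non-negative integers) or transformed \code{"values"}.
#' @return a [SingleCellExperiment-class].
#' @export
readCellDataset <- function(path, format = c("csv", "mtx"), metaFile = NULL,
                            orientation = c("genes_by_cells",
                                            "cells_by_genes"),
                            assayType = c("counts", "values")) {
    format <- match.arg(format)
    orientation <- match.arg(orientation)
    assayType <- match.arg(assayType)
    if (format == "csv") {
        df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
        m <- as.matrix(df)
        if (orientation == "cells_by_genes") {
            message("transposing cell x gene input to genes x cells")
            m <- t(m)
        }
    } else {
        mtx <- file.path(path, "matrix.mtx")
        genes <- file.path(path, "genes.tsv")
        cells <- file.path(path, "barcodes.tsv")
        if (!all(file.exists(mtx, genes, cells)))
            stop("MTX directory must contain matrix.mtx, genes.tsv ",
                 "and barcodes.tsv")
        m <- as.matrix(Matrix::readMM(mtx))
        rownames(m) <- utils::read.table(genes)[, 1]
        colnames(m) <- utils::read.table(cells)[, 1]
    }
    if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
    if (assayType == "counts" &&
        (any(m < 0) || max(abs(m - round(m))) > 0))
        stop("counts were claimed but the matrix holds negative or ",
             "non-integer values")
    meta <- DataFrame(row.names = colnames(m))
    if (!is.null(metaFile)) {
        mt <- utils::read.delim(metaFile,
                                sep = if (grepl("\\.csv$", metaFile)) ","
                                      else "\t")
        if (!"cell_id" %in% colnames(mt))
            stop("metadata must contain a cell_id column")
        idx <- match(colnames(m), mt$cell_id)
        if (anyNA(idx)) stop("metadata is missing entries for some cells")
        meta <- DataFrame(mt[idx, setdiff(colnames(mt), "cell_id"),
                             drop = FALSE], row.names = colnames(m))
    }
    assays <- if (assayType == "counts") list(counts = m)
              else list(logcounts = m)
    SingleCellExperiment(assays = assays, colData = meta)
}

#' Write a cell dataset to a dense CSV
#'
#' Inverse of [readCellDataset()] for the CSV format: genes in rows, cells
#' in columns, plus an optional metadata TSV with a \code{cell_id} column.
#'
#' @param sce a [SingleCellExperiment-class].
#' @param file output CSV path.
#' @param metaFile optional metadata TSV path.
#' @param assay assay to write.
#' @export
writeCellDatasetCsv <- function(sce, file, metaFile = NULL,
                                assay = "counts") {
    m <- as.matrix(SummarizedExperiment::assay(sce, assay))
    utils::write.csv(as.data.frame(m), file, row.names = TRUE)
    if (!is.null(metaFile)) {
        md <- as.data.frame(colData(sce))
        md <- cbind(cell_id = rownames(md), md)
        utils::write.table(md, metaFile, sep = "\t", row.names = FALSE,
                           quote = FALSE)
    }
    invisible(file)
}

#' Read matching sets from a two-column TSV
#'
#' File format: \code{cell_id} and \code{group_id} columns (header
#' optional); unknown cell ids raise an error. Returns a list of cell-id
#' vectors suitable for [alignWithSets()], which itself drops groups
#' confined to a single condition.
#'
#' @param path TSV path.
#' @return named list of character vectors.
#' @export
readMatchingSets <- function(path) {
    df <- utils::read.delim(path, header = TRUE,
                            col.names = c("cell_id", "group_id"))
    split(as.character(df$cell_id), df$group_id)
}

#' Build a design matrix from cell metadata
#'
#' Expands a formula on the metadata into a full-rank numeric design with an
#' intercept and treatment-coded factors. For a continuous covariate a
#' natural cubic spline basis can be appended (\code{spline = list(covariate
#' = "time", df = 3)}): boundary knots at the covariate range, internal
#' knots at quantiles, as in \code{splines::ns}. Rank deficiency is reported
#' with the names of the collinear columns.
#'
#' @param meta per-cell data.frame.
#' @param spec model formula (e.g. \code{~ condition}), or an explicit
#'   numeric matrix passed through unchanged after a rank check.
#' @param spline optional list \code{(covariate, df)}.
#' @return list with \code{matrix} (C x K, named columns) and
#'   \code{formula}.
#' @export
buildDesign <- function(meta, spec, spline = NULL) {
    meta <- as.data.frame(meta)
    if (!inherits(spec, "formula")) {
        X <- as.matrix(spec)
        .checkDesignRank(X)
        return(list(matrix = X, formula = NULL))
    }
    if (!is.null(spline)) {
        stopifnot(is.list(spline), !is.null(spline$covariate),
                  !is.null(spline$df))
        add <- sprintf("splines::ns(%s, df = %d)", spline$covariate,
                       as.integer(spline$df))
        spec <- stats::update(spec, paste("~ . +", add))
    }
    X <- model.matrix(spec, data = meta)
    .checkDesignRank(X)
    list(matrix = X, formula = spec)
}

.checkDesignRank <- function(X) {
    qrd <- qr(X)
    if (qrd$rank < ncol(X)) {
        bad <- colnames(X)[qrd$pivot[(qrd$rank + 1):ncol(X)]]
        stop("design matrix is rank deficient; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    invisible(TRUE)
}

#' Write pipeline results to a directory
#'
#' Emits \code{de_table.tsv} (genes ordered by adjusted p-value, ties by
#' gene name), \code{neighborhoods.tsv} (gene, cell_id), and
#' \code{run_config.json} with the resolved configuration, contrast and
#' package version. Optionally serializes the fit object as
#' \code{fit.rds}.
#'
#' @param result a [LemurDEResult-class].
#' @param outDir output directory (created if missing).
#' @param fit optional [LemurFit-class] to serialize.
#' @return invisibly, the output directory.
#' @export
writeResults <- function(result, outDir, fit = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    tab <- as.data.frame(deTable(result))
    ord <- order(tab$adjPval, tab$gene, na.last = TRUE)
    utils::write.table(tab[ord, ], file.path(outDir, "de_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    nbh <- neighborhoods(result)
    keep <- !vapply(nbh, is.null, logical(1))
    nbhDf <- if (any(keep)) {
        data.frame(gene = rep(names(nbh)[keep],
                              vapply(nbh[keep], function(x)
                                  length(x$cells), integer(1))),
                   cell_id = unlist(lapply(nbh[keep], `[[`, "cells"),
                                    use.names = FALSE))
    } else data.frame(gene = character(0), cell_id = character(0))
    utils::write.table(nbhDf, file.path(outDir, "neighborhoods.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cfg <- result@config
    cfg$contrast <- result@contrast
    cfg$package_version <- as.character(utils::packageVersion("lemda"))
    jsonlite::write_json(cfg, file.path(outDir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    if (!is.null(fit)) saveRDS(fit, file.path(outDir, "fit.rds"))
    invisible(outDir)
}
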