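# Count preprocessing: size factors and the variance-stabilizing transform.

#' Normed-sum size factors
#'
#' Per-cell size factor \eqn{sf_c = s_c / mean(s)} where \eqn{s_c} is the
#' column (cell) total. The mean size factor is 1 by construction.
#'
#' @param counts non-negative G x C count matrix (dense or sparse).
#' @return positive numeric vector of length C.
#' @examples
#' sizeFactorsNormedSum(matrix(c(10, 0, 30, 0, 10, 10), nrow = 2))
#' @export
sizeFactorsNormedSum <- function(counts) {
    cs <- Matrix::colSums(counts)
    if (any(cs <= 0)) {
        bad <- which(cs <= 0)
        nm <- colnames(counts)[bad]
        if (is.null(nm)) nm <- bad
        stop("cells with zero total count cannot be normalized: ",
             paste(utils::head(nm, 5), collapse = ", "))
    }
    sf <- cs / mean(cs)
    names(sf) <- colnames(counts)
    sf
}

#' Shifted logarithm transform
#'
#' Variance-stabilizing transform
#' \eqn{y_{gc} = \log(k_{gc} / sf_c + pseudo)} applied to size-normalized
#' counts. With the default pseudo-count of 1 this is \code{log1p} of the
#' normalized counts.
#'
#' @param counts non-negative G x C count matrix.
#' @param sf positive length-C size factors; computed with
#'   [sizeFactorsNormedSum()] when missing.
#' @param pseudo positive pseudo-count, default 1.
#' @return dense numeric G x C matrix.
#' @export
shiftedLogTransform <- function(counts, sf = NULL, pseudo = 1) {
    if (pseudo <= 0) stop("pseudo-count must be positive")
    if (is.null(sf)) sf <- sizeFactorsNormedSum(counts)
    stopifnot(length(sf) == ncol(counts), all(sf > 0))
    m <- as.matrix(counts)
    log(sweep(m, 2, sf, "/") + pseudo)
}
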