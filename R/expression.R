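#' Construct an expression study
#'
#' @param exprs numeric matrix, genes x samples, non-negative linear-scale
#'   expression levels, with gene symbols as rownames and sample ids as
#'   colnames.
#' @param cohort character/factor vector of \code{"young"}/\code{"old"}
#'   labels, one per sample; if named, names are matched against the matrix
#'   colnames.
#' @return an [ExpressionStudy-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'             dimnames = list(c("G1", "G2"), c("y1", "y2", "o1")))
#' ExpressionStudy(m, c(y1 = "young", y2 = "young", o1 = "old"))
#' @export
ExpressionStudy <- function(exprs, cohort) {
    exprs <- as.matrix(exprs)
    rownames(exprs) <- toupper(rownames(exprs))
    if (!is.null(names(cohort))) {
        miss <- setdiff(colnames(exprs), names(cohort))
        if (length(miss))
            stop("samples present in the matrix but absent from metadata: ",
                 paste(miss, collapse = ", "))
        cohort <- cohort[colnames(exprs)]
    } else if (length(cohort) != ncol(exprs)) {
        stop("cohort must have one label per sample")
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = S4Vectors::DataFrame(cohort = as.character(cohort),
                                       row.names = colnames(exprs)))
    new("ExpressionStudy", se)
}

#' @rdname ExpressionStudy-class
#' @export
setMethod("cohort", "ExpressionStudy", function(x)
    stats::setNames(as.character(SummarizedExperiment::colData(x)$cohort),
                    colnames(x)))

#' @rdname ExpressionStudy-class
#' @export
setMethod("youngSamples", "ExpressionStudy", function(x)
    colnames(x)[cohort(x) == "young"])

#' @rdname ExpressionStudy-class
#' @export
setMethod("oldSamples", "ExpressionStudy", function(x)
    colnames(x)[cohort(x) == "old"])

#' @rdname ExpressionStudy-class
#' @export
setMethod("exprValues", "ExpressionStudy", function(x)
    SummarizedExperiment::assay(x, "exprs"))

setMethod("show", "ExpressionStudy", function(object) {
    cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples",
        sprintf("(%d young, %d old)\n",
                length(youngSamples(object)), length(oldSamples(object))))
})

#' Read an expression matrix and cohort metadata
#'
#' The matrix file is tab-separated with a first column \code{gene} and one
#' column per sample; the metadata file is tab-separated with columns
#' \code{sample_id} and \code{cohort} (labels \code{young}/\code{old}).
#'
#' @param matrixPath path to the expression TSV.
#' @param metadataPath path to the metadata TSV.
#' @return a validated [ExpressionStudy-class].
#' @seealso [ExpressionStudy()]
#' @export
readExpression <- function(matrixPath, metadataPath) {
    if (!file.exists(matrixPath)) stop("expression matrix not found: ", matrixPath)
    if (!file.exists(metadataPath)) stop("metadata file not found: ", metadataPath)
    tab <- utils::read.delim(matrixPath, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L || !identical(tolower(colnames(tab)[1]), "gene"))
        stop("expression matrix must have a leading 'gene' column")
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (any(is.na(m))) stop("expression matrix contains missing values")
    if (any(m < 0)) stop("negative expression value in ", basename(matrixPath))
    rownames(m) <- toupper(tab[[1]])
    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "cohort") %in% colnames(meta)))
        stop("metadata must have columns sample_id and cohort")
    bad <- setdiff(meta$cohort, c("young", "old"))
    if (length(bad))
        stop("cohort label outside {young, old}: ", paste(bad, collapse = ", "))
    ExpressionStudy(m, stats::setNames(meta$cohort, meta$sample_id))
}

#' Normalize an expression study across samples
#'
#' \describe{
#'   \item{\code{none}}{identity; the default, for pre-normalized input.}
#'   \item{\code{median_scale}}{each sample is rescaled so that all sample
#'     medians equal the median of the per-sample medians.}
#'   \item{\code{quantile}}{quantile normalization
#'     (\code{limma::normalizeQuantiles}); all samples share one empirical
#'     distribution afterwards.}
#' }
#' Normalization is applied to all samples jointly, before any scoring, so
#' the young reference is computed on the same scale as the old samples.
#'
#' @param study an [ExpressionStudy-class].
#' @param method one of \code{"none"}, \code{"median_scale"},
#'   \code{"quantile"}.
#' @return a new [ExpressionStudy-class] with non-negative values.
#' @export
normalizeStudy <- function(study, method = c("none", "median_scale", "quantile")) {
    stopifnot(is(study, "ExpressionStudy"))
    method <- match.arg(method)
    v <- exprValues(study)
    v2 <- switch(method,
        none = v,
        median_scale = {
            med <- apply(v, 2, stats::median)
            if (any(med <= 0))
                stop("median_scale requires positive per-sample medians")
            target <- stats::median(med)
            sweep(v, 2, med / target, "/")
        },
        quantile = limma::normalizeQuantiles(v))
    v2[v2 < 0] <- 0  # guard against numeric fuzz
    ExpressionStudy(v2, cohort(study))
}

#' Per-gene young-cohort reference statistics
#'
#' Computes, over the young samples only, the per-gene arithmetic mean and
#' sample standard deviation (n - 1 denominator) of expression. These are the
#' reference against which OYR ratios and the 2-SD tolerance criterion are
#' evaluated.
#'
#' @param study an [ExpressionStudy-class] with >= 2 young samples.
#' @return a \code{data.frame} with rownames = genes and columns \code{mean},
#'   \code{sd}.
#' @examples
#' m <- matrix(c(1, 2, 3, 10), nrow = 1,
#'             dimnames = list("G1", c("y1", "y2", "y3", "o1")))
#' st <- ExpressionStudy(m, c("young", "young", "young", "old"))
#' youngReference(st)  # mean 2, sd 1
#' @export
youngReference <- function(study) {
    stopifnot(is(study, "ExpressionStudy"))
    v <- exprValues(study)[, youngSamples(study), drop = FALSE]
    data.frame(mean = rowMeans(v),
               sd = apply(v, 1, stats::sd),
               row.names = rownames(v))
}
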