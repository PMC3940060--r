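#' @import methods
NULL

## ARR (activator/repressor role) weights are a closed 5-value set: +1 pure
## activator, -1 pure repressor, +/-0.5 predominant role, 0 ambivalent.
.ARR_DOMAIN <- c(-1, -0.5, 0, 0.5, 1)

#' Role-annotated pathway
#'
#' A named gene set in which every member gene carries a discrete
#' activator/repressor role (ARR) weight used by the pathway activation
#' strength (PAS) score. Allowed ARR values are -1 (repressor), 1 (activator),
#' -0.5/0.5 (predominantly repressor/activator) and 0 (ambivalent).
#'
#' @slot pathwayId single identifier string, unique within a cloud.
#' @slot pathwayName human-readable pathway name.
#' @slot members \code{data.frame} with columns \code{gene} (uppercase symbol)
#'   and \code{arr} (numeric ARR weight).
#'
#' @seealso [RoleAnnotatedPathway()], [PathwayCloud-class]
#' @export
setClass("RoleAnnotatedPathway",
    representation(pathwayId = "character",
                   pathwayName = "character",
                   members = "data.frame"))

setValidity("RoleAnnotatedPathway", function(object) {
    msg <- NULL
    if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
        msg <- c(msg, "pathwayId must be a single non-empty string")
    if (length(object@pathwayName) != 1L)
        msg <- c(msg, "pathwayName must be a single string")
    m <- object@members
    if (!all(c("gene", "arr") %in% colnames(m)))
        msg <- c(msg, "members must have columns 'gene' and 'arr'")
    else {
        if (nrow(m) < 1L)
            msg <- c(msg, "pathway must have at least one member gene")
        if (any(!nzchar(m$gene)))
            msg <- c(msg, "member gene symbols must be non-empty")
        if (anyDuplicated(m$gene))
            msg <- c(msg, sprintf("duplicate member gene(s): %s",
                paste(unique(m$gene[duplicated(m$gene)]), collapse = ", ")))
        if (!is.numeric(m$arr) || !all(m$arr %in% .ARR_DOMAIN))
            msg <- c(msg, "invalid ARR: every arr must be one of -1, -0.5, 0, 0.5, 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' Pathway cloud
#'
#' An ordered collection of [RoleAnnotatedPathway-class] objects with unique
#' identifiers. The cloud is the joint scoring unit: disturbance of the
#' old-versus-young activation profile is accumulated over all its pathways.
#'
#' @slot pathways list of \code{RoleAnnotatedPathway}, named by pathway id;
#'   iteration order is load/construction order and is deterministic.
#' @slot provenance free-text description of how the cloud was built.
#'
#' @seealso [PathwayCloud()], [readPathwayFile()], [runORA()]
#' @export
setClass("PathwayCloud",
    representation(pathways = "list", provenance = "character"))

setValidity("PathwayCloud", function(object) {
    msg <- NULL
    ok <- vapply(object@pathways, is, logical(1), "RoleAnnotatedPathway")
    if (!all(ok))
        msg <- c(msg, "all elements of pathways must be RoleAnnotatedPathway")
    else {
        ids <- vapply(object@pathways, function(p) p@pathwayId, character(1))
        if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicate pathway id(s): %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
        if (length(ids) && !identical(unname(names(object@pathways)), unname(ids)))
            msg <- c(msg, "pathways list must be named by pathway id")
    }
    if (length(object@provenance) != 1L)
        msg <- c(msg, "provenance must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' Expression study with young/old cohorts
#'
#' A \code{SummarizedExperiment} holding a non-negative, linear-scale
#' expression matrix (genes x samples, assay \code{"exprs"}) together with a
#' \code{cohort} column in \code{colData} assigning each sample to the
#' \code{"young"} or \code{"old"} group. At least two young samples are
#' required so that the per-gene young standard deviation is defined, and at
#' least one old sample so that there is something to score.
#'
#' @seealso [ExpressionStudy()], [readExpression()], [youngReference()],
#'   [scoreStudy()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v) || any(!is.finite(v)))
            msg <- c(msg, "expression values must be finite numbers")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene symbols (rownames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"cohort" %in% colnames(cd))
        msg <- c(msg, "colData must have a 'cohort' column")
    else {
        co <- as.character(cd$cohort)
        if (!all(co %in% c("young", "old")))
            msg <- c(msg, "cohort labels must be 'young' or 'old'")
        else {
            if (sum(co == "young") < 2L)
                msg <- c(msg, "at least 2 young samples required (young SD undefined otherwise)")
            if (sum(co == "old") < 1L)
                msg <- c(msg, "at least 1 old sample required")
        }
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.null(msg)) TRUE else msg
})

#' Drug library
#'
#' Candidate drugs encoded as multiplicative fold-change effects on the
#' expression of their target genes: \code{fold_change < 1} models
#' inhibition, \code{> 1} activation. One effect per (drug, gene) pair.
#'
#' @slot effects \code{data.frame} with columns \code{drug_id}, \code{gene}
#'   (uppercase symbol) and \code{fold_change} (positive, finite).
#'
#' @seealso [DrugLibrary()], [readDrugLibrary()], [applyDrug()],
#'   [screenDrugs()]
#' @export
setClass("DrugLibrary", representation(effects = "data.frame"))

setValidity("DrugLibrary", function(object) {
    msg <- NULL
    e <- object@effects
    if (!all(c("drug_id", "gene", "fold_change") %in% colnames(e)))
        msg <- c(msg, "effects must have columns drug_id, gene, fold_change")
    else {
        if (nrow(e) < 1L)
            msg <- c(msg, "drug library must contain at least one effect")
        if (!is.numeric(e$fold_change) ||
            any(!is.finite(e$fold_change)) || any(e$fold_change <= 0))
            msg <- c(msg, "fold_change must be positive and finite")
        if (anyDuplicated(e[, c("drug_id", "gene")]))
            msg <- c(msg, "one effect per gene per drug: duplicate (drug_id, gene) pair")
        if (any(!nzchar(e$drug_id)) || any(!nzchar(e$gene)))
            msg <- c(msg, "drug_id and gene must be non-empty")
    }
    if (is.null(msg)) TRUE else msg
})

#' Pathway-cloud disturbance report
#'
#' Result container of [scoreStudy()]: per-old-sample pathway activation
#' strength (PAS) profiles, the mean-of-old profile, and the cumulative
#' disturbance D (L1 or L2 norm of each PAS vector). PAS is a signed
#' log-scale score; D >= 0 and D = 0 exactly when every PAS value is 0.
#'
#' @slot pas numeric matrix, pathways x old samples.
#' @slot pasMean numeric vector, per-pathway arithmetic mean of the
#'   per-sample PAS values ("mean-of-old" profile).
#' @slot disturbance numeric vector of per-old-sample D values.
#' @slot disturbanceMean D of the mean-of-old profile.
#' @slot norm \code{"L1"} or \code{"L2"}.
#' @slot logBase base of the logarithm used in PAS.
#' @slot epsilon expression floor applied before ratios/logs.
#' @slot skippedGenes integer vector: per pathway, how many member genes were
#'   absent from the expression matrix (skipped, not imputed).
#'
#' @seealso [scoreStudy()], [computeDisturbance()]
#' @export
setClass("DisturbanceReport",
    representation(pas = "matrix", pasMean = "numeric",
                   disturbance = "numeric", disturbanceMean = "numeric",
                   norm = "character", logBase = "numeric",
                   epsilon = "numeric", skippedGenes = "integer"))

setValidity("DisturbanceReport", function(object) {
    msg <- NULL
    if (any(!is.finite(object@pas)))
        msg <- c(msg, "PAS values must be finite")
    if (!object@norm %in% c("L1", "L2"))
        msg <- c(msg, "norm must be 'L1' or 'L2'")
    if (length(object@pasMean) != nrow(object@pas))
        msg <- c(msg, "pasMean length must match number of pathways")
    if (length(object@disturbance) != ncol(object@pas))
        msg <- c(msg, "one disturbance value per old sample required")
    if (is.null(msg)) TRUE else msg
})
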