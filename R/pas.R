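#' Old-to-young expression ratio (OYR)
#'
#' OYR for a gene is the expression level in an old sample divided by the
#' mean expression of the same gene in the (normalized) young cohort. Both
#' numerator and denominator are floored at \code{floor} so the ratio is
#' strictly positive and finite even for unexpressed genes.
#'
#' @param oldValue expression level(s) in the old sample, >= 0 (vectorized).
#' @param youngMean young-cohort mean expression, >= 0 (vectorized).
#' @param floor expression floor epsilon (default \code{1e-6}).
#' @return numeric vector of ratios, strictly positive and finite.
#' @examples
#' computeOYR(4, 2)        # 2
#' computeOYR(0, 1)        # 1e-6
#' @export
computeOYR <- function(oldValue, youngMean, floor = 1e-6) {
    if (any(oldValue < 0) || any(youngMean < 0))
        stop("expression levels must be non-negative")
    stopifnot(floor > 0)
    pmax(oldValue, floor) / pmax(youngMean, floor)
}

#' Beyond-tolerance-interval flag (BTIF)
#'
#' A gene is flagged (BTIF = 1) only when two criteria hold simultaneously:
#' its OYR is strictly above 3/2 or strictly below 2/3, and its old-sample
#' expression level differs from the young mean by strictly more than two
#' young-cohort standard deviations. All inequalities are strict, so
#' OYR = 1.5 exactly is not flagged.
#'
#' When the young SD is zero the deviation is taken as 0 if the old value
#' equals the young mean and +Inf otherwise; \code{sdZero = "fail"} makes a
#' zero-SD gene never pass the 2-SD criterion instead.
#'
#' @param oyr OYR ratio(s) from [computeOYR()].
#' @param oldValue old-sample expression level(s).
#' @param youngMean young-cohort mean(s).
#' @param youngSd young-cohort standard deviation(s), >= 0.
#' @param sdZero policy for SD = 0 genes: \code{"pass"} (default) or
#'   \code{"fail"}.
#' @return integer vector of 0/1 flags.
#' @examples
#' computeBTIF(2.0, 4, 2, 0.5)  # 1: ratio and 2-SD criteria both met
#' computeBTIF(1.4, 4, 2, 0.5)  # 0: within fold tolerance
#' computeBTIF(2.0, 4, 2, 1.5)  # 0: only 1.33 SD away
#' @export
computeBTIF <- function(oyr, oldValue, youngMean, youngSd,
                        sdZero = c("pass", "fail")) {
    sdZero <- match.arg(sdZero)
    stopifnot(all(is.finite(oyr)), all(is.finite(oldValue)),
              all(is.finite(youngMean)), all(is.finite(youngSd)),
              all(youngSd >= 0))
    dev <- deviationSD(oldValue, youngMean, youngSd)
    beyond_fold <- oyr > 3 / 2 | oyr < 2 / 3
    beyond_sd <- dev > 2
    if (sdZero == "fail") beyond_sd <- beyond_sd & youngSd > 0
    as.integer(beyond_fold & beyond_sd)
}

#' @rdname computeBTIF
#' @details \code{deviationSD} returns |old - young mean| / young SD, with
#'   the SD = 0 convention described above.
#' @export
deviationSD <- function(oldValue, youngMean, youngSd) {
    d <- abs(oldValue - youngMean)
    ifelse(youngSd == 0, ifelse(d == 0, 0, Inf), d / youngSd)
}

#' Pathway activation strength (PAS)
#'
#' The signed log-additive pathway score
#' \deqn{PAS_p = \sum_n ARR_{np} \cdot BTIF_n \cdot \log(OYR_n)}
#' summed over the pathway's member genes that are present in the study.
#' Activators pushed up and repressors pushed down in old samples both drive
#' PAS positive ("activated" pathway); genes inside the tolerance interval
#' (BTIF = 0) contribute nothing, so an undisturbed pathway scores exactly 0.
#'
#' @param pathway a [RoleAnnotatedPathway-class].
#' @param oyr named numeric vector of OYR values (names = gene symbols).
#' @param btif named integer vector of BTIF flags, same names as \code{oyr}.
#' @param logBase base of the logarithm: 10 (default), 2 or \code{exp(1)}.
#' @return a list with \code{pas} (finite numeric) and \code{skipped}
#'   (number of member genes absent from \code{oyr}).
#' @examples
#' p <- RoleAnnotatedPathway("P1", "GENEA", 1)
#' computePAS(p, c(GENEA = 10), c(GENEA = 1L))  # pas = 1
#' @export
computePAS <- function(pathway, oyr, btif, logBase = 10) {
    stopifnot(is(pathway, "RoleAnnotatedPathway"), logBase > 0, logBase != 1)
    m <- pathway@members
    present <- m$gene %in% names(oyr)
    skipped <- sum(!present)
    if (!any(present))
        return(list(pas = 0, skipped = skipped))
    g <- m$gene[present]
    pas <- sum(m$arr[present] * as.numeric(btif[g]) * log(oyr[g], base = logBase))
    list(pas = unname(pas), skipped = skipped)
}

#' Multiplicative signal pathway cloud disturbance (SPCD) estimator
#'
#' The product of (floored) activator expression levels divided by the
#' product of (floored) repressor levels. Its logarithm is the sum of
#' activator log-levels minus the sum of repressor log-levels, which links
#' the multiplicative estimator to the additive PAS form.
#'
#' @param activatorLevels numeric vector of activator expression levels, >= 0.
#' @param repressorLevels numeric vector of repressor expression levels, >= 0.
#' @param floor expression floor epsilon (default \code{1e-6}).
#' @return single positive finite ratio.
#' @examples
#' computeSPCD(c(2, 3), 2)  # 3
#' @export
computeSPCD <- function(activatorLevels, repressorLevels, floor = 1e-6) {
    if (any(activatorLevels < 0) || any(repressorLevels < 0))
        stop("expression levels must be non-negative")
    stopifnot(floor > 0)
    ## products in log space to avoid overflow on long gene lists
    exp(sum(log(pmax(activatorLevels, floor))) -
        sum(log(pmax(repressorLevels, floor))))
}

#' Cumulative disturbance of a PAS profile
#'
#' The screening objective: the L1 (default) or L2 norm of the PAS vector.
#' Zero exactly when every pathway's PAS is zero, i.e. when the old profile
#' is indistinguishable from the young reference under the tolerance rules.
#'
#' @param pas numeric vector of per-pathway PAS values.
#' @param norm \code{"L1"} or \code{"L2"}.
#' @return single number, >= 0.
#' @examples
#' computeDisturbance(c(1, -2))          # 3
#' computeDisturbance(c(3, 4), "L2")     # 5
#' @export
computeDisturbance <- function(pas, norm = c("L1", "L2")) {
    norm <- match.arg(norm)
    stopifnot(all(is.finite(pas)))
    switch(norm, L1 = sum(abs(pas)), L2 = sqrt(sum(pas^2)))
}

#' Per-gene scores for one old sample
#'
#' Computes OYR, BTIF and the SD-deviation for every gene in the study,
#' for a single old sample against the young reference.
#'
#' @param study an [ExpressionStudy-class].
#' @param sample an old sample id.
#' @param floor expression floor epsilon.
#' @param sdZero zero-SD policy, see [computeBTIF()].
#' @return \code{data.frame} with rownames = genes and columns \code{oyr},
#'   \code{btif}, \code{deviation_sd}.
#' @export
geneScores <- function(study, sample, floor = 1e-6,
                       sdZero = c("pass", "fail")) {
    stopifnot(is(study, "ExpressionStudy"))
    sdZero <- match.arg(sdZero)
    if (!sample %in% oldSamples(study))
        stop("'", sample, "' is not an old sample of the study")
    ref <- youngReference(study)
    old <- exprValues(study)[, sample]
    oyr <- computeOYR(old, ref$mean, floor = floor)
    data.frame(
        oyr = oyr,
        btif = computeBTIF(oyr, old, ref$mean, ref$sd, sdZero = sdZero),
        deviation_sd = deviationSD(old, ref$mean, ref$sd),
        row.names = rownames(ref))
}

#' Score a study against a pathway cloud
#'
#' The end-to-end scoring pipeline: for every old sample, per-gene OYR and
#' BTIF are computed against the young reference, PAS is accumulated per
#' pathway, and the cumulative disturbance D is taken over the cloud. Old
#' samples are scored individually and then averaged at the PAS level
#' (arithmetic mean per pathway) into the "mean-of-old" profile, preserving
#' per-sample profiles for individual-level use.
#'
#' Member genes absent from the expression matrix are skipped (never
#' imputed) and their per-pathway count is reported in the result.
#'
#' @param study an [ExpressionStudy-class].
#' @param cloud a [PathwayCloud-class] with >= 1 pathway.
#' @param logBase PAS logarithm base (default 10).
#' @param norm disturbance norm, \code{"L1"} (default) or \code{"L2"}.
#' @param floor expression floor epsilon (default \code{1e-6}).
#' @param sdZero zero-SD policy, see [computeBTIF()].
#' @return a [DisturbanceReport-class].
#' @examples
#' set.seed(1)
#' sim <- simulateStudy(simulationConfig(nGenes = 20, nPathways = 2,
#'                                       genesPerPathway = 5, seed = 1))
#' scoreStudy(sim$study, sim$cloud)
#' @export
scoreStudy <- function(study, cloud, logBase = 10, norm = c("L1", "L2"),
                       floor = 1e-6, sdZero = c("pass", "fail")) {
    stopifnot(is(study, "ExpressionStudy"), is(cloud, "PathwayCloud"))
    norm <- match.arg(norm)
    sdZero <- match.arg(sdZero)
    if (length(cloud) == 0L)
        stop("nothing to score: empty pathway cloud")
    olds <- oldSamples(study)
    if (length(olds) == 0L)
        stop("study has no old samples")

    ids <- pathwayIds(cloud)
    pas <- matrix(0, nrow = length(ids), ncol = length(olds),
                  dimnames = list(ids, olds))
    skipped <- stats::setNames(integer(length(ids)), ids)
    for (s in olds) {
        gs <- geneScores(study, s, floor = floor, sdZero = sdZero)
        oyr <- stats::setNames(gs$oyr, rownames(gs))
        btif <- stats::setNames(gs$btif, rownames(gs))
        for (id in ids) {
            r <- computePAS(cloud[[id]], oyr, btif, logBase = logBase)
            pas[id, s] <- r$pas
            skipped[id] <- r$skipped
        }
    }
    unmeasured <- ids[vapply(ids, function(id)
        skipped[[id]] == nrow(cloud[[id]]@members), logical(1))]
    if (length(unmeasured))
        warning("unmeasured pathway (no member gene in the matrix): ",
                paste(unmeasured, collapse = ", "))

    pas_mean <- rowMeans(pas)
    new("DisturbanceReport",
        pas = pas, pasMean = pas_mean,
        disturbance = apply(pas, 2, computeDisturbance, norm = norm),
        disturbanceMean = computeDisturbance(pas_mean, norm = norm),
        norm = norm, logBase = logBase, epsilon = floor,
        skippedGenes = skipped)
}

#' @rdname DisturbanceReport-class
#' @export
setMethod("pasMatrix", "DisturbanceReport", function(x) x@pas)

#' @rdname DisturbanceReport-class
#' @export
setMethod("pasMean", "DisturbanceReport", function(x) x@pasMean)

#' @rdname DisturbanceReport-class
#' @export
setMethod("disturbance", "DisturbanceReport", function(x) x@disturbance)

#' @rdname DisturbanceReport-class
#' @export
setMethod("disturbanceMean", "DisturbanceReport", function(x) x@disturbanceMean)

#' @rdname DisturbanceReport-class
#' @export
setMethod("skippedGenes", "DisturbanceReport", function(x) x@skippedGenes)

setMethod("show", "DisturbanceReport", function(object) {
    cat("DisturbanceReport:", nrow(object@pas), "pathway(s) x",
        ncol(object@pas), "old sample(s)\n")
    cat(sprintf("  norm %s, log base %s, epsilon %g\n",
                object@norm, format(object@logBase), object@epsilon))
    cat(sprintf("  D (mean-of-old profile): %.4g\n", object@disturbanceMean))
    cat(sprintf("  per-sample D: %s\n",
                paste(sprintf("%.4g", object@disturbance), collapse = ", ")))
})

#' Write a disturbance report as TSV
#'
#' One row per pathway with the per-sample PAS columns and the mean-of-old
#' PAS, followed by a final \code{__disturbance__} row holding the D values.
#'
#' @param report a [DisturbanceReport-class].
#' @param path destination TSV path.
#' @return invisibly, \code{path}.
#' @export
writePASReport <- function(report, path) {
    stopifnot(is(report, "DisturbanceReport"))
    tab <- data.frame(pathway_id = rownames(report@pas),
                      report@pas, pas_mean = report@pasMean,
                      check.names = FALSE)
    dist_row <- c("__disturbance__", report@disturbance, report@disturbanceMean)
    out <- rbind(tab, stats::setNames(as.list(dist_row), colnames(tab)))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
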