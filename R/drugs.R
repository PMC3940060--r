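#' Construct a drug library
#'
#' @param effects \code{data.frame} with columns \code{drug_id}, \code{gene}
#'   and either \code{fold_change} (positive multiplicative effect) or
#'   \code{direction} (\code{"inhibit"}/\code{"activate"}, mapped to the
#'   default fold-changes 0.5 / 2).
#' @return a [DrugLibrary-class].
#' @examples
#' DrugLibrary(data.frame(drug_id = "rapalogue", gene = "MTOR",
#'                        fold_change = 0.5))
#' @export
DrugLibrary <- function(effects) {
    effects <- as.data.frame(effects)
    if (!"fold_change" %in% colnames(effects)) {
        if (!"direction" %in% colnames(effects))
            stop("effects need a fold_change or a direction column")
        bad <- setdiff(effects$direction, c("inhibit", "activate"))
        if (length(bad))
            stop("direction must be 'inhibit' or 'activate', got: ",
                 paste(bad, collapse = ", "))
        effects$fold_change <- ifelse(effects$direction == "inhibit", 0.5, 2)
    }
    effects$gene <- toupper(effects$gene)
    effects$drug_id <- as.character(effects$drug_id)
    new("DrugLibrary",
        effects = effects[, c("drug_id", "gene", "fold_change")])
}

#' @rdname DrugLibrary-class
#' @export
setMethod("drugIds", "DrugLibrary", function(x) unique(x@effects$drug_id))

#' @rdname DrugLibrary-class
#' @export
setMethod("drugEffects", "DrugLibrary", function(x) x@effects)

setMethod("show", "DrugLibrary", function(object) {
    cat("DrugLibrary:", length(drugIds(object)), "drug(s),",
        nrow(object@effects), "target effect(s)\n")
})

#' Read a drug library TSV
#'
#' Tab-separated with columns \code{drug_id}, \code{gene} and either
#' \code{fold_change} or \code{direction} (\code{inhibit}/\code{activate},
#' defaulting to fold-changes 0.5 / 2).
#'
#' @param path path to the TSV file.
#' @return a [DrugLibrary-class].
#' @export
readDrugLibrary <- function(path) {
    if (!file.exists(path)) stop("drug library not found: ", path)
    DrugLibrary(utils::read.delim(path, stringsAsFactors = FALSE))
}

## effects of one drug as a named fold-change vector
.drugFolds <- function(drugs, id) {
    e <- drugs@effects[drugs@effects$drug_id == id, ]
    if (nrow(e) == 0L) stop("unknown drug id: ", id)
    stats::setNames(e$fold_change, e$gene)
}

#' Apply a drug's effects to the old samples of a study
#'
#' Each target gene's expression is multiplied by the drug's fold-change in
#' every old sample; young samples are untouched, so the young reference —
#' the therapeutic goal — is unchanged. Targets absent from the matrix are
#' skipped, with a count reported as the \code{"skippedTargets"} attribute.
#' The input study is not modified.
#'
#' @param study an [ExpressionStudy-class].
#' @param drug either a named numeric vector of fold-changes
#'   (names = genes), or a [DrugLibrary-class] together with \code{drugId}.
#' @param drugId drug id to pull from \code{drug} when it is a library.
#' @return a new [ExpressionStudy-class].
#' @examples
#' m <- matrix(c(2, 2, 4), nrow = 1, dimnames = list("G1", c("y1", "y2", "o1")))
#' st <- ExpressionStudy(m, c("young", "young", "old"))
#' exprValues(applyDrug(st, c(G1 = 0.5)))["G1", "o1"]  # 2
#' @export
applyDrug <- function(study, drug, drugId = NULL) {
    stopifnot(is(study, "ExpressionStudy"))
    if (is(drug, "DrugLibrary")) {
        stopifnot(!is.null(drugId))
        drug <- .drugFolds(drug, drugId)
    }
    stopifnot(is.numeric(drug), !is.null(names(drug)), all(drug > 0))
    names(drug) <- toupper(names(drug))
    v <- exprValues(study)
    hit <- intersect(names(drug), rownames(v))
    olds <- oldSamples(study)
    v[hit, olds] <- v[hit, olds, drop = FALSE] * drug[hit]
    out <- ExpressionStudy(v, cohort(study))
    attr(out, "skippedTargets") <- length(drug) - length(hit)
    out
}

#' Combine two drugs into a pair profile
#'
#' Gene-wise product of fold-changes: a shared target gets both effects
#' multiplied, disjoint targets are concatenated.
#'
#' @param foldsA,foldsB named fold-change vectors.
#' @return named fold-change vector of the combination.
#' @export
combineDrugs <- function(foldsA, foldsB) {
    genes <- union(names(foldsA), names(foldsB))
    fa <- stats::setNames(rep(1, length(genes)), genes)
    fb <- fa
    fa[names(foldsA)] <- foldsA
    fb[names(foldsB)] <- foldsB
    fa * fb
}

#' Screen a drug library for disturbance reversal
#'
#' Every drug (and, with \code{pairs = TRUE}, every unordered pair, combined
#' by gene-wise fold-change product) is applied in silico to the old samples
#' and the study is rescored with [scoreStudy()]. Drugs are ranked by the
#' treated disturbance of the mean-of-old PAS profile, ascending — the best
#' drug drives the pathway-cloud activation pattern of the old cohort
#' closest to the young state (all PAS toward 0). Ties are broken by drug id.
#'
#' @param study an [ExpressionStudy-class].
#' @param cloud a [PathwayCloud-class].
#' @param drugs a [DrugLibrary-class].
#' @param pairs also screen all unordered drug pairs (default FALSE).
#' @param ... scoring options passed to [scoreStudy()] (\code{logBase},
#'   \code{norm}, \code{floor}, \code{sdZero}).
#' @return \code{data.frame} with columns \code{rank}, \code{drug_id},
#'   \code{baseline_D}, \code{treated_D}, \code{delta}
#'   (= baseline_D - treated_D), sorted by rank.
#' @examples
#' set.seed(7)
#' sim <- simulateStudy(simulationConfig(seed = 7))
#' lib <- simulateDrugLibrary(sim$truth, nDistractors = 3)
#' screenDrugs(sim$study, sim$cloud, lib$library)[1:3, ]
#' @export
screenDrugs <- function(study, cloud, drugs, pairs = FALSE, ...) {
    stopifnot(is(study, "ExpressionStudy"), is(drugs, "DrugLibrary"))
    if (is(cloud, "PathwayCloud") && length(cloud) == 0L)
        stop("nothing to score: empty pathway cloud")
    ids <- drugIds(drugs)
    if (anyDuplicated(drugs@effects[, c("drug_id", "gene")]))
        stop("duplicate (drug_id, gene) effect")
    baseline <- disturbanceMean(scoreStudy(study, cloud, ...))

    folds <- lapply(ids, .drugFolds, drugs = drugs)
    names(folds) <- ids
    cand <- folds
    if (pairs && length(ids) >= 2L) {
        pr <- utils::combn(sort(ids), 2, simplify = FALSE)
        for (p in pr)
            cand[[paste(p, collapse = "+")]] <-
                combineDrugs(folds[[p[1]]], folds[[p[2]]])
    }

    treated <- vapply(cand, function(f)
        disturbanceMean(scoreStudy(applyDrug(study, f), cloud, ...)),
        numeric(1))
    out <- data.frame(drug_id = names(cand),
                      baseline_D = baseline,
                      treated_D = unname(treated),
                      stringsAsFactors = FALSE)
    out <- out[order(out$treated_D, out$drug_id), ]
    out$delta <- out$baseline_D - out$treated_D
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("rank", "drug_id", "baseline_D", "treated_D", "delta")]
}

#' Write a screening ranking as TSV
#'
#' @param ranking result of [screenDrugs()].
#' @param path destination TSV path.
#' @return invisibly, \code{path}.
#' @export
reportScreen <- function(ranking, path) {
    stopifnot(nrow(ranking) >= 1L,
              all(c("rank", "drug_id", "baseline_D", "treated_D", "delta")
                  %in% colnames(ranking)))
    utils::write.table(
        ranking[, c("rank", "drug_id", "baseline_D", "treated_D", "delta")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
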