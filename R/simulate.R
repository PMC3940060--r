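#' Simulation configuration
#'
#' Defines a fully synthetic young/old expression study with known ground
#' truth. Baseline per-gene levels are log-normal; samples add i.i.d.
#' log-scale Gaussian measurement noise; "old" samples additionally carry
#' planted per-pathway fold-shifts applied coherently with each member's ARR
#' sign (activators up and repressors down for an \code{"activated"}
#' pathway, the reverse for \code{"repressed"}; ARR = 0 members are not
#' shifted). Pathways are non-overlapping so planted signal is attributable.
#'
#' Defaults describe a small but realistic screening scenario: 50 genes in 5
#' pathways of 10, cohorts of 5 young and 5 old samples, log-normal baseline
#' (meanlog 4, sdlog 1, i.e. typical levels ~55 units spanning about two
#' orders of magnitude), measurement noise SD 0.1 on the log scale (~10%
#' CV), and one pathway activated 4-fold in the old cohort.
#'
#' @param nGenes,nYoung,nOld,nPathways,genesPerPathway counts, all >= 1.
#' @param baselineMeanLog,baselineSdLog log-normal baseline parameters
#'   (natural-log scale).
#' @param noiseSd measurement noise SD on the natural-log scale; 0 gives a
#'   noise-free study.
#' @param perturbations \code{data.frame} with columns \code{pathway}
#'   (1-based index), \code{direction} (\code{"activated"} or
#'   \code{"repressed"}) and \code{fold} (> 0).
#' @param seed integer random seed, recorded in the truth record.
#' @return a validated configuration list of class \code{SimulationConfig}.
#' @seealso [simulateStudy()], [simulateDrugLibrary()]
#' @export
simulationConfig <- function(nGenes = 50, nYoung = 5, nOld = 5,
                             nPathways = 5, genesPerPathway = 10,
                             baselineMeanLog = 4, baselineSdLog = 1,
                             noiseSd = 0.1,
                             perturbations = data.frame(
                                 pathway = 1L, direction = "activated",
                                 fold = 4),
                             seed = 1L) {
    stopifnot(nGenes >= 1, nYoung >= 2, nOld >= 1, nPathways >= 1,
              genesPerPathway >= 1, baselineSdLog >= 0, noiseSd >= 0)
    if (genesPerPathway * nPathways > nGenes)
        stop("genesPerPathway x nPathways exceeds nGenes ",
             "(pathways are non-overlapping)")
    if (nrow(perturbations) > 0) {
        stopifnot(all(perturbations$fold > 0),
                  all(perturbations$direction %in% c("activated", "repressed")),
                  all(perturbations$pathway >= 1),
                  all(perturbations$pathway <= nPathways))
    }
    structure(list(nGenes = nGenes, nYoung = nYoung, nOld = nOld,
                   nPathways = nPathways, genesPerPathway = genesPerPathway,
                   baselineMeanLog = baselineMeanLog,
                   baselineSdLog = baselineSdLog, noiseSd = noiseSd,
                   perturbations = perturbations, seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Simulate a young/old study with a planted pathway perturbation
#'
#' Generates an [ExpressionStudy-class], a role-annotated
#' [PathwayCloud-class] and a truth record. Young samples are i.i.d. draws
#' around each gene's log-normal baseline; old samples are the same draws
#' with the planted per-gene fold-shifts applied. The truth record carries
#' everything needed to verify recovery: the seed, the perturbation table,
#' the per-gene expected OYR (the planted shift) and the member genes of
#' each perturbed pathway.
#'
#' All output is a deterministic function of the configuration (including
#' its seed).
#'
#' @param config a [simulationConfig()] object.
#' @return list with elements \code{study}, \code{cloud}, \code{truth}.
#' @examples
#' sim <- simulateStudy(simulationConfig(seed = 42))
#' sim$truth$perturbedPathways
#' @export
simulateStudy <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    genes <- sprintf("SIMG%04d", seq_len(config$nGenes))

    ## non-overlapping pathway memberships with mixed ARR roles
    pathways <- vector("list", config$nPathways)
    arr_pool <- c(1, -1, 0.5, -0.5, 0)
    arr_prob <- c(0.4, 0.3, 0.1, 0.1, 0.1)
    for (i in seq_len(config$nPathways)) {
        idx <- (i - 1) * config$genesPerPathway + seq_len(config$genesPerPathway)
        arr <- sample(arr_pool, config$genesPerPathway, replace = TRUE,
                      prob = arr_prob)
        if (all(arr == 0)) arr[1] <- 1  # keep every pathway scoreable
        pathways[[i]] <- RoleAnnotatedPathway(sprintf("SIMP%02d", i),
                                              genes[idx], arr)
    }
    cloud <- PathwayCloud(pathways,
        provenance = sprintf("simulated cloud (seed %d)", config$seed))

    baseline <- stats::rlnorm(config$nGenes, config$baselineMeanLog,
                              config$baselineSdLog)
    names(baseline) <- genes

    ## planted per-gene multiplicative shift, ARR-coherent
    shift <- stats::setNames(rep(1, config$nGenes), genes)
    perturbed_ids <- character(0)
    if (nrow(config$perturbations) > 0) {
        for (r in seq_len(nrow(config$perturbations))) {
            p <- pathways[[config$perturbations$pathway[r]]]
            perturbed_ids <- c(perturbed_ids, p@pathwayId)
            fold <- config$perturbations$fold[r]
            s <- sign(p@members$arr)
            if (config$perturbations$direction[r] == "repressed") s <- -s
            shift[p@members$gene] <- shift[p@members$gene] * fold^s
        }
    }

    noise <- function(n) {
        if (config$noiseSd == 0) matrix(0, config$nGenes, n)
        else matrix(stats::rnorm(config$nGenes * n, 0, config$noiseSd),
                    config$nGenes, n)
    }
    young <- baseline * exp(noise(config$nYoung))
    old <- (baseline * shift) * exp(noise(config$nOld))
    m <- cbind(young, old)
    colnames(m) <- c(sprintf("young_%02d", seq_len(config$nYoung)),
                     sprintf("old_%02d", seq_len(config$nOld)))
    rownames(m) <- genes
    study <- ExpressionStudy(m, c(rep("young", config$nYoung),
                                  rep("old", config$nOld)))

    truth <- list(seed = config$seed, config = config,
                  perturbations = config$perturbations,
                  perturbedPathways = unique(perturbed_ids),
                  geneShifts = shift,
                  perturbedGenes = names(shift)[shift != 1],
                  perturbedMembers = unique(unlist(lapply(
                      unique(perturbed_ids),
                      function(id) cloud[[id]]@members$gene))))
    list(study = study, cloud = cloud, truth = truth)
}

#' Simulate a drug library with a known best drug
#'
#' Builds a [DrugLibrary-class] around a [simulateStudy()] truth record:
#' \describe{
#'   \item{antidote}{fold-changes exactly reciprocal to every planted
#'     per-gene shift — on a noise-free study it restores old values to the
#'     young means gene-wise.}
#'   \item{partial_antidote}{the reciprocal effects on a random half of the
#'     perturbed genes.}
#'   \item{distractor_NN}{drugs hitting random target genes with fold-change
#'     0.5 or 2.}
#'   \item{null}{a drug with fold-change 1 (no effect).}
#' }
#'
#' @param truth truth record from [simulateStudy()].
#' @param nDistractors number of random-target distractor drugs (default 10).
#' @param targetsPerDrug targets per distractor (default 5).
#' @param includeAntidote,includePartial include the exact/partial antidote.
#' @param seed RNG seed for distractor draws; defaults to the study seed + 1.
#' @return list with \code{library} (a [DrugLibrary-class]) and
#'   \code{labels} (\code{data.frame} drug_id, type).
#' @export
simulateDrugLibrary <- function(truth, nDistractors = 10, targetsPerDrug = 5,
                                includeAntidote = TRUE, includePartial = TRUE,
                                seed = NULL) {
    if (is.null(seed)) seed <- truth$seed + 1L
    set.seed(seed)
    genes <- names(truth$geneShifts)
    rows <- list()
    labels <- list()

    if (includeAntidote) {
        pg <- truth$perturbedGenes
        if (length(pg) == 0L) pg <- genes[1]  # degenerate null study
        rows[[length(rows) + 1L]] <- data.frame(
            drug_id = "antidote", gene = pg,
            fold_change = 1 / truth$geneShifts[pg])
        labels[[length(labels) + 1L]] <- c("antidote", "antidote")
    }
    if (includePartial && length(truth$perturbedGenes) >= 2L) {
        pg <- sort(sample(truth$perturbedGenes,
                          ceiling(length(truth$perturbedGenes) / 2)))
        rows[[length(rows) + 1L]] <- data.frame(
            drug_id = "partial_antidote", gene = pg,
            fold_change = 1 / truth$geneShifts[pg])
        labels[[length(labels) + 1L]] <- c("partial_antidote", "partial")
    }
    for (i in seq_len(nDistractors)) {
        id <- sprintf("distractor_%02d", i)
        tg <- sort(sample(genes, min(targetsPerDrug, length(genes))))
        rows[[length(rows) + 1L]] <- data.frame(
            drug_id = id, gene = tg,
            fold_change = sample(c(0.5, 2), length(tg), replace = TRUE))
        labels[[length(labels) + 1L]] <- c(id, "distractor")
    }
    rows[[length(rows) + 1L]] <- data.frame(
        drug_id = "null", gene = genes[1], fold_change = 1)
    labels[[length(labels) + 1L]] <- c("null", "null")

    eff <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    lab <- do.call(rbind, labels)
    list(library = DrugLibrary(eff),
         labels = data.frame(drug_id = lab[, 1], type = lab[, 2],
                             stringsAsFactors = FALSE))
}

#' Write a simulated dataset as plain-text files
#'
#' Writes \code{expr.tsv}, \code{meta.tsv}, \code{cloud.tsv},
#' \code{drugs.tsv} and \code{truth.tsv} (per-gene planted shifts) into a
#' directory, in the formats the readers of this package consume.
#'
#' @param sim result of [simulateStudy()].
#' @param library a [DrugLibrary-class] (optional).
#' @param dir output directory, created if needed.
#' @return invisibly, \code{dir}.
#' @export
writeSimulation <- function(sim, library = NULL, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    v <- exprValues(sim$study)
    utils::write.table(
        data.frame(gene = rownames(v), v, check.names = FALSE),
        file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(
        data.frame(sample_id = colnames(sim$study),
                   cohort = cohort(sim$study)),
        file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writePathwayFile(sim$cloud, file.path(dir, "cloud.tsv"))
    if (!is.null(library))
        utils::write.table(drugEffects(library), file.path(dir, "drugs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(gene = names(sim$truth$geneShifts),
                   planted_shift = sim$truth$geneShifts,
                   seed = sim$truth$seed),
        file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}
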