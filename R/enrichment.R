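#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k), X ~ Hypergeometric(N, K, n): the chance
#' of drawing at least \code{overlap} pathway genes when \code{listSize}
#' genes are drawn without replacement from a universe of \code{universeSize}
#' genes of which \code{pathwaySize} belong to the pathway. The observed
#' overlap is included in the tail.
#'
#' @param universeSize N, genes in the universe.
#' @param pathwaySize K, genes in the pathway (background count).
#' @param listSize n, genes in the input list.
#' @param overlap k, genes shared between list and pathway.
#' @return p-value in (0, 1].
#' @examples
#' hypergeomPValue(10, 5, 4, 4)  # 5/210
#' @export
hypergeomPValue <- function(universeSize, pathwaySize, listSize, overlap) {
    N <- universeSize; K <- pathwaySize; n <- listSize; k <- overlap
    if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
        stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort, multiply by m/rank, take the running
#' minimum from the largest rank down, cap at 1, restore input order.
#'
#' @param pValues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in input order; empty in, empty out.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhFDR <- function(pValues) {
    if (length(pValues) == 0L) return(numeric(0))
    stopifnot(all(pValues > 0), all(pValues <= 1))
    stats::p.adjust(pValues, method = "BH")
}

## round half away from zero, 1 decimal — the convention of printed
## enrichment tables (16.666 -> 16.7)
.roundPercent <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Overlap percentage of a pathway
#'
#' \code{100 * overlap / background}, rounded half away from zero to one
#' decimal. Exposed so the value is recomputable exactly from the two counts.
#'
#' @param overlap genes shared with the input list.
#' @param background genes in the pathway.
#' @return percentage with one decimal.
#' @examples
#' overlapPercent(5, 30)  # 16.7
#' @export
overlapPercent <- function(overlap, background) {
    stopifnot(background > 0, overlap >= 0, overlap <= background)
    .roundPercent(100 * overlap / background)
}

#' Over-representation analysis of a gene list against a pathway cloud
#'
#' For each pathway, the overlap with the input list is counted; pathways
#' with overlap below \code{minOverlap} are excluded before testing; the
#' hypergeometric upper-tail p-value is computed against the stated gene
#' universe; BH-FDR is taken over all tested pathways; rows are then
#' filtered to \code{p < pCutoff} and sorted by descending overlap
#' percentage, ascending p, ascending pathway id.
#'
#' The universe size is a required explicit argument because the p-values
#' depend entirely on it; there is no defensible hidden default.
#'
#' @param geneList character vector of gene symbols (case-insensitive).
#' @param cloud a [PathwayCloud-class].
#' @param universeSize N, total genes in the annotation universe; must be
#'   at least every pathway size and the list size.
#' @param minOverlap minimum overlap required for a pathway to be tested
#'   (default 2).
#' @param pCutoff raw-p threshold on reported rows (default 0.01); set to 1
#'   (with \code{minOverlap = 0}) to report every pathway.
#' @return \code{data.frame} with columns \code{pathway_id},
#'   \code{pathway_name}, \code{background_count}, \code{overlap_count},
#'   \code{overlap_percent}, \code{p_value}, \code{fdr}.
#' @examples
#' cl <- PathwayCloud(list(
#'     RoleAnnotatedPathway("P1", paste0("G", 1:10), 1),
#'     RoleAnnotatedPathway("P2", paste0("H", 1:10), 1)))
#' runORA(paste0("G", 1:5), cl, universeSize = 100, pCutoff = 1)
#' @export
runORA <- function(geneList, cloud, universeSize, minOverlap = 2,
                   pCutoff = 0.01) {
    stopifnot(is(cloud, "PathwayCloud"))
    geneList <- unique(toupper(geneList))
    if (length(geneList) == 0L)
        stop("empty gene list")
    sizes <- vapply(cloud@pathways, function(p) nrow(p@members), integer(1))
    if (length(sizes) && universeSize < max(sizes))
        stop("universeSize smaller than the largest pathway")
    if (universeSize < length(geneList))
        stop("universeSize smaller than the gene list")

    rows <- lapply(cloud@pathways, function(p) {
        k <- sum(p@members$gene %in% geneList)
        data.frame(pathway_id = p@pathwayId, pathway_name = p@pathwayName,
                   background_count = nrow(p@members), overlap_count = k,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    tab <- tab[tab$overlap_count >= minOverlap, , drop = FALSE]
    if (nrow(tab) == 0L)
        return(.emptyORA())

    tab$overlap_percent <- mapply(overlapPercent,
                                  tab$overlap_count, tab$background_count)
    tab$p_value <- mapply(hypergeomPValue, universeSize,
                          tab$background_count, length(geneList),
                          tab$overlap_count)
    tab$fdr <- bhFDR(tab$p_value)
    ## strict threshold; a cutoff of 1 disables the filter so that k = 0
    ## rows (p exactly 1) can still be reported
    if (pCutoff < 1)
        tab <- tab[tab$p_value < pCutoff, , drop = FALSE]
    ord <- order(-tab$overlap_percent, tab$p_value, tab$pathway_id)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

.emptyORA <- function() {
    data.frame(pathway_id = character(0), pathway_name = character(0),
               background_count = integer(0), overlap_count = integer(0),
               overlap_percent = numeric(0), p_value = numeric(0),
               fdr = numeric(0), stringsAsFactors = FALSE)
}

#' Bundled aging-pathway enrichment table
#'
#' A published KEGG over-representation summary for a list of
#' longevity-candidate genes (genes whose inactivation extends lifespan in
#' model organisms, mapped to human orthologs): 44 pathways with their
#' background gene counts, overlap counts, printed overlap percentages,
#' p-values and FDR values. Shipped as a plain-text fixture; the p-value and
#' FDR columns depend on the source database's unprinted gene universe and
#' tested-pathway count and are therefore reference-only, while the counts
#' and percentages are recomputable.
#'
#' Note that a few printed percentage cells are inconsistent with their own
#' printed counts (e.g. Ribosome: 21/136 = 15.4 but printed 15.7),
#' suggesting an undisclosed effective background in the source; this
#' package recomputes percentages from the counts.
#'
#' @return \code{data.frame} with columns \code{pathway_name},
#'   \code{background_count}, \code{overlap_count}, \code{percent_printed},
#'   \code{p_value_printed}, \code{fdr_printed}.
#' @seealso [agingEnrichmentCloud()]
#' @export
agingEnrichmentTable <- function() {
    path <- system.file("extdata", "aging_pathway_enrichment.tsv",
                        package = "pascloud", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Synthetic cloud and gene list realizing the bundled enrichment counts
#'
#' Builds a fully synthetic, non-overlapping pathway cloud in which every
#' pathway of [agingEnrichmentTable()] has exactly its printed background
#' count of (generated) member genes, together with a gene list that
#' overlaps each pathway by exactly its printed overlap count. Member gene
#' symbols are synthetic placeholders (the real memberships are not
#' printed); the construction exists so the overlap/percentage arithmetic of
#' the table can be re-run through [runORA()].
#'
#' @param table enrichment table, by default [agingEnrichmentTable()].
#' @return list with \code{cloud} (a [PathwayCloud-class]), \code{geneList}
#'   (character) and \code{universeSize} (total synthetic genes).
#' @export
agingEnrichmentCloud <- function(table = agingEnrichmentTable()) {
    pathways <- vector("list", nrow(table))
    gene_list <- character(0)
    counter <- 0L
    for (i in seq_len(nrow(table))) {
        K <- table$background_count[i]
        k <- table$overlap_count[i]
        genes <- sprintf("SYNGENE%05d", counter + seq_len(K))
        counter <- counter + K
        id <- sprintf("KEGGSYN%02d", i)
        pathways[[i]] <- RoleAnnotatedPathway(id, genes, 1,
                                              pathwayName = table$pathway_name[i])
        gene_list <- c(gene_list, genes[seq_len(k)])
    }
    list(cloud = PathwayCloud(pathways,
             provenance = "synthetic realization of the bundled enrichment counts"),
         geneList = gene_list, universeSize = counter)
}
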