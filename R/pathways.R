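#' Construct a role-annotated pathway
#'
#' Gene symbols are treated case-insensitively and normalized to uppercase
#' (HGNC convention). ARR weights must belong to the 5-value domain
#' \{-1, -0.5, 0, 0.5, 1\}.
#'
#' @param pathwayId single identifier string.
#' @param genes character vector of member gene symbols.
#' @param arr numeric vector of ARR weights, recycled if length 1.
#' @param pathwayName human-readable name; defaults to \code{pathwayId}.
#' @return a [RoleAnnotatedPathway-class] object.
#' @examples
#' RoleAnnotatedPathway("P1", c("mtor", "TSC2"), c(1, -1),
#'                      "mTOR signaling (toy)")
#' @export
RoleAnnotatedPathway <- function(pathwayId, genes, arr, pathwayName = pathwayId) {
    if (length(arr) == 1L) arr <- rep(arr, length(genes))
    members <- data.frame(gene = toupper(as.character(genes)),
                          arr = as.numeric(arr),
                          stringsAsFactors = FALSE)
    new("RoleAnnotatedPathway", pathwayId = as.character(pathwayId),
        pathwayName = as.character(pathwayName), members = members)
}

#' Construct a pathway cloud
#'
#' @param pathways list of [RoleAnnotatedPathway-class] objects.
#' @param provenance free-text description of the cloud's origin.
#' @return a [PathwayCloud-class] object.
#' @examples
#' p1 <- RoleAnnotatedPathway("P1", c("GENEA", "GENEB"), c(1, -1))
#' PathwayCloud(list(p1), provenance = "toy example")
#' @export
PathwayCloud <- function(pathways = list(), provenance = "") {
    names(pathways) <- vapply(pathways, function(p) p@pathwayId, character(1))
    new("PathwayCloud", pathways = pathways, provenance = provenance)
}

#' @rdname RoleAnnotatedPathway-class
#' @export
setMethod("members", "RoleAnnotatedPathway", function(x) x@members)

#' @rdname PathwayCloud-class
#' @export
setMethod("pathwayIds", "PathwayCloud", function(x)
    vapply(x@pathways, function(p) p@pathwayId, character(1), USE.NAMES = FALSE))

#' @rdname PathwayCloud-class
#' @export
setMethod("pathwayNames", "PathwayCloud", function(x)
    vapply(x@pathways, function(p) p@pathwayName, character(1), USE.NAMES = FALSE))

#' @rdname PathwayCloud-class
#' @export
setMethod("provenance", "PathwayCloud", function(x) x@provenance)

#' @rdname PathwayCloud-class
#' @export
setMethod("length", "PathwayCloud", function(x) length(x@pathways))

#' @rdname PathwayCloud-class
#' @param i pathway id or index.
#' @export
setMethod("[[", "PathwayCloud", function(x, i) x@pathways[[i]])

setMethod("show", "RoleAnnotatedPathway", function(object) {
    cat("RoleAnnotatedPathway:", object@pathwayId,
        if (!identical(object@pathwayName, object@pathwayId))
            paste0("(", object@pathwayName, ")") else "", "\n")
    m <- object@members
    cat("  ", nrow(m), " member genes; ARR: ",
        sum(m$arr > 0), " activator(s), ", sum(m$arr < 0), " repressor(s), ",
        sum(m$arr == 0), " ambivalent\n", sep = "")
})

setMethod("show", "PathwayCloud", function(object) {
    cat("PathwayCloud with", length(object), "pathway(s)\n")
    if (nzchar(object@provenance))
        cat("  provenance:", object@provenance, "\n")
    ids <- pathwayIds(object)
    if (length(ids))
        cat("  ids:", paste(utils::head(ids, 5), collapse = ", "),
            if (length(ids) > 5) "..." else "", "\n")
})

## --- file I/O -------------------------------------------------------------

#' Read a role-annotated pathway file
#'
#' The native dialect is a 3-column tab-separated file with columns
#' \code{pathway_id}, \code{gene}, \code{arr}. Lines starting with \code{#}
#' are comments; an optional \code{# name: <pathway_id>\\t<display name>}
#' comment attaches a human-readable name to a pathway. Pathway order is the
#' order of first appearance; member order is row order.
#'
#' @param path path to the TSV file.
#' @return a [PathwayCloud-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("P1\tGENEA\t1", "P1\tGENEB\t-1"), tf)
#' readPathwayFile(tf)
#' @seealso [writePathwayFile()], [importGMT()]
#' @export
readPathwayFile <- function(path) {
    if (!file.exists(path))
        stop("pathway file not found: ", path)
    lines <- readLines(path)
    if (length(lines) == 0L || all(!nzchar(trimws(lines))))
        stop("empty pathway file: ", path)

    names_map <- character(0)
    name_lines <- grep("^#\\s*name:", lines)
    for (i in name_lines) {
        body <- sub("^#\\s*name:\\s*", "", lines[i])
        parts <- strsplit(body, "\t", fixed = TRUE)[[1]]
        if (length(parts) >= 2)
            names_map[parts[1]] <- paste(parts[-1], collapse = "\t")
    }

    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    rows <- which(keep)
    if (length(rows) == 0L)
        stop("pathway file has no data rows: ", path)

    fields <- strsplit(lines[rows], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 3L))
        stop("line ", rows[which(nf != 3L)[1]],
             ": expected 3 tab-separated fields (pathway_id, gene, arr)")
    df <- data.frame(
        pathway_id = vapply(fields, `[[`, character(1), 1L),
        gene = toupper(vapply(fields, `[[`, character(1), 2L)),
        arr_raw = vapply(fields, `[[`, character(1), 3L),
        line = rows, stringsAsFactors = FALSE)

    arr <- suppressWarnings(as.numeric(df$arr_raw))
    bad <- is.na(arr) | !(arr %in% .ARR_DOMAIN)
    if (any(bad))
        stop("line ", df$line[which(bad)[1]], ": invalid ARR value '",
             df$arr_raw[which(bad)[1]],
             "' (must be one of -1, -0.5, 0, 0.5, 1)")
    df$arr <- arr

    dup <- duplicated(df[, c("pathway_id", "gene")])
    if (any(dup))
        stop("line ", df$line[which(dup)[1]], ": duplicate gene '",
             df$gene[which(dup)[1]], "' in pathway '",
             df$pathway_id[which(dup)[1]], "'")

    ids <- unique(df$pathway_id)
    pathways <- lapply(ids, function(id) {
        sub <- df[df$pathway_id == id, ]
        nm <- if (id %in% names(names_map)) names_map[[id]] else id
        RoleAnnotatedPathway(id, sub$gene, sub$arr, pathwayName = nm)
    })
    PathwayCloud(pathways, provenance = paste0("read from ", basename(path)))
}

#' Write a pathway cloud to the native TSV dialect
#'
#' Round-trips with [readPathwayFile()]: reading the written file reproduces
#' the cloud's ids, names, member order and ARR values exactly. Refuses to
#' write an empty cloud.
#'
#' @param cloud a [PathwayCloud-class].
#' @param path destination file path.
#' @return invisibly, \code{path}.
#' @export
writePathwayFile <- function(cloud, path) {
    stopifnot(is(cloud, "PathwayCloud"))
    validObject(cloud)
    if (length(cloud) == 0L)
        stop("refusing to write an empty pathway cloud")
    con <- file(path, "w")
    on.exit(close(con))
    for (p in cloud@pathways) {
        if (!identical(p@pathwayName, p@pathwayId))
            writeLines(sprintf("# name: %s\t%s", p@pathwayId, p@pathwayName), con)
        m <- p@members
        writeLines(sprintf("%s\t%s\t%s", p@pathwayId, m$gene,
                           format(m$arr, trim = TRUE)), con)
    }
    invisible(path)
}

#' Import a GMT gene-set file as a pathway cloud
#'
#' GMT carries no per-gene role information, so every member is assigned
#' ARR = 1 (pure activator). This import is therefore lossy with respect to
#' repressor semantics and is intended for enrichment use, where only
#' membership matters.
#'
#' @param path path to a GMT file (tab-separated: set name, description,
#'   genes...).
#' @return a [PathwayCloud-class] with all ARR = 1.
#' @export
importGMT <- function(path) {
    if (!file.exists(path))
        stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("empty GMT file: ", path)
    pathways <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("line ", i, ": GMT rows need a name, a description and >= 1 gene")
        genes <- unique(toupper(f[-(1:2)]))
        nm <- if (nzchar(f[2]) && !identical(f[2], f[1])) f[2] else f[1]
        RoleAnnotatedPathway(f[1], genes, 1, pathwayName = nm)
    })
    PathwayCloud(pathways,
                 provenance = paste0("GMT import (all ARR = 1) from ",
                                     basename(path)))
}
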