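## shared in-code fixtures; everything is built at test time

## 3 genes x (3 young + 2 old); GENEA is 4-fold up and GENEB 4-fold down in
## old samples, GENEC is unchanged
makeToyStudy <- function() {
    m <- rbind(
        GENEA = c(1.9, 2.0, 2.1, 8.0, 8.0),
        GENEB = c(3.9, 4.0, 4.1, 1.0, 1.0),
        GENEC = c(5.0, 5.1, 4.9, 5.0, 5.0))
    colnames(m) <- c("y1", "y2", "y3", "o1", "o2")
    ExpressionStudy(m, c("young", "young", "young", "old", "old"))
}

## P1 holds the perturbed activator/repressor pair, P2 the quiet gene
makeToyCloud <- function() {
    PathwayCloud(list(
        RoleAnnotatedPathway("P1", c("GENEA", "GENEB"), c(1, -1),
                             "perturbed toy pathway"),
        RoleAnnotatedPathway("P2", "GENEC", 1, "quiet toy pathway")),
        provenance = "toy fixture")
}

## a study whose old samples equal the young per-gene means exactly
makeNullStudy <- function(nGenes = 4) {
    genes <- paste0("G", seq_len(nGenes))
    young <- cbind(seq_len(nGenes), seq_len(nGenes) + 1, seq_len(nGenes) + 2)
    old <- rowMeans(young)
    m <- cbind(young, old, old)
    dimnames(m) <- list(genes, c("y1", "y2", "y3", "o1", "o2"))
    ExpressionStudy(m, c("young", "young", "young", "old", "old"))
}

randomCloud <- function(nPathways = 3, nGenes = 4, withNames = TRUE) {
    arr_pool <- c(-1, -0.5, 0, 0.5, 1)
    PathwayCloud(lapply(seq_len(nPathways), function(i) {
        genes <- sprintf("RND%02dG%02d", i, seq_len(nGenes))
        RoleAnnotatedPathway(
            sprintf("RP%02d", i), genes,
            sample(arr_pool, nGenes, replace = TRUE),
            pathwayName = if (withNames) sprintf("random pathway %d", i)
                          else sprintf("RP%02d", i))
    }), provenance = "random test cloud")
}

## independent enumeration oracle for the hypergeometric upper tail:
## explicit sum of counting ratios, no distribution functions involved
enumHyperTail <- function(N, K, n, k) {
    i <- k:min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## independent BH step-up oracle written out longhand
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}
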