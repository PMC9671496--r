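# Correlation-threshold clustering of gene phenotypic profiles across
# challenge/stress conditions: genes whose per-condition log2 fold-change
# profiles correlate above a threshold (default r > 0.9) are grouped, the
# minimal reading of profile-similarity grouping for heatmap display.

#' Validate a phenotype matrix
#'
#' A phenotype matrix holds per-gene (rows), per-condition (columns)
#' scores — typically log2 fold changes from a panel of challenges.
#'
#' @param m Numeric matrix with unique row (gene) and column (condition)
#'   names; `NA` marks missing scores.
#' @return `m`, invisibly, after validation.
#' @export
phenotype_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("phenotype matrix needs gene row names and condition column names")
  if (anyDuplicated(rownames(m))) stop("duplicate gene (row) labels")
  if (anyDuplicated(colnames(m))) stop("duplicate condition (column) labels")
  if (!is.numeric(m)) stop("phenotype matrix must be numeric")
  if (any(is.infinite(m))) stop("non-finite scores: use NA for missing")
  invisible(m)
}

#' Pearson correlation between two gene profiles
#'
#' Correlation over the conditions where both genes have a score
#' (pairwise deletion of missing values). Undefined similarities —
#' fewer than 3 shared conditions, or zero variance in either profile —
#' are reported as `NA`.
#'
#' @param m A [phenotype_matrix()].
#' @param gene_a,gene_b Row labels.
#' @return Pearson `r`, or `NA_real_` when undefined.
#' @export
profile_correlation <- function(m, gene_a, gene_b) {
  m <- phenotype_matrix(m)
  if (!all(c(gene_a, gene_b) %in% rownames(m)))
    stop("unknown gene label(s)")
  a <- m[gene_a, ]
  b <- m[gene_b, ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Cluster genes by correlation threshold
#'
#' Builds a graph with an edge between two genes when their profile
#' correlation exceeds `r_threshold` and takes connected components as
#' clusters (undefined correlations contribute no edge). A
#' complete-linkage alternative cuts an average of the same distance at
#' the threshold. Cluster labels are deterministic: each cluster is named
#' by its lexicographically smallest member gene. An average-linkage
#' dendrogram ordering is emitted for heatmap display.
#'
#' @param m A [phenotype_matrix()] with >= 2 genes.
#' @param r_threshold Correlation threshold (default 0.9; edges require
#'   `r > r_threshold`, strictly).
#' @param method `"components"` (default) or `"complete"` (complete
#'   linkage cut at `1 - r_threshold`).
#' @return List with `clusters` (`data.frame(gene_id, cluster_id)` in row
#'   order of `m`), `order` (gene ordering from average-linkage
#'   clustering of `1 - r`), and `correlations` (the pairwise `r` matrix).
#' @export
correlation_cluster <- function(m, r_threshold = 0.9,
                                method = c("components", "complete")) {
  method <- match.arg(method)
  m <- phenotype_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 genes to cluster")
  suppressWarnings(
    r <- cor(t(m), use = "pairwise.complete.obs"))
  # pairwise-complete pairs with < 3 shared conditions are unreliable:
  shared <- (!is.na(m)) %*% t(!is.na(m))
  r[shared < 3L] <- NA
  diag(r) <- 1
  if (method == "components") {
    adj <- !is.na(r) & r > r_threshold
    diag(adj) <- FALSE
    gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    membership <- igraph::components(gph)$membership
  } else {
    d <- 1 - r
    d[is.na(d)] <- 2  # maximal Pearson distance for undefined pairs
    membership <- cutree(hclust(as.dist(d), method = "complete"),
                         h = 1 - r_threshold)
  }
  ids <- rownames(m)
  cluster_id <- vapply(seq_along(ids), function(i)
    min(ids[membership == membership[i]]), "")
  d_avg <- 1 - r
  d_avg[is.na(d_avg)] <- 2
  ord <- ids[hclust(as.dist(d_avg), method = "average")$order]
  list(clusters = data.frame(gene_id = ids, cluster_id = cluster_id,
                             stringsAsFactors = FALSE),
       order = ord, correlations = r)
}

#' Read / write a phenotype matrix TSV
#'
#' Matrix TSV: header row of condition labels, first column of gene ids.
#'
#' @param path TSV path.
#' @return `read_phenotype_matrix`: a validated matrix.
#' @export
read_phenotype_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  phenotype_matrix(m)
}

#' @rdname read_phenotype_matrix
#' @param m Phenotype matrix.
#' @export
write_phenotype_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
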