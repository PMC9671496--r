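# Core inference for the phage-resistance screen: paired total-read
# normalization, per-gene log2 fold change, Mann-Whitney U testing of
# per-site counts, and two-replicate hit calling with the unique-insertion
# filter and small-gene review flag.

#' Normalize challenged counts to the paired control's sequencing depth
#'
#' Every challenged site count is multiplied by
#' `scale = control total / challenged total`, so that after scaling the
#' challenged library total equals the paired control total exactly.
#' Control counts are untouched. Normalized counts are real-valued.
#'
#' @param challenged,control [insertion_count_table()]s paired per the
#'   sample sheet.
#' @return The challenged table with scaled counts; the scale factor is
#'   attached as attribute `scale`.
#' @export
normalize_counts <- function(challenged, control) {
  stopifnot(inherits(challenged, "insertion_count_table"),
            inherits(control, "insertion_count_table"))
  if (challenged$total_reads == 0)
    stop("challenged sample '", challenged$sample_id,
         "' has zero total reads: normalization scale undefined")
  if (control$total_reads == 0)
    stop("control sample '", control$sample_id, "' has zero total reads")
  scale <- control$total_reads / challenged$total_reads
  out <- challenged
  out$counts$count <- challenged$counts$count * scale
  out$total_reads <- sum(out$counts$count)
  attr(out, "scale") <- scale
  out
}

#' Per-gene log2 fold change with pseudocount
#'
#' `log2((challenged_norm_total + c) / (control_total + c))`; the shared
#' pseudocount `c > 0` keeps the value finite for zero-count genes (common
#' in challenged libraries after strong selection) and makes the transform
#' antisymmetric under swapping the two roles.
#'
#' @param challenged_norm_total Normalized challenged read total (>= 0).
#' @param control_total Control read total (>= 0). Both vectorized.
#' @param pseudocount Shared pseudocount `c` (default 1).
#' @return Numeric log2 fold change(s), always finite.
#' @export
gene_log2_fold_change <- function(challenged_norm_total, control_total,
                                  pseudocount = 1) {
  stopifnot(pseudocount > 0, all(challenged_norm_total >= 0),
            all(control_total >= 0))
  log2((challenged_norm_total + pseudocount) /
         (control_total + pseudocount))
}

#' Mann-Whitney U test on per-site counts within a gene
#'
#' Compares the challenged sample's per-site (normalized) counts against
#' the paired control's over the union of sites observed in either sample
#' (a site absent from one sample contributes 0 for it). Exact two-sided
#' p by complete enumeration of labelings when both group sizes are at
#' most `exact_max` (ties handled exactly: the null distribution of U is
#' enumerated over all \eqn{C(n+m, n)} relabelings of the observed
#' values); otherwise a tie-corrected normal approximation with
#' continuity correction. The reported `U` is for the challenged group.
#'
#' The exact two-sided p is
#' \eqn{P(|U - nm/2| \ge |U_{obs} - nm/2|)} under uniform relabeling,
#' which for tie-free data equals the classical doubled one-tail p.
#'
#' @param challenged,control Numeric per-site count vectors (each length
#'   >= 1).
#' @param exact_max Enumerate exactly when both lengths <= this (default 8).
#' @return List with `U`, `p.value`, `method` (`"exact"` or `"normal"`),
#'   and `degenerate` (`TRUE` when all values are tied, e.g. both groups
#'   all zero, in which case `p = 1` by convention).
#' @export
mann_whitney_gene <- function(challenged, control, exact_max = 8L) {
  n <- length(challenged)
  m <- length(control)
  if (n < 1L || m < 1L) stop("each group needs at least one site value")
  pooled <- c(challenged, control)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, p.value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  if (n <= exact_max && m <= exact_max) {
    labelings <- combn(n + m, n)
    base <- n * (n + 1) / 2
    Us <- colSums(matrix(r[labelings], nrow = n)) - base
    p <- mean(abs(Us - mu) >= abs(U - mu))
    return(list(U = U, p.value = p, method = "exact", degenerate = FALSE))
  }
  N <- n + m
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n * m / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(U = U, p.value = 1, method = "degenerate", degenerate = TRUE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p.value = p, method = "normal", degenerate = FALSE)
}

# per-site vectors over the union of observed sites in a gene
site_union_vectors <- function(prof_ch, prof_co) {
  pos <- sort(unique(c(prof_ch$sites$position, prof_co$sites$position)))
  if (!length(pos)) return(NULL)
  ch <- prof_ch$sites$count[match(pos, prof_ch$sites$position)]
  co <- prof_co$sites$count[match(pos, prof_co$sites$position)]
  ch[is.na(ch)] <- 0
  co[is.na(co)] <- 0
  list(challenged = ch, control = co)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Canonical BH step-up (via `stats::p.adjust`), emitted as supplementary
#' output only: hit calling gates on fold change and unique insertions,
#' never on p or q.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
adjust_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Enrich one challenged/control pair
#'
#' Runs normalization, site-to-gene assignment and the per-gene statistics
#' for a single replicate pair.
#'
#' @param challenged,control [insertion_count_table()]s.
#' @param ann A [genome_annotation()].
#' @param pseudocount Pseudocount for [gene_log2_fold_change()].
#' @param trim_frac Terminal trimming fraction for
#'   [assign_sites_to_genes()] (default 0).
#' @return `data.frame` with one row per annotated gene: raw and
#'   normalized totals, unique insertion counts, `log2fc`, `U`, `p`.
#' @export
enrich_pair <- function(challenged, control, ann, pseudocount = 1,
                        trim_frac = 0) {
  ch_norm <- normalize_counts(challenged, control)
  prof_ch <- assign_sites_to_genes(ch_norm, ann, trim_frac = trim_frac)
  prof_ch_raw <- assign_sites_to_genes(challenged, ann, trim_frac = trim_frac)
  prof_co <- assign_sites_to_genes(control, ann, trim_frac = trim_frac)
  ids <- ann$genes$gene_id
  res <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  res$control_total <- vapply(ids, function(g) prof_co$genes[[g]]$gene_total, 0)
  res$challenged_total <- vapply(ids, function(g)
    prof_ch_raw$genes[[g]]$gene_total, 0)
  res$challenged_norm <- vapply(ids, function(g)
    prof_ch$genes[[g]]$gene_total, 0)
  res$unique_insertions_challenged <- vapply(ids, function(g)
    prof_ch_raw$genes[[g]]$unique_insertions, 0L)
  res$unique_insertions_control <- vapply(ids, function(g)
    prof_co$genes[[g]]$unique_insertions, 0L)
  res$log2fc <- gene_log2_fold_change(res$challenged_norm, res$control_total,
                                      pseudocount)
  mw <- lapply(ids, function(g) {
    v <- site_union_vectors(prof_ch$genes[[g]], prof_co$genes[[g]])
    if (is.null(v))
      return(list(U = NA_real_, p.value = 1, degenerate = TRUE))
    mann_whitney_gene(v$challenged, v$control)
  })
  res$U <- vapply(mw, function(x) as.numeric(x$U), 0)
  res$p <- vapply(mw, function(x) x$p.value, 0)
  res$degenerate <- vapply(mw, function(x) isTRUE(x$degenerate), TRUE)
  attr(res, "scale") <- attr(ch_norm, "scale")
  attr(res, "pseudocount") <- pseudocount
  res
}

#' Per-gene enrichment over a two-replicate experiment
#'
#' Pairs each challenged replicate with its control per the sample sheet,
#' computes per-replicate statistics with [enrich_pair()], and calls hits
#' with [call_hits()]. Every annotated gene appears in the output.
#'
#' @param samples Named list of [insertion_count_table()]s.
#' @param sample_sheet Sample sheet `data.frame` (see
#'   [read_sample_sheet()]).
#' @param ann A [genome_annotation()].
#' @param fc_threshold,strong_threshold,min_unique,require_all_replicates,
#'   small_gene_len Hit-calling knobs; see [call_hits()].
#' @param pseudocount Fold-change pseudocount.
#' @param trim_frac Terminal trimming fraction (default 0).
#' @return `data.frame` of gene enrichment records: per-replicate columns
#'   suffixed `_A`, `_B`, plus `mean_log2fc`, `p_combined`
#'   (max over replicates), `q` (BH of `p_combined`), and the hit flags.
#' @export
enrich_experiment <- function(samples, sample_sheet, ann,
                              fc_threshold = 2, strong_threshold = 5,
                              min_unique = 1, pseudocount = 1,
                              require_all_replicates = TRUE,
                              small_gene_len = 400, trim_frac = 0) {
  ph <- sample_sheet[sample_sheet$condition == "phage", , drop = FALSE]
  ph <- ph[order(ph$replicate), , drop = FALSE]
  if (nrow(ph) < 1L) stop("sample sheet lists no phage-challenged samples")
  if (nrow(ph) != 2L && require_all_replicates)
    stop("expected exactly 2 challenged replicates, found ", nrow(ph),
         " (set require_all_replicates = FALSE to proceed)")
  tags <- LETTERS[seq_len(nrow(ph))]
  per_rep <- list()
  for (i in seq_len(nrow(ph))) {
    cid <- ph$paired_control_id[i]
    if (!cid %in% names(samples))
      stop("paired control '", cid, "' not found for sample '",
           ph$sample_id[i], "'")
    per_rep[[tags[i]]] <- enrich_pair(samples[[ph$sample_id[i]]],
                                      samples[[cid]], ann,
                                      pseudocount = pseudocount,
                                      trim_frac = trim_frac)
  }
  res <- data.frame(gene_id = ann$genes$gene_id,
                    gene_length = ann$genes$length,
                    stringsAsFactors = FALSE)
  for (tag in tags) {
    r <- per_rep[[tag]]
    stopifnot(identical(r$gene_id, res$gene_id))
    for (col in c("control_total", "challenged_total", "challenged_norm",
                  "unique_insertions_challenged", "unique_insertions_control",
                  "log2fc", "U", "p"))
      res[[paste0(col, "_", tag)]] <- r[[col]]
  }
  fc_cols <- paste0("log2fc_", tags)
  res$mean_log2fc <- rowMeans(res[, fc_cols, drop = FALSE])
  res$p_combined <- do.call(pmax, res[paste0("p_", tags)])
  res$q <- adjust_pvalues(res$p_combined)
  res <- call_hits(res, fc_threshold = fc_threshold,
                   strong_threshold = strong_threshold,
                   min_unique = min_unique,
                   require_all_replicates = require_all_replicates,
                   small_gene_len = small_gene_len)
  attr(res, "pseudocount") <- pseudocount
  attr(res, "thresholds") <- c(fc_threshold = fc_threshold,
                               strong_threshold = strong_threshold,
                               min_unique = min_unique,
                               small_gene_len = small_gene_len)
  res
}

#' Call hits from per-gene, per-replicate enrichment records
#'
#' A gene is a *hit* iff in **every** replicate its log2 fold change
#' exceeds `fc_threshold` **and** its challenged unique-insertion count
#' exceeds `min_unique` (strictly: "more than one unique insertion" means
#' `> 1` with the default). A *strong hit* additionally exceeds
#' `strong_threshold` in every replicate (the display tier). Genes shorter
#' than `small_gene_len` that fail **only** the unique-insertion criterion
#' get `small_gene_flag = TRUE` — a review flag, never an automatic
#' promotion. Genes with negative mean log2 fold change are marked
#' `depleted` and are never hits: depletion in a survival selection is not
#' interpreted.
#'
#' @param records `data.frame` with columns `gene_id`, per-replicate
#'   `log2fc_<tag>` and `unique_insertions_challenged_<tag>` (tags `A`,
#'   `B`, ...), and optionally `gene_length`.
#' @param fc_threshold Log2 fold-change threshold for calling (default 2).
#' @param strong_threshold Log2 threshold of the strong/display tier
#'   (default 5).
#' @param min_unique Unique-insertion threshold; the criterion is
#'   `unique insertions > min_unique` (default 1).
#' @param require_all_replicates If `TRUE` (default) both criteria must
#'   hold in every replicate; if `FALSE`, in at least one.
#' @param small_gene_len Genes shorter than this are eligible for the
#'   review flag (default 400 bp).
#' @return `records` with logical columns `hit`, `strong_hit`,
#'   `small_gene_flag`, `depleted` added.
#' @export
call_hits <- function(records, fc_threshold = 2, strong_threshold = 5,
                      min_unique = 1, require_all_replicates = TRUE,
                      small_gene_len = 400) {
  stopifnot(fc_threshold > 0, strong_threshold > 0, min_unique >= 0)
  tags <- sub("^log2fc_", "", grep("^log2fc_[A-Z]$", names(records),
                                   value = TRUE))
  if (!length(tags)) stop("records carry no per-replicate log2fc columns")
  uq_cols <- paste0("unique_insertions_challenged_", tags)
  if (!all(uq_cols %in% names(records)))
    stop("records lack unique-insertion columns for replicates: ",
         paste(tags, collapse = ", "))
  fc <- as.matrix(records[paste0("log2fc_", tags)])
  uq <- as.matrix(records[uq_cols])
  if (require_all_replicates && anyNA(fc))
    stop("missing replicate values; set require_all_replicates = FALSE")
  comb <- if (require_all_replicates) {
    function(m) apply(m, 1L, all)
  } else {
    function(m) apply(m, 1L, any, na.rm = TRUE)
  }
  pass_fc <- comb(fc > fc_threshold)
  pass_uq <- comb(uq > min_unique)
  records$hit <- pass_fc & pass_uq
  records$strong_hit <- records$hit & comb(fc > strong_threshold)
  len <- if (!is.null(records$gene_length)) records$gene_length else Inf
  records$small_gene_flag <- !records$hit & pass_fc & !pass_uq &
    len < small_gene_len
  mean_fc <- rowMeans(fc, na.rm = !require_all_replicates)
  records$depleted <- mean_fc < 0
  records$hit <- records$hit & !records$depleted
  records
}

#' Replicate reproducibility of per-gene log2 fold changes
#'
#' Pearson correlation of the two replicates' per-gene log2 fold changes,
#' over all annotated genes with finite values in both.
#'
#' @param records Output of [enrich_experiment()], or a `data.frame` with
#'   columns `log2fc_A`, `log2fc_B`.
#' @return Pearson `r`.
#' @export
replicate_reproducibility <- function(records) {
  a <- records$log2fc_A
  b <- records$log2fc_B
  if (is.null(a) || is.null(b))
    stop("records lack log2fc_A / log2fc_B columns")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("need at least 3 genes with finite values")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0)
    stop("zero variance in a replicate: correlation undefined")
  cor(a[ok], b[ok])
}
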