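# End-to-end workflow: configuration, the simulate -> enrich -> score
# pipeline, deterministic artifact writing, and truth-table scoring.

#' Build a run configuration
#'
#' Collects every knob of a pipeline run. `mode = "simulate"` generates a
#' synthetic experiment from the selection model and analyses it;
#' `mode = "analyze"` reads counts, GFF3 and sample sheet from the given
#' paths. All defaults are echoed into the run-metadata artifact.
#'
#' @param mode `"simulate"` or `"analyze"`.
#' @param out_dir Output directory (created if absent).
#' @param counts,gff,sample_sheet Input paths (`analyze` mode).
#' @param matrix Optional phenotype-matrix TSV to cluster.
#' @param fc_threshold,strong_threshold,min_unique,pseudocount,small_gene_len
#'   Enrichment thresholds (see [call_hits()]).
#' @param r_threshold Profile-clustering correlation threshold.
#' @param seed Master seed.
#' @param n_genes Genes in the simulated genome (`simulate` mode).
#' @param model A [selection_model()]; its `seed` is overridden by `seed`.
#' @param verbose Log stage progress to stderr.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "analyze"), out_dir,
                       counts = NULL, gff = NULL, sample_sheet = NULL,
                       matrix = NULL,
                       fc_threshold = 2, strong_threshold = 5,
                       min_unique = 1, pseudocount = 1, small_gene_len = 400,
                       r_threshold = 0.9, seed = 1L, n_genes = 2000,
                       model = selection_model(), verbose = TRUE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, counts = counts, gff = gff,
              sample_sheet = sample_sheet, matrix = matrix,
              fc_threshold = fc_threshold,
              strong_threshold = strong_threshold, min_unique = min_unique,
              pseudocount = pseudocount, small_gene_len = small_gene_len,
              r_threshold = r_threshold, seed = as.integer(seed),
              n_genes = n_genes, model = model, verbose = verbose)
  problems <- validate_run_config(cfg)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  cfg$model$seed <- cfg$seed
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.character(cfg$out_dir) && nzchar(cfg$out_dir),
       "out_dir: required")
  need(cfg$fc_threshold > 0, "fc_threshold: must be positive")
  need(cfg$strong_threshold > 0, "strong_threshold: must be positive")
  need(cfg$min_unique >= 0, "min_unique: must be nonnegative")
  need(cfg$pseudocount > 0, "pseudocount: must be positive")
  need(cfg$small_gene_len > 0, "small_gene_len: must be positive")
  need(cfg$r_threshold > -1 && cfg$r_threshold <= 1,
       "r_threshold: must lie in (-1, 1]")
  if (identical(cfg$mode, "analyze")) {
    for (field in c("counts", "gff", "sample_sheet")) {
      v <- cfg[[field]]
      if (is.null(v) || !nzchar(v)) {
        problems <- c(problems, paste0(field, ": required in analyze mode"))
      } else if (!file.exists(v)) {
        problems <- c(problems, paste0(field, ": file not found: ", v))
      }
    }
  } else {
    need(cfg$n_genes >= 1, "n_genes: must be >= 1")
  }
  if (!is.null(cfg$matrix) && !file.exists(cfg$matrix))
    problems <- c(problems, paste0("matrix: file not found: ", cfg$matrix))
  problems
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `model:` section maps to
#' [selection_model()] arguments. `overrides` (typically from CLI flags)
#' take precedence over file values, which take precedence over defaults.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  model_args <- raw$model
  raw$model <- NULL
  raw <- modifyList(raw, overrides[setdiff(names(overrides), "model")])
  if (!is.null(overrides$model))
    model_args <- modifyList(model_args %||% list(), overrides$model)
  args <- raw
  args$model <- do.call(selection_model, model_args %||% list())
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(verbose, ...) {
  if (verbose) message("[tnscreen] ", ...)
}

# fixed-format TSV writer so identical values give identical bytes
write_tsv_artifact <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  for (col in names(df)[num]) df[[col]] <- sprintf("%.10g", df[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulate (or read) a two-replicate phage-challenge experiment, run the
#' enrichment analysis, call hits, and write the artifact set to
#' `out_dir`: `per_gene.tsv` (every annotated gene), `hits.tsv`,
#' `review_small_genes.tsv`, `reproducibility.txt`, `run_metadata.txt`,
#' plus (simulate mode) the generated `genome.gff3`, `genome.fasta`,
#' `counts.tsv`, `sample_sheet.tsv`, `truth.tsv` and `score.tsv`, and
#' (when a matrix is supplied) `clusters.tsv` / `heatmap_order.txt`.
#' Identical configuration and seed give byte-identical artifacts.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `records`, `hits`, `r` (replicate
#'   reproducibility), and `score` (simulate mode).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cfg$mode == "simulate") {
    log_msg(cfg$verbose, "simulating experiment (", cfg$n_genes,
            " genes, seed ", cfg$seed, ")")
    sim <- simulate_experiment(model = cfg$model, n_genes = cfg$n_genes,
                               small_gene_len = cfg$small_gene_len)
    ann <- sim$annotation
    samples <- sim$samples
    sheet <- sim$sample_sheet
    write_annotation(ann, file.path(cfg$out_dir, "genome.gff3"))
    write_genome_fasta(sim$sequence, file.path(cfg$out_dir, "genome.fasta"))
    write_counts_tsv(samples, file.path(cfg$out_dir, "counts.tsv"))
    write_sample_sheet(sheet, file.path(cfg$out_dir, "sample_sheet.tsv"))
    write_tsv_artifact(sim$truth, file.path(cfg$out_dir, "truth.tsv"))
  } else {
    log_msg(cfg$verbose, "reading inputs")
    ann <- read_annotation(cfg$gff)
    sheet <- read_sample_sheet(cfg$sample_sheet)
    samples <- read_counts_tsv(cfg$counts, sample_sheet = sheet,
                               contig_length = ann$contig_length)
  }
  n_ch <- sum(sheet$condition == "phage")
  log_msg(cfg$verbose, "enrichment over ", length(samples), " samples (",
          n_ch, " challenged), ", n_genes(ann), " genes")
  records <- enrich_experiment(samples, sheet, ann,
                               fc_threshold = cfg$fc_threshold,
                               strong_threshold = cfg$strong_threshold,
                               min_unique = cfg$min_unique,
                               pseudocount = cfg$pseudocount,
                               small_gene_len = cfg$small_gene_len)
  hits <- records[records$hit, , drop = FALSE]
  review <- records[records$small_gene_flag, , drop = FALSE]
  log_msg(cfg$verbose, nrow(records), " genes -> ", nrow(hits), " hits, ",
          sum(records$strong_hit), " strong, ", nrow(review),
          " small-gene review flags")
  write_tsv_artifact(records, file.path(cfg$out_dir, "per_gene.tsv"))
  write_tsv_artifact(hits, file.path(cfg$out_dir, "hits.tsv"))
  write_tsv_artifact(review, file.path(cfg$out_dir,
                                       "review_small_genes.tsv"))
  r <- replicate_reproducibility(records)
  writeLines(sprintf("replicate_log2fc_pearson_r\t%.10g", r),
             file.path(cfg$out_dir, "reproducibility.txt"))
  score <- NULL
  if (cfg$mode == "simulate") {
    score <- score_against_truth(hits, sim$truth)
    write_tsv_artifact(as.data.frame(score),
                       file.path(cfg$out_dir, "score.tsv"))
    log_msg(cfg$verbose, sprintf(
      "sensitivity %.3f, false positives %d, precision %.3f",
      score$sensitivity, score$false_positives, score$precision))
  }
  if (!is.null(cfg$matrix)) {
    m <- read_phenotype_matrix(cfg$matrix)
    cl <- correlation_cluster(m, r_threshold = cfg$r_threshold)
    write_tsv_artifact(cl$clusters, file.path(cfg$out_dir, "clusters.tsv"))
    writeLines(cl$order, file.path(cfg$out_dir, "heatmap_order.txt"))
    log_msg(cfg$verbose, nrow(m), " profiles -> ",
            length(unique(cl$clusters$cluster_id)), " clusters")
  }
  meta <- c(
    sprintf("tnscreen %s", as.character(utils::packageVersion("tnscreen"))),
    sprintf("mode\t%s", cfg$mode),
    sprintf("seed\t%d", cfg$seed),
    sprintf("fc_threshold\t%g", cfg$fc_threshold),
    sprintf("strong_threshold\t%g", cfg$strong_threshold),
    sprintf("min_unique\t%g", cfg$min_unique),
    sprintf("pseudocount\t%g", cfg$pseudocount),
    sprintf("small_gene_len\t%g", cfg$small_gene_len),
    sprintf("r_threshold\t%g", cfg$r_threshold),
    sprintf("model_escape_baseline\t%g", cfg$model$escape_baseline),
    sprintf("model_library_size\t%d", cfg$model$library_size),
    sprintf("model_survivor_plate_capacity\t%d",
            cfg$model$survivor_plate_capacity),
    sprintf("model_read_depth\t%d", cfg$model$read_depth),
    sprintf("model_dispersion\t%g", cfg$model$dispersion),
    sprintf("model_resistance_survival\t%g", cfg$model$resistance_survival),
    sprintf("model_costly_fitness\t%g", cfg$model$costly_fitness))
  writeLines(meta, file.path(cfg$out_dir, "run_metadata.txt"))
  invisible(list(records = records, hits = hits, r = r, score = score))
}

#' Score called hits against the planted truth
#'
#' @param hits `data.frame` with a `gene_id` column (the called hits).
#' @param truth Truth table from [simulate_experiment()]:
#'   `data.frame(gene_id, class, planted)`.
#' @return List with `sensitivity` (called planted / total planted over
#'   resistance + costly-resistance genes), `false_positives` (called
#'   non-planted count), and `precision`.
#' @export
score_against_truth <- function(hits, truth) {
  if (!all(c("gene_id", "planted") %in% names(truth)))
    stop("truth table needs gene_id and planted columns")
  called <- unique(hits$gene_id)
  if (length(called) && !any(called %in% truth$gene_id))
    stop("called genes share no ids with the truth table")
  planted <- truth$gene_id[truth$planted]
  tp <- sum(called %in% planted)
  fp <- sum(!called %in% planted)
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       false_positives = as.integer(fp),
       precision = if (length(called)) tp / length(called) else NA_real_)
}
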