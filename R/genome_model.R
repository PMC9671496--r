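#' @importFrom stats cor lm p.adjust pnorm rbinom rgamma rmultinom runif
#'   t.test coef complete.cases sd setNames aggregate hclust as.dist cutree
#' @importFrom utils combn read.delim write.table head modifyList
NULL

# ---------------------------------------------------------------------------
# Domain constructors
# ---------------------------------------------------------------------------

#' Construct a genome annotation
#'
#' A `genome_annotation` holds one contig and an ordered table of gene
#' records in 1-based, closed (GFF3-style) coordinates. Genes are the unit
#' of enrichment analysis: every downstream per-gene statistic is computed
#' over the insertion sites falling inside these spans.
#'
#' @param contig_id Single contig (chromosome) identifier.
#' @param contig_length Contig length in bp.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), and optionally `name` and the simulation
#'   attribute columns `class`, `fitness`, `survival` (see
#'   [selection_model()]). Coordinates are 1-based inclusive.
#' @return An object of class `genome_annotation`: a list with elements
#'   `contig_id`, `contig_length` and `genes` (sorted by `(start, gene_id)`,
#'   with a derived `length` column).
#' @export
genome_annotation <- function(contig_id, contig_length, genes) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L)
  contig_length <- as.integer(contig_length)
  stopifnot(length(contig_length) == 1L, contig_length >= 1L)
  required <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("gene table is missing columns: ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$start > genes$end))
    stop("gene with start > end: ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  if (any(genes$start < 1L) || any(genes$end > contig_length))
    stop("gene coordinates outside [1, contig_length]")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(genes$name)) genes$name <- genes$gene_id
  genes <- genes[order(genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes$length <- genes$end - genes$start + 1L
  structure(list(contig_id = contig_id, contig_length = contig_length,
                 genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation: contig", x$contig_id,
      sprintf("(%d bp), %d genes\n", x$contig_length, nrow(x$genes)))
  if ("class" %in% names(x$genes))
    print(table(x$genes$class))
  invisible(x)
}

#' Number of genes in an annotation
#' @param ann A [genome_annotation()].
#' @return Integer gene count.
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Construct a per-sample insertion count table
#'
#' Maps genomic insertion sites (1-based positions, optionally stranded) to
#' read counts for one sequencing sample, together with the sample metadata
#' used to pair each phage-challenged replicate with its untreated control.
#'
#' @param sample_id Sample identifier.
#' @param condition `"control"` or `"phage"`.
#' @param counts `data.frame` with columns `position`, `count` and
#'   optionally `strand` (`"+"`, `"-"` or `"."`; defaults to `"."`).
#' @param contig_id Contig the positions refer to.
#' @param contig_length Optional contig length used to bound-check positions.
#' @param phage_label Phage used for the challenge (empty for controls).
#' @param replicate Replicate number (>= 1).
#' @param paired_control_id `sample_id` of the paired untreated control
#'   (empty for controls themselves).
#' @return An object of class `insertion_count_table` with a cached
#'   `total_reads` element.
#' @export
insertion_count_table <- function(sample_id, condition, counts, contig_id,
                                  contig_length = NA_integer_,
                                  phage_label = "", replicate = 1L,
                                  paired_control_id = "") {
  condition <- match.arg(condition, c("control", "phage"))
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  if (!all(c("position", "count") %in% names(counts)))
    stop("counts must have columns 'position' and 'count'")
  if (is.null(counts$strand)) counts$strand <- "."
  if (!all(counts$strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  counts$position <- as.integer(counts$position)
  if (any(counts$count < 0)) stop("negative read count")
  if (any(counts$position < 1L))
    stop("positions must be >= 1")
  if (!is.na(contig_length) && nrow(counts) &&
      max(counts$position) > contig_length)
    stop("position beyond contig length")
  # collapse accidental duplicate (position, strand) keys
  key <- paste(counts$position, counts$strand)
  if (anyDuplicated(key)) {
    counts <- aggregate(count ~ position + strand, data = counts, FUN = sum)
  }
  counts <- counts[order(counts$position, counts$strand),
                   c("position", "strand", "count"), drop = FALSE]
  rownames(counts) <- NULL
  structure(list(sample_id = as.character(sample_id), condition = condition,
                 phage_label = as.character(phage_label),
                 replicate = as.integer(replicate),
                 paired_control_id = as.character(paired_control_id),
                 contig_id = as.character(contig_id),
                 contig_length = as.integer(contig_length),
                 counts = counts,
                 total_reads = sum(counts$count)),
            class = "insertion_count_table")
}

#' @export
print.insertion_count_table <- function(x, ...) {
  cat(sprintf("insertion_count_table '%s' (%s): %d sites, %s reads on %s\n",
              x$sample_id, x$condition, nrow(x$counts),
              format(x$total_reads, big.mark = ","), x$contig_id))
  invisible(x)
}

#' Collapse insertion strands
#'
#' Sums the `+` and `-` counts observed at the same position into a single
#' unstranded site. A transposon disrupts a gene in either orientation, so
#' "unique insertion" counting is not strand-qualified by default.
#'
#' @param table An [insertion_count_table()].
#' @return The table with one row per position and strand `"."`.
#' @export
collapse_strands <- function(table) {
  stopifnot(inherits(table, "insertion_count_table"))
  cts <- table$counts
  if (all(cts$strand == ".")) return(table)
  agg <- aggregate(count ~ position, data = cts, FUN = sum)
  agg$strand <- "."
  out <- table
  out$counts <- agg[order(agg$position), c("position", "strand", "count")]
  rownames(out$counts) <- NULL
  out$total_reads <- sum(out$counts$count)
  out
}

# ---------------------------------------------------------------------------
# GFF3 / FASTA I/O (rtracklayer / Biostrings)
# ---------------------------------------------------------------------------

#' Read a genome annotation from GFF3
#'
#' Wraps `rtracklayer::import` and keeps features of a single type
#' (default `"gene"`). GFF3 coordinates are 1-based inclusive and are used
#' unchanged as the package's internal convention.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (GFF3 column 3).
#' @param contig_length Optional contig length; defaults to the
#'   `##sequence-region` pragma if present, else the largest feature end.
#' @return A [genome_annotation()] with genes ordered by `(start, gene_id)`.
#' @export
read_annotation <- function(path, feature_type = "gene",
                            contig_length = NA_integer_) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", path)
  contigs <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(contigs) != 1L)
    stop("expected a single contig, found: ", paste(contigs, collapse = ", "))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  if (is.null(ids) || anyNA(ids))
    stop("GFF3 features lack ID attributes")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  if (is.na(contig_length)) {
    si <- GenomeInfoDb_len(gr, contigs)
    if (is.na(si)) si <- sequence_region_length(path, contigs)
    contig_length <- if (!is.na(si)) si else max(GenomicRanges::end(gr))
  }
  genes <- data.frame(gene_id = ids,
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      name = nm, stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  for (col in c("class", "fitness", "survival")) {
    if (!is.null(S4Vectors::mcols(gr)[[col]])) {
      v <- S4Vectors::mcols(gr)[[col]]
      genes[[col]] <- if (col == "class") as.character(v) else as.numeric(as.character(v))
    }
  }
  genome_annotation(contigs, contig_length, genes)
}

GenomeInfoDb_len <- function(gr, contig) {
  len <- GenomeInfoDb::seqlengths(gr)[contig]
  if (length(len) == 1L && !is.na(len)) as.integer(len) else NA_integer_
}

# parse a '##sequence-region <contig> 1 <len>' pragma from the file header
sequence_region_length <- function(path, contig) {
  hdr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
  for (line in hdr) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) >= 4L && f[2] == contig) return(as.integer(f[4]))
  }
  NA_integer_
}

#' Write a genome annotation to GFF3
#'
#' @param ann A [genome_annotation()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig_id,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand)
  gr$type <- "gene"
  gr$ID <- g$gene_id
  gr$Name <- g$name
  for (col in c("class", "fitness", "survival"))
    if (!is.null(g[[col]])) S4Vectors::mcols(gr)[[col]] <- g[[col]]
  GenomeInfoDb::seqlengths(gr) <- setNames(ann$contig_length, ann$contig_id)
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer drops the length pragma; re-insert it after the version line
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", ann$contig_id,
                    ann$contig_length)
  writeLines(append(lines, pragma, after = 1L), path)
  invisible(path)
}

#' Write a genome sequence to FASTA
#' @param seq A `Biostrings::DNAStringSet` (named by contig).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seq, path) {
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Positions of TA dinucleotides in a genome
#'
#' Convenience for mariner-family transposon libraries, whose insertions
#' are restricted to TA sites; Tn5-style libraries (the default model here)
#' insert anywhere.
#'
#' @param seq A `Biostrings::DNAStringSet` with one contig, or `DNAString`.
#' @return Integer vector of 1-based positions of the `T` of each `TA`.
#' @export
ta_sites <- function(seq) {
  if (inherits(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  IRanges::start(Biostrings::matchPattern("TA", seq))
}

# ---------------------------------------------------------------------------
# Count-table and sample-sheet I/O
# ---------------------------------------------------------------------------

#' Write insertion count tables to a wide TSV
#'
#' One row per (contig, position, strand) site, one count column per sample.
#' This is the package's native interchange dialect; [read_counts_tsv()]
#' round-trips it bit-exactly.
#'
#' @param tables Named list of [insertion_count_table()]s sharing a contig.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(tables, path) {
  stopifnot(length(tables) >= 1L)
  contigs <- unique(vapply(tables, function(t) t$contig_id, ""))
  if (length(contigs) != 1L) stop("tables span multiple contigs")
  ids <- vapply(tables, function(t) t$sample_id, "")
  keys <- unique(do.call(rbind, lapply(tables, function(t)
    t$counts[, c("position", "strand")])))
  keys <- keys[order(keys$position, keys$strand), , drop = FALSE]
  out <- data.frame(contig = contigs, position = keys$position,
                    strand = keys$strand, stringsAsFactors = FALSE)
  kk <- paste(keys$position, keys$strand)
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    m <- match(kk, paste(t$counts$position, t$counts$strand))
    v <- t$counts$count[m]
    v[is.na(v)] <- 0L
    out[[ids[i]]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read insertion count tables from a wide TSV
#'
#' @param path TSV written by [write_counts_tsv()] (columns `contig`,
#'   `position`, `strand`, then one column per sample).
#' @param sample_sheet Optional sample sheet `data.frame`
#'   (see [read_sample_sheet()]) supplying metadata per sample; samples
#'   absent from the sheet default to `condition = "control"`, replicate 1.
#' @param contig_length Optional contig length for bound checks.
#' @return Named list of [insertion_count_table()]s.
#' @export
read_counts_tsv <- function(path, sample_sheet = NULL,
                            contig_length = NA_integer_) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("contig", "position", "strand")
  if (!all(fixed %in% names(df)))
    stop("counts TSV must have columns contig, position, strand")
  samples <- setdiff(names(df), fixed)
  if (!length(samples)) stop("counts TSV has no sample columns")
  contig <- unique(df$contig)
  if (length(contig) != 1L) stop("counts TSV spans multiple contigs")
  out <- list()
  for (s in samples) {
    meta <- list(condition = "control", phage_label = "", replicate = 1L,
                 paired_control_id = "")
    if (!is.null(sample_sheet)) {
      row <- sample_sheet[sample_sheet$sample_id == s, , drop = FALSE]
      if (nrow(row) == 1L)
        meta <- list(condition = row$condition, phage_label = row$phage_label,
                     replicate = row$replicate,
                     paired_control_id = row$paired_control_id)
    }
    keep <- df[[s]] != 0L
    out[[s]] <- insertion_count_table(
      s, meta$condition,
      data.frame(position = df$position[keep], strand = df$strand[keep],
                 count = df[[s]][keep], stringsAsFactors = FALSE),
      contig_id = contig, contig_length = contig_length,
      phage_label = meta$phage_label, replicate = meta$replicate,
      paired_control_id = meta$paired_control_id)
  }
  out
}

#' Write one sample's counts as a variableStep genome track
#'
#' Emits the classic wiggle `variableStep` dialect (1-based positions).
#' Strands are collapsed first, since the track format is unstranded.
#'
#' @param table An [insertion_count_table()].
#' @param path Output `.wig` path.
#' @return `path`, invisibly.
#' @export
write_counts_wig <- function(table, path) {
  t <- collapse_strands(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", t$sample_id), con)
  writeLines(sprintf("variableStep chrom=%s", t$contig_id), con)
  nz <- t$counts[t$counts$count > 0, , drop = FALSE]  # absent site = 0
  writeLines(sprintf("%d\t%d", nz$position, nz$count), con)
  invisible(path)
}

#' Read a variableStep genome track into an insertion count table
#'
#' Uses `rtracklayer::import` (wig positions are 1-based; single-bp spans
#' are kept as single unstranded sites).
#'
#' @param path `.wig` file.
#' @param sample_id Sample identifier for the resulting table.
#' @param condition,phage_label,replicate,paired_control_id Sample metadata.
#' @param contig_length Optional contig length.
#' @return An [insertion_count_table()].
#' @export
read_counts_wig <- function(path, sample_id = basename(path),
                            condition = "control", phage_label = "",
                            replicate = 1L, paired_control_id = "",
                            contig_length = NA_integer_) {
  gr <- rtracklayer::import(path, format = "wig")
  contig <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(contig) != 1L) stop("wig track spans multiple contigs")
  # expand any multi-bp spans to per-bp sites with the span's score
  w <- GenomicRanges::width(gr)
  pos <- unlist(mapply(function(s, wd) s + seq_len(wd) - 1L,
                       GenomicRanges::start(gr), w, SIMPLIFY = FALSE))
  cnt <- rep(gr$score, w)
  insertion_count_table(sample_id, condition,
                        data.frame(position = pos, strand = ".", count = cnt),
                        contig_id = contig, contig_length = contig_length,
                        phage_label = phage_label, replicate = replicate,
                        paired_control_id = paired_control_id)
}

#' Read / write the sample sheet
#'
#' The sample sheet pairs each phage-challenged replicate with its untreated
#' control: columns `sample_id`, `condition`, `phage_label`, `replicate`,
#' `paired_control_id`.
#'
#' @param path TSV path.
#' @return `read_sample_sheet`: a `data.frame`. `write_sample_sheet`:
#'   `path`, invisibly.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  req <- c("sample_id", "condition", "phage_label", "replicate",
           "paired_control_id")
  if (!all(req %in% names(df)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (!all(df$condition %in% c("control", "phage")))
    stop("condition must be 'control' or 'phage'")
  df$replicate <- as.integer(df$replicate)
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Site -> gene assignment
# ---------------------------------------------------------------------------

#' Assign insertion sites to genes
#'
#' A site at position `p` belongs to gene `g` iff
#' `start(g) <= p <= end(g)` (closed interval, both ends inclusive).
#' Insertion strand is ignored by default (a transposon disrupts either
#' orientation); with overlapping genes a site is assigned to every
#' overlapping gene. Sites outside all genes are kept in an `"intergenic"`
#' bucket.
#'
#' @param table An [insertion_count_table()].
#' @param ann A [genome_annotation()] on the same contig.
#' @param collapse_strand Collapse `+`/`-` counts at a position into one
#'   site before assignment (default `TRUE`).
#' @param trim_frac Fraction of each gene's length excluded at *each*
#'   terminus before assignment (default 0; no trimming).
#' @return List with elements `genes` (named list of `gene_site_profile`s,
#'   one per annotated gene, each a list with `gene_id`, `sites`
#'   (`data.frame(position, count)`), `unique_insertions`, `gene_total`)
#'   and `intergenic` (the same shape for the leftover sites).
#' @export
assign_sites_to_genes <- function(table, ann, collapse_strand = TRUE,
                                  trim_frac = 0) {
  stopifnot(inherits(table, "insertion_count_table"),
            inherits(ann, "genome_annotation"))
  if (table$contig_id != ann$contig_id)
    stop("contig mismatch: table '", table$contig_id, "' vs annotation '",
         ann$contig_id, "'")
  stopifnot(trim_frac >= 0, trim_frac < 0.5)
  if (collapse_strand) table <- collapse_strands(table)
  cts <- table$counts
  g <- ann$genes
  starts <- g$start
  ends <- g$end
  if (trim_frac > 0) {
    trim <- floor(g$length * trim_frac)
    starts <- starts + trim
    ends <- ends - trim
  }
  gene_rng <- IRanges::IRanges(starts, ends)
  site_rng <- IRanges::IRanges(cts$position, width = 1L)
  ov <- IRanges::findOverlaps(site_rng, gene_rng)
  profile <- function(id, idx) {
    s <- cts[idx, c("position", "count"), drop = FALSE]
    rownames(s) <- NULL
    structure(list(gene_id = id, sites = s,
                   unique_insertions = sum(s$count >= 1),
                   gene_total = sum(s$count)),
              class = "gene_site_profile")
  }
  hits_by_gene <- split(S4Vectors::queryHits(ov),
                        factor(S4Vectors::subjectHits(ov),
                               levels = seq_len(nrow(g))))
  genes <- lapply(seq_len(nrow(g)), function(i)
    profile(g$gene_id[i], hits_by_gene[[i]]))
  names(genes) <- g$gene_id
  inter_idx <- setdiff(seq_len(nrow(cts)), unique(S4Vectors::queryHits(ov)))
  list(genes = genes, intergenic = profile("intergenic", inter_idx))
}

#' @export
print.gene_site_profile <- function(x, ...) {
  cat(sprintf("gene_site_profile %s: %d sites, %d unique insertions, total %s\n",
              x$gene_id, nrow(x$sites), x$unique_insertions,
              format(x$gene_total, digits = 12)))
  invisible(x)
}
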