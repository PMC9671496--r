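# Synthetic transposon-library-under-phage-selection generator.
#
# The generator emulates the regimes a high-density Tn5-style library shows
# after a high-MOI phage challenge: essential-gene insertion voids, depletion
# of fitness-costly mutants during library growth, strong enrichment of
# phage-survival mutants, a colony plating bottleneck, and overdispersed
# sequencing counts.

GENE_CLASSES <- c("neutral", "essential", "resistance",
                  "costly_resistance", "costly_neutral")

#' Global parameters of the selection simulation
#'
#' Collects the global knobs of the simulated screen. Per-gene parameters
#' (class, relative fitness `w`, survival probability `s`) live as columns
#' of the [genome_annotation()] gene table, filled in by [generate_genome()].
#'
#' @param escape_baseline Survival probability of phage-*sensitive* mutants
#'   under challenge (models lysogeny / phenotypic escape). Default `1e-3`.
#' @param library_size Number of transposon mutants in the library.
#'   Default `1e5`.
#' @param survivor_plate_capacity Colony capacity of the challenged-arm
#'   plating (survivors are subsampled without replacement down to this
#'   many colonies). Default `2e4`.
#' @param control_capacity_factor The control arm skips phage killing but
#'   has its own, larger plating capacity:
#'   `control_capacity_factor * survivor_plate_capacity` (default 100,
#'   mirroring the hundred-fold dilution difference between the arms).
#' @param read_depth Total sequencing reads for a control sample.
#'   Default `1e6`.
#' @param challenged_depth_ratio Challenged samples are sequenced at
#'   `read_depth * challenged_depth_ratio` reads (default `0.01`,
#'   mirroring 1:100 pooling of low-complexity challenged libraries
#'   against controls).
#' @param dispersion Overdispersion of sequencing counts: per-site Gamma
#'   shape of the multinomial rate mixture; `Inf` gives a plain
#'   multinomial. Default 10 (coefficient of variation ~0.32 per site).
#' @param resistance_survival Survival probability `s` of mutants in
#'   resistance-class genes. Default 0.9.
#' @param costly_fitness Relative fitness `w` of costly classes during
#'   library growth. Default 0.1.
#' @param seed Master seed; all per-stage seeds derive from it via
#'   [child_seed()].
#' @return A `selection_model` list.
#' @export
selection_model <- function(escape_baseline = 1e-3,
                            library_size = 1e5,
                            survivor_plate_capacity = 2e4,
                            control_capacity_factor = 100,
                            read_depth = 1e6,
                            challenged_depth_ratio = 0.01,
                            dispersion = 10,
                            resistance_survival = 0.9,
                            costly_fitness = 0.1,
                            seed = 1L) {
  stopifnot(escape_baseline >= 0, escape_baseline <= 1,
            resistance_survival >= 0, resistance_survival <= 1,
            library_size >= 1, survivor_plate_capacity >= 1,
            read_depth >= 0, dispersion > 0,
            costly_fitness >= 0, costly_fitness <= 1)
  structure(list(escape_baseline = escape_baseline,
                 library_size = as.integer(library_size),
                 survivor_plate_capacity = as.integer(survivor_plate_capacity),
                 control_capacity_factor = control_capacity_factor,
                 read_depth = as.integer(read_depth),
                 challenged_depth_ratio = challenged_depth_ratio,
                 dispersion = dispersion,
                 resistance_survival = resistance_survival,
                 costly_fitness = costly_fitness,
                 seed = as.integer(seed)),
            class = "selection_model")
}

#' Derive a per-stage child seed from the master seed
#'
#' A documented counter scheme so each simulation stage is independently
#' reproducible: `child_seed(master, k) = (master * 7919 + k * 104729)
#' mod (2^31 - 1)` (two primes; result always a valid 32-bit seed).
#'
#' @param master Master seed (integer).
#' @param index Stage counter (integer >= 0).
#' @return Integer seed.
#' @export
child_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + as.double(index) * 104729) %%
               2147483647)
}

#' Apportion gene classes by largest remainder
#'
#' Hamilton apportionment of `n` genes to class fractions: each class gets
#' `floor(n * f)` and leftover seats go to the largest fractional
#' remainders (ties broken by class order). Any class with a positive
#' fraction but zero seats is topped up from the largest class when `n`
#' permits, so every requested class is represented.
#'
#' @param n Number of genes.
#' @param fractions Named numeric vector over gene classes, summing to 1.
#' @return Named integer vector of class counts summing to `n`.
#' @export
apportion_classes <- function(n, fractions) {
  stopifnot(n >= 1, abs(sum(fractions) - 1) < 1e-8,
            all(names(fractions) %in% GENE_CLASSES))
  quota <- n * fractions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  # guarantee representation of requested classes
  for (cl in names(fractions)) {
    if (fractions[cl] > 0 && counts[cl] == 0 && n >= sum(fractions > 0)) {
      donor <- names(which.max(counts))
      counts[donor] <- counts[donor] - 1
      counts[cl] <- 1
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a synthetic genome with class-annotated genes
#'
#' Lays out `n_genes` non-overlapping genes separated by fixed intergenic
#' spacers on one contig, assigns each gene a selection class, per-gene
#' relative fitness `w` and phage-survival probability `s`, and draws a
#' random nucleotide sequence. Two designated "small genes"
#' (length < `small_gene_len`) are planted — one resistance-class if the
#' class is present, one neutral — to exercise the small-gene review path
#' of the hit caller.
#'
#' @param n_genes Number of genes (>= 1).
#' @param mean_gene_len Mean gene length, bp (Gamma-distributed lengths,
#'   sd ~ 30% of the mean, floor 150 bp).
#' @param intergenic_len Spacer between consecutive genes, bp.
#' @param class_fractions Named fractions over
#'   `neutral, essential, resistance, costly_resistance, costly_neutral`,
#'   summing to 1.
#' @param model A [selection_model()] supplying `s`, `w` and the seed.
#' @param small_gene_len Genes shorter than this are "small" (default 400).
#' @param seed Seed; defaults to stage 1 of the model's master seed.
#' @return List with `annotation` (a [genome_annotation()] whose gene table
#'   carries `class`, `fitness`, `survival` columns) and `sequence`
#'   (a `DNAStringSet`).
#' @export
generate_genome <- function(n_genes = 2000,
                            mean_gene_len = 1000,
                            intergenic_len = 100,
                            class_fractions = c(neutral = 0.9175,
                                                essential = 0.05,
                                                resistance = 0.005,
                                                costly_resistance = 0.0025,
                                                costly_neutral = 0.025),
                            model = selection_model(),
                            small_gene_len = 400,
                            seed = child_seed(model$seed, 1L)) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  counts <- apportion_classes(n_genes, class_fractions)
  set.seed(seed)
  lens <- pmax(150L, as.integer(round(
    rgamma(n_genes, shape = 11.1, scale = mean_gene_len / 11.1))))
  classes <- sample(rep(names(counts), counts))
  # plant the two small genes: one resistance (if any), one neutral
  small_len <- max(150L, as.integer(small_gene_len * 0.6))
  small_idx <- integer(0)
  if (any(classes == "resistance"))
    small_idx <- which(classes == "resistance")[1L]
  small_idx <- c(small_idx, setdiff(which(classes == "neutral"),
                                    small_idx)[1L])
  small_idx <- small_idx[!is.na(small_idx)]
  lens[small_idx] <- small_len
  starts <- intergenic_len + cumsum(c(1L, head(lens, -1) + intergenic_len))
  ends <- starts + lens - 1L
  contig_len <- ends[n_genes] + intergenic_len
  if (contig_len > 2^31 - 2)
    stop("requested genome too large for integer coordinates")
  w <- c(neutral = 1, essential = 0, resistance = 1,
         costly_resistance = model$costly_fitness,
         costly_neutral = model$costly_fitness)[classes]
  s <- ifelse(classes %in% c("resistance", "costly_resistance"),
              model$resistance_survival, model$escape_baseline)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    start = starts, end = ends,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    name = sprintf("g%04d", seq_len(n_genes)),
    class = classes, fitness = unname(w), survival = unname(s),
    stringsAsFactors = FALSE)
  ann <- genome_annotation("chrSim", contig_len, genes)
  seq <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
    collapse = ""))
  names(seq) <- "chrSim"
  list(annotation = ann, sequence = seq)
}

#' Build the latent transposon library
#'
#' Draws `library_size` independent mutants with insertion sites uniform
#' over the insertable genome — all positions except essential gene bodies
#' (essential voids) — and clonal abundances from a unit-mean Gamma
#' (shape 1) scaled by the host gene's relative fitness `w`, so costly
#' classes are depleted during outgrowth.
#'
#' @param ann A [genome_annotation()] with `class`/`fitness` columns.
#' @param model A [selection_model()].
#' @param seed Seed; defaults to stage 2 of the model's master seed.
#' @param ta_positions Optional integer vector restricting insertion sites
#'   (e.g. from [ta_sites()]) for mariner-style libraries.
#' @return A `tn_library` data.frame: one row per mutant with columns
#'   `mutant_id`, `position`, `strand`, `gene_id` (`NA` if intergenic),
#'   `class`, `abundance`; the annotation is attached as attribute `ann`.
#' @export
build_library <- function(ann, model, seed = child_seed(model$seed, 2L),
                          ta_positions = NULL) {
  g <- ann$genes
  ess <- g[g$class == "essential", , drop = FALSE]
  allowed <- IRanges::setdiff(
    IRanges::IRanges(1L, ann$contig_length),
    IRanges::IRanges(ess$start, ess$end))
  set.seed(seed)
  n <- model$library_size
  if (is.null(ta_positions)) {
    widths <- IRanges::width(allowed)
    iv <- sample.int(length(allowed), n, replace = TRUE,
                     prob = widths / sum(widths))
    offs <- floor(runif(n) * widths[iv])
    pos <- IRanges::start(allowed)[iv] + as.integer(offs)
  } else {
    ok <- !IRanges::overlapsAny(
      IRanges::IRanges(ta_positions, width = 1L),
      IRanges::IRanges(ess$start, ess$end))
    pool <- ta_positions[ok]
    if (!length(pool)) stop("no insertable TA sites outside essential genes")
    pos <- sample(pool, n, replace = TRUE)
  }
  ov <- IRanges::findOverlaps(IRanges::IRanges(pos, width = 1L),
                              IRanges::IRanges(g$start, g$end),
                              select = "first")
  gene_id <- ifelse(is.na(ov), NA_character_, g$gene_id[ov])
  class <- ifelse(is.na(ov), "intergenic", g$class[ov])
  w <- ifelse(is.na(ov), 1, g$fitness[ov])
  abundance <- rgamma(n, shape = 1, rate = 1) * w
  lib <- data.frame(mutant_id = seq_len(n), position = pos,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    gene_id = gene_id, class = class, abundance = abundance,
                    stringsAsFactors = FALSE)
  attr(lib, "ann") <- ann
  class(lib) <- c("tn_library", "data.frame")
  lib
}

#' Apply phage selection and the plating bottleneck
#'
#' Under the `"phage"` arm each mutant survives independently with
#' probability `s` of its gene's class (resistance classes) or the global
#' escape baseline otherwise; survivors are then subsampled without
#' replacement — weighted by clonal abundance — down to the challenged
#' plate capacity. The `"control"` arm bypasses killing and applies its
#' own, `control_capacity_factor`-fold larger capacity.
#'
#' @param library A `tn_library` from [build_library()].
#' @param model A [selection_model()].
#' @param arm `"phage"` or `"control"`.
#' @param seed Seed; defaults to stage 3 of the model's master seed.
#' @return The surviving `tn_library` (possibly empty, with a warning).
#' @export
apply_phage_selection <- function(library, model,
                                  arm = c("phage", "control"),
                                  seed = child_seed(model$seed, 3L)) {
  arm <- match.arg(arm)
  if (!nrow(library)) stop("library is empty")
  set.seed(seed)
  if (arm == "phage") {
    p <- ifelse(library$class %in% c("resistance", "costly_resistance"),
                model$resistance_survival, model$escape_baseline)
    keep <- runif(nrow(library)) < p
    surv <- library[keep, , drop = FALSE]
    capacity <- model$survivor_plate_capacity
  } else {
    surv <- library
    capacity <- as.integer(min(
      model$survivor_plate_capacity * model$control_capacity_factor,
      .Machine$integer.max))
  }
  if (!nrow(surv)) {
    warning("no survivors after phage selection")
  } else if (nrow(surv) > capacity) {
    idx <- sample.int(nrow(surv), capacity, replace = FALSE,
                      prob = surv$abundance)
    surv <- surv[sort(idx), , drop = FALSE]
  }
  rownames(surv) <- NULL
  attr(surv, "ann") <- attr(library, "ann")
  class(surv) <- c("tn_library", "data.frame")
  surv
}

#' Sequence a library into an insertion count table
#'
#' Aggregates clonal abundances per (position, strand) site and draws
#' `read_depth` reads from a gamma-multinomial: each site's multinomial
#' rate is its abundance share perturbed by a Gamma with shape
#' `dispersion` and mean equal to that share (`dispersion = Inf` gives
#' the plain multinomial). The returned table's total is exactly
#' `read_depth`.
#'
#' @param library A `tn_library`.
#' @param read_depth Total reads to draw (>= 0).
#' @param dispersion Per-site Gamma shape (> 0, `Inf` allowed).
#' @param seed RNG seed.
#' @param sample_id,condition,phage_label,replicate,paired_control_id
#'   Metadata for the resulting [insertion_count_table()].
#' @return An [insertion_count_table()].
#' @export
sequence_library <- function(library, read_depth, dispersion = 10, seed = 1L,
                             sample_id = "sample", condition = "control",
                             phage_label = "", replicate = 1L,
                             paired_control_id = "") {
  stopifnot(read_depth >= 0)
  ann <- attr(library, "ann")
  contig <- if (!is.null(ann)) ann$contig_id else "chrSim"
  contig_len <- if (!is.null(ann)) ann$contig_length else NA_integer_
  make_table <- function(counts_df)
    insertion_count_table(sample_id, condition, counts_df,
                          contig_id = contig, contig_length = contig_len,
                          phage_label = phage_label, replicate = replicate,
                          paired_control_id = paired_control_id)
  if (!nrow(library) || read_depth == 0)
    return(make_table(data.frame(position = integer(0), strand = character(0),
                                 count = integer(0))))
  agg <- aggregate(abundance ~ position + strand, data = library, FUN = sum)
  set.seed(seed)
  share <- agg$abundance / sum(agg$abundance)
  rate <- if (is.finite(dispersion)) {
    rgamma(length(share), shape = dispersion, rate = dispersion / share)
  } else share
  if (sum(rate) == 0) rate <- share  # degenerate gamma draw guard
  reads <- as.integer(rmultinom(1L, size = read_depth, prob = rate))
  keep <- reads > 0L
  make_table(data.frame(position = agg$position[keep],
                        strand = agg$strand[keep],
                        count = reads[keep], stringsAsFactors = FALSE))
}

#' Simulate a complete two-replicate phage-challenge screen
#'
#' Orchestrates genome generation, library construction, two independent
#' phage challenges of the same library with paired untreated controls,
#' and sequencing, using per-stage seeds derived from the master seed.
#' Challenged samples are sequenced at `read_depth *
#' challenged_depth_ratio` reads, controls at `read_depth`.
#'
#' @param model A [selection_model()].
#' @param n_genes,mean_gene_len,intergenic_len,class_fractions,small_gene_len
#'   Passed to [generate_genome()].
#' @param phage_label Label recorded for the challenged samples.
#' @return List with `annotation`, `sequence`, `library`, `samples`
#'   (named list of four [insertion_count_table()]s: `phage_A`, `phage_B`,
#'   `control_A`, `control_B`), `sample_sheet`, and `truth`
#'   (`data.frame(gene_id, class, length, planted)` where `planted` marks
#'   resistance and costly-resistance genes).
#' @export
simulate_experiment <- function(model = selection_model(),
                                n_genes = 2000, mean_gene_len = 1000,
                                intergenic_len = 100,
                                class_fractions = c(neutral = 0.9175,
                                                    essential = 0.05,
                                                    resistance = 0.005,
                                                    costly_resistance = 0.0025,
                                                    costly_neutral = 0.025),
                                small_gene_len = 400,
                                phage_label = "phiSim") {
  gen <- generate_genome(n_genes = n_genes, mean_gene_len = mean_gene_len,
                         intergenic_len = intergenic_len,
                         class_fractions = class_fractions, model = model,
                         small_gene_len = small_gene_len,
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model,
                       seed = child_seed(model$seed, 2L))
  depth_ch <- as.integer(round(model$read_depth * model$challenged_depth_ratio))
  samples <- list()
  for (r in 1:2) {
    rep_tag <- c("A", "B")[r]
    ch <- apply_phage_selection(lib, model, arm = "phage",
                                seed = child_seed(model$seed, 10L + r))
    co <- apply_phage_selection(lib, model, arm = "control",
                                seed = child_seed(model$seed, 20L + r))
    samples[[paste0("phage_", rep_tag)]] <- sequence_library(
      ch, depth_ch, model$dispersion, seed = child_seed(model$seed, 30L + r),
      sample_id = paste0("phage_", rep_tag), condition = "phage",
      phage_label = phage_label, replicate = r,
      paired_control_id = paste0("control_", rep_tag))
    samples[[paste0("control_", rep_tag)]] <- sequence_library(
      co, model$read_depth, model$dispersion,
      seed = child_seed(model$seed, 40L + r),
      sample_id = paste0("control_", rep_tag), condition = "control",
      phage_label = "", replicate = r)
  }
  sheet <- data.frame(
    sample_id = c("phage_A", "phage_B", "control_A", "control_B"),
    condition = c("phage", "phage", "control", "control"),
    phage_label = c(phage_label, phage_label, "", ""),
    replicate = c(1L, 2L, 1L, 2L),
    paired_control_id = c("control_A", "control_B", "", ""),
    stringsAsFactors = FALSE)
  g <- gen$annotation$genes
  truth <- data.frame(gene_id = g$gene_id, class = g$class,
                      length = g$length,
                      planted = g$class %in% c("resistance",
                                               "costly_resistance"),
                      stringsAsFactors = FALSE)
  list(annotation = gen$annotation, sequence = gen$sequence, library = lib,
       samples = samples, sample_sheet = sheet, truth = truth)
}
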