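test_that("class apportionment follows largest remainder and guarantees representation", {
  counts <- apportion_classes(100, c(neutral = .85, essential = .05,
                                     resistance = .05,
                                     costly_resistance = .05))
  expect_equal(unname(counts[c("neutral", "essential", "resistance",
                               "costly_resistance")]),
               c(85L, 5L, 5L, 5L))
  # a tiny positive fraction still gets one gene
  counts2 <- apportion_classes(50, c(neutral = 0.999, resistance = 0.001))
  expect_equal(unname(counts2["resistance"]), 1L)
  expect_equal(sum(counts2), 50L)
})

test_that("genome generation is deterministic and respects its preconditions", {
  expect_error(generate_genome(n_genes = 0), "n_genes")
  g1 <- generate_genome(n_genes = 60, seed = 5)
  g2 <- generate_genome(n_genes = 60, seed = 5)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  genes <- g1$annotation$genes
  # non-overlapping in start order
  expect_true(all(head(genes$end, -1) < genes$start[-1]))
  # at least one gene per requested class
  expect_true(all(c("neutral", "essential", "resistance",
                    "costly_resistance", "costly_neutral") %in% genes$class))
  # two planted small genes to exercise the review flag
  expect_gte(sum(genes$length < 400), 2L)
  expect_equal(nchar(as.character(g1$sequence[[1]])),
               g1$annotation$contig_length)
})

test_that("library building leaves essential genes void and scales abundance by fitness", {
  model <- selection_model(library_size = 4e4, seed = 9)
  gen <- generate_genome(n_genes = 100, model = model,
                         class_fractions = c(neutral = 0.5, essential = 0.2,
                                             costly_neutral = 0.3),
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model)
  genes <- gen$annotation$genes
  ess <- genes[genes$class == "essential", ]
  in_ess <- mapply(function(s, e) any(lib$position >= s & lib$position <= e),
                   ess$start, ess$end)
  expect_false(any(in_ess))
  # abundance ratio ~ fitness ratio (0.1), Monte-Carlo tolerance over >= 1e4 draws
  mean_w1 <- mean(lib$abundance[lib$class == "neutral"])
  mean_w01 <- mean(lib$abundance[lib$class == "costly_neutral"])
  expect_gt(sum(lib$class == "costly_neutral"), 1e4)
  expect_equal(mean_w01 / mean_w1, 0.1, tolerance = 0.1)
  # determinism
  lib2 <- build_library(gen$annotation, model)
  expect_identical(lib$position, lib2$position)
})

test_that("TA-restricted libraries only insert at TA sites", {
  model <- selection_model(library_size = 500, seed = 3)
  gen <- generate_genome(n_genes = 20, model = model,
                         seed = child_seed(model$seed, 1L))
  ta <- ta_sites(gen$sequence)
  lib <- build_library(gen$annotation, model, ta_positions = ta)
  expect_true(all(lib$position %in% ta))
})

test_that("phage selection keeps resistance mutants and drops sensitive ones in the limiting case", {
  model <- selection_model(library_size = 2e4, escape_baseline = 0,
                           resistance_survival = 1, seed = 13)
  gen <- generate_genome(n_genes = 200, model = model,
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model)
  surv <- apply_phage_selection(lib, model, arm = "phage")
  expect_true(all(surv$class %in% c("resistance", "costly_resistance")))
  expect_equal(nrow(surv),
               sum(lib$class %in% c("resistance", "costly_resistance")))
})

test_that("escape survivors match the binomial expectation", {
  # eps = 0.01 over 2e4 sensitive mutants -> 200 +- 4*sqrt(200*0.99)
  model <- selection_model(library_size = 2e4, escape_baseline = 0.01,
                           seed = 31)
  gen <- generate_genome(n_genes = 200, model = model,
                         class_fractions = c(neutral = 1),
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model)
  surv <- apply_phage_selection(lib, model, arm = "phage")
  expected <- nrow(lib) * 0.01
  expect_lt(abs(nrow(surv) - expected), 4 * sqrt(expected * 0.99))
})

test_that("plating bottleneck is the identity when capacity covers survivors", {
  model <- selection_model(library_size = 1000,
                           survivor_plate_capacity = 1e6, seed = 7)
  gen <- generate_genome(n_genes = 50, model = model,
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model)
  ctrl <- apply_phage_selection(lib, model, arm = "control")
  expect_equal(nrow(ctrl), nrow(lib))
  expect_equal(ctrl$position, lib$position)
})

test_that("zero survivors is a warned, valid edge", {
  model <- selection_model(library_size = 500, escape_baseline = 0, seed = 2)
  gen <- generate_genome(n_genes = 50, model = model,
                         class_fractions = c(neutral = 1),
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model)
  expect_warning(surv <- apply_phage_selection(lib, model, arm = "phage"),
                 "no survivors")
  expect_equal(nrow(surv), 0L)
})

test_that("sequencing conserves read depth exactly and handles edges", {
  model <- selection_model(library_size = 2000, seed = 17)
  gen <- generate_genome(n_genes = 50, model = model,
                         seed = child_seed(model$seed, 1L))
  lib <- build_library(gen$annotation, model)
  for (depth in c(0L, 1L, 12345L)) {
    t <- sequence_library(lib, depth, dispersion = 5, seed = 4)
    expect_identical(t$total_reads, depth)
  }
  # single-mutant library receives every read
  t1 <- sequence_library(lib[1, ], 999L, seed = 4)
  expect_equal(nrow(t1$counts), 1L)
  expect_equal(t1$counts$count, 999L)
})

test_that("dispersion -> Inf converges to the plain multinomial variance", {
  lib <- data.frame(mutant_id = 1:4, position = c(10L, 20L, 30L, 40L),
                    strand = "+", gene_id = NA, class = "intergenic",
                    abundance = c(1, 2, 3, 4))
  class(lib) <- c("tn_library", "data.frame")
  depth <- 400L
  p1 <- 1 / 10  # site 10's share
  draws <- function(disp) vapply(1:1000, function(i)
    site_count(sequence_library(lib, depth, dispersion = disp, seed = i), 10L),
    0)
  site_count <- function(t, pos) {
    i <- match(pos, t$counts$position)
    if (is.na(i)) 0 else t$counts$count[i]
  }
  v_inf <- var(draws(Inf))
  v_small <- var(draws(2))
  v_multinom <- depth * p1 * (1 - p1)
  expect_equal(v_inf, v_multinom, tolerance = 0.15)
  expect_gt(v_small, 2 * v_multinom)
})

test_that("increasing survival never decreases expected challenged counts (common random numbers)", {
  base <- selection_model(library_size = 5000, read_depth = 5e4, seed = 23)
  gen <- generate_genome(n_genes = 100, model = base,
                         seed = child_seed(base$seed, 1L))
  lib <- build_library(gen$annotation, base)
  target <- gen$annotation$genes$gene_id[gen$annotation$genes$class ==
                                           "resistance"][1]
  count_for <- function(s) {
    m <- base
    m$resistance_survival <- s
    tot <- 0
    for (i in 1:20) {
      surv <- apply_phage_selection(lib, m, arm = "phage",
                                    seed = child_seed(100L, i))
      t <- sequence_library(surv, m$read_depth, m$dispersion,
                            seed = child_seed(200L, i))
      asn <- assign_sites_to_genes(t, gen$annotation)
      tot <- tot + asn$genes[[target]]$gene_total
    }
    tot
  }
  expect_lte(count_for(0.3), count_for(0.9))
})

test_that("simulate_experiment emits 2+2 samples, a sheet, and a consistent truth table", {
  sim <- small_sim()
  expect_named(sim$samples, c("phage_A", "control_A", "phage_B", "control_B"),
               ignore.order = TRUE)
  conds <- vapply(sim$samples, function(s) s$condition, "")
  expect_equal(sum(conds == "phage"), 2L)
  expect_equal(sum(conds == "control"), 2L)
  expect_equal(nrow(sim$truth), 300L)
  expect_equal(sim$truth$class, sim$annotation$genes$class)
  # essential genes have zero counts in every sample, always
  ess <- sim$annotation$genes[sim$annotation$genes$class == "essential", ]
  for (s in sim$samples) {
    asn <- assign_sites_to_genes(s, sim$annotation)
    for (g in ess$gene_id) expect_equal(asn$genes[[g]]$gene_total, 0)
  }
  # resistance genes' challenged read share far exceeds their control share
  res_ids <- sim$truth$gene_id[sim$truth$class == "resistance"]
  share <- function(s) {
    asn <- assign_sites_to_genes(s, sim$annotation)
    sum(vapply(res_ids, function(g) asn$genes[[g]]$gene_total, 0)) /
      s$total_reads
  }
  expect_gt(share(sim$samples$phage_A), 20 * share(sim$samples$control_A))
})
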