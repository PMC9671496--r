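# Shared fixture builders and independent oracles.

# three non-overlapping genes on a 1 kb contig
toy_annotation <- function() {
  genome_annotation("chrT", 1000L, data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    start = c(101L, 301L, 601L),
    end = c(200L, 500L, 900L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
}

toy_table <- function(positions, counts, strand = ".",
                      sample_id = "s1", condition = "control", ...) {
  insertion_count_table(
    sample_id, condition,
    data.frame(position = positions,
               strand = rep(strand, length.out = length(positions)),
               count = counts),
    contig_id = "chrT", contig_length = 1000L, ...)
}

# Independent Mann-Whitney oracle: enumerate every labeling, computing U by
# direct pair counting (x > y scores 1, ties 0.5); two-sided p is the share
# of labelings at least as far from nm/2 as the observed U.
brute_force_mw <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  gt <- outer(pooled, pooled, ">") + 0.5 * outer(pooled, pooled, "==")
  U_of <- function(idx) sum(gt[idx, -idx, drop = FALSE])
  labelings <- combn(n + m, n)
  Us <- apply(labelings, 2L, U_of)
  U_obs <- U_of(seq_len(n))
  mu <- n * m / 2
  list(U = U_obs, p.value = mean(abs(Us - mu) >= abs(U_obs - mu)))
}

# Independent BH oracle: q_(i) = min_{j >= i} p_(j) * m / j, by definition.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i)
    min(ps[i:m] * m / (i:m), 1), 0)
  out <- numeric(m)
  out[ord] <- q
  out
}

# small simulated experiment shared across tests (cheap; seconds)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- selection_model(library_size = 2e4, read_depth = 2e5,
                               survivor_plate_capacity = 5e3, seed = 101L)
      cache <<- simulate_experiment(model = model, n_genes = 300)
    }
    cache
  }
})
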