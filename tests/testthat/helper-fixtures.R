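# Shared fixtures: small chips and simulation configs used across tests.

tiny_layout <- function(n = 8L, areas = 1L) {
  chip_layout(n_channels = n, alignment_channels = c(0L, n - 1L),
              grid_rows = areas, grid_cols = areas)
}

tiny_config <- function(seed = 42L, layout = tiny_layout(), ...) {
  defaults <- list(seed = seed, layout = layout, n_genes = 20L,
                   reads_per_umi = 2L, error_rate = 0,
                   contamination_rate = 0, intron_fraction = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Four-barcode toy legend with pairwise Hamming distance >= 3 per axis
# (hand-picked, so correction behaviour is fully predictable).
toy_legend <- function(with_z = TRUE) {
  barcode_legend(
    x = c(AAAAAAAA = 0L, CCCCAAAA = 1L, AAAACCCC = 2L, GGGGGGGG = 3L),
    y = c(TTTTTTTT = 0L, AAATTTTT = 1L, TTTTAAAA = 2L, CCCCCCCC = 3L),
    z = if (with_z) c(ACACACAC = "A1", GTGTGTGT = "A1",
                      AGAGAGAG = "B1", TCTCTCTC = "B1")
  )
}

# Assemble a read 2 for the default layout from its fields.
build_read2 <- function(umi, x, y, z = NULL, linker = strrep("N", 20)) {
  linker <- chartr("N", "A", linker)
  paste0(umi, x, linker, y, if (!is.null(z)) paste0(linker, z))
}

# Independent oracle: per-read exhaustive minimum-Hamming legend search.
oracle_match <- function(seq, ref_seqs, max_hamming) {
  if (is.na(seq) || nchar(seq) != nchar(ref_seqs[1]) ||
      !grepl("^[ACGT]+$", seq)) return(NA_integer_)
  d <- vapply(ref_seqs, function(r)
    sum(strsplit(seq, "")[[1]] != strsplit(r, "")[[1]]), integer(1))
  m <- min(d)
  if (m > max_hamming || sum(d == m) > 1L) return(NA_integer_)
  which.min(d)
}

# Independent oracle: UMI cluster count via igraph connected components
# over the graph of all Hamming<=1 pairs.
oracle_umi_clusters <- function(umis) {
  u <- unique(umis)
  n <- length(u)
  if (n <= 1L) return(n)
  edges <- integer(0)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- sum(strsplit(u[i], "")[[1]] != strsplit(u[j], "")[[1]])
    if (d <= 1L) edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  as.integer(igraph::components(g)$no)
}
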