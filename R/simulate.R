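# Synthetic-data generator: every input the pipeline consumes (legends,
# reads, truth counts, images, transforms) with the statistical structure
# the downstream analysis assumes, fully determined by a seed.

#' Configuration for a synthetic experiment
#'
#' Bundles the chip layout, read structure and all statistical parameters
#' of the generator. Identical configurations with identical seeds yield
#' identical outputs.
#'
#' @param seed Master seed; the generator derives fixed sub-streams for
#'   legend, counts, reads and images.
#' @param layout [chip_layout()] of the simulated chip.
#' @param read_layout [read_layout()] of read 2.
#' @param n_genes Number of genes in the toy transcriptome.
#' @param contamination_gene_fraction Fraction of genes that are ambient
#'   contamination only (no tissue expression).
#' @param gene_mean_meanlog,gene_mean_sdlog Log-normal parameters for
#'   per-gene tissue expression means (counts per spot).
#' @param background_lambda Ambient Poisson mean per gene per spot,
#'   observed in every spot (background spots show only this).
#' @param expression_model `"poisson"` (default) or `"nb"`; `"nb"` adds
#'   overdispersion with size `nb_size`.
#' @param nb_size Negative-binomial size parameter (only for `"nb"`).
#' @param stripe_row_factors,stripe_col_factors Optional multiplicative
#'   per-channel factors (length `n_channels`) emulating unequal flow;
#'   `NULL` means no stripe artifact.
#' @param tissue_radius_frac Tissue disc radius as a fraction of the
#'   capture-area side.
#' @param reads_per_umi Sequencing duplicates per molecule.
#' @param error_rate Per-base substitution probability on both reads.
#' @param contamination_rate Probability that a read's well (z) barcode
#'   is swapped for another well's barcode.
#' @param intron_fraction Fraction of molecules drawn from intronic
#'   transcript regions.
#' @param read1_len Read 1 length in nt.
#' @param barcodes_per_well z-barcodes per well (default 4).
#' @param legend_min_hamming Minimal pairwise Hamming distance within
#'   each legend axis (default 3).
#' @param transcript_len,intron_len Lengths of the toy exonic/intronic
#'   reference sequences.
#' @param nuclei_per_area,nuclei_sigma_um Nuclei count per capture area
#'   and Gaussian blob sigma (um) for image rendering.
#' @param tissue_background,noise_sd Diffuse tissue intensity and
#'   additive pixel noise of rendered images.
#' @param pixel_size_alignment,pixel_size_hires Image resolutions in
#'   um/px (defaults 0.49 and 0.24).
#' @param rotation_alignment_deg,rotation_hires_deg True rotations of
#'   the rendered images relative to the spot grid.
#' @param render_well Capture area rendered by [render_images()]
#'   (default: the first).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       layout = chip_layout(),
                       read_layout = default_read_layout(),
                       n_genes = 100L,
                       contamination_gene_fraction = 0.1,
                       gene_mean_meanlog = log(0.5),
                       gene_mean_sdlog = 1,
                       background_lambda = 0.2,
                       expression_model = c("poisson", "nb"),
                       nb_size = 2,
                       stripe_row_factors = NULL,
                       stripe_col_factors = NULL,
                       tissue_radius_frac = 0.35,
                       reads_per_umi = 4L,
                       error_rate = 0.005,
                       contamination_rate = 0.07,
                       intron_fraction = 0.1,
                       read1_len = 70L,
                       barcodes_per_well = 4L,
                       legend_min_hamming = 3L,
                       transcript_len = 1000L,
                       intron_len = 500L,
                       nuclei_per_area = 250L,
                       nuclei_sigma_um = 3,
                       tissue_background = 0.15,
                       noise_sd = 0.02,
                       pixel_size_alignment = 0.49,
                       pixel_size_hires = 0.24,
                       rotation_alignment_deg = 2,
                       rotation_hires_deg = 5,
                       render_well = NULL) {
  expression_model <- match.arg(expression_model)
  stopifnot(inherits(layout, "chip_layout"), inherits(read_layout, "read_layout"))
  rates <- c(contamination_gene_fraction, error_rate, contamination_rate,
             intron_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (is.null(render_well)) render_well <- layout$section_origins$well_id[1]
  for (f in list(stripe_row_factors, stripe_col_factors))
    if (!is.null(f) && length(f) != layout$n_channels)
      stop("stripe factors need one value per channel", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, %d genes, %d-channel chip, %s counts\n",
              x$seed, x$n_genes, x$layout$n_channels, x$expression_model))
  cat(sprintf("  reads/UMI %d, error %.3g, z-contamination %.3g\n",
              x$reads_per_umi, x$error_rate, x$contamination_rate))
  invisible(x)
}

# Greedy rejection sampling of n barcodes with pairwise Hamming >= d.
.sample_barcodes <- function(n, len, min_hamming, max_tries = 2000L) {
  if (4^len < n) stop("infeasible barcode constraints", call. = FALSE)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- .random_dna(1L, len)
    ok <- length(out) == 0L ||
      min(hamming_distances(cand, out)) >= min_hamming
    if (ok) out <- c(out, cand)
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop("infeasible barcode constraints: could not reach ", n,
           " barcodes at min Hamming ", min_hamming, call. = FALSE)
  }
  out
}

#' Generate a barcode legend with guaranteed pairwise separation
#'
#' Rejection-samples barcode sets so that, within each axis, every pair
#' of sequences differs at `min_hamming` or more positions; this is what
#' makes single-mismatch correction unambiguous. Wells receive
#' `barcodes_per_well` z-barcodes each (reverse-transcription primer
#' sets).
#'
#' @param n_x,n_y Number of x/y barcodes.
#' @param wells Character vector of well identifiers (or `NULL` for no z
#'   axis).
#' @param barcodes_per_well z-barcodes per well (default 4).
#' @param barcode_len Barcode length in nt (default 8).
#' @param min_hamming Minimal pairwise distance within an axis
#'   (default 3).
#' @param x_indices,y_indices Channel indices assigned to the barcodes
#'   (default `0 ... n-1`); pass `barcoded_channels(layout)` to skip
#'   alignment channels.
#' @param seed RNG seed (`NULL` = current stream).
#' @return A [barcode_legend()].
#' @export
make_legend <- function(n_x = 36L, n_y = 36L,
                        wells = paste0(rep(LETTERS[1:3], each = 3), 1:3),
                        barcodes_per_well = 4L, barcode_len = 8L,
                        min_hamming = 3L,
                        x_indices = seq_len(n_x) - 1L,
                        y_indices = seq_len(n_y) - 1L,
                        seed = NULL) {
  stopifnot(length(x_indices) == n_x, length(y_indices) == n_y)
  .with_seed(seed, {
    xb <- .sample_barcodes(n_x, barcode_len, min_hamming)
    yb <- .sample_barcodes(n_y, barcode_len, min_hamming)
    zb <- if (!is.null(wells))
      .sample_barcodes(length(wells) * barcodes_per_well, barcode_len,
                       min_hamming)
    barcode_legend(
      stats::setNames(as.integer(x_indices), xb),
      stats::setNames(as.integer(y_indices), yb),
      if (!is.null(wells))
        stats::setNames(rep(wells, each = barcodes_per_well), zb)
    )
  })
}

#' Generate a toy transcript reference
#'
#' Random sequences, one exonic transcript per gene plus (optionally) an
#' intronic block, named `gene|transcript|region` as required by
#' [assign_gene()]. A generated reference keeps all tests hermetic; it
#' is synthetic and resembles no real genome.
#'
#' @param n_genes Number of genes.
#' @param transcript_len,intron_len Sequence lengths (nt); `intron_len =
#'   0` omits intronic records.
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
simulate_reference <- function(n_genes, transcript_len = 1000L,
                               intron_len = 500L, seed = NULL) {
  .with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    tx <- .random_dna(n_genes, transcript_len)
    names(tx) <- paste0(genes, "|tx1|exonic")
    if (intron_len > 0L) {
      intr <- .random_dna(n_genes, intron_len)
      names(intr) <- paste0(genes, "|int1|intronic")
      tx <- c(tx, intr)
    }
    tx
  })
}

# Tissue disc (centre + radius, global um) of one capture area.
.tissue_disc <- function(layout, well_id, radius_frac) {
  i <- match(well_id, layout$section_origins$well_id)
  side <- (layout$n_channels - 1L) * layout$pitch + layout$channel_width
  list(center = c(layout$section_origins$x0[i] + side / 2,
                  layout$section_origins$y0[i] + side / 2),
       radius = radius_frac * side)
}

#' Simulate ground-truth spot counts
#'
#' Tissue spots (inside a central disc per capture area) draw per-gene
#' counts from the gene's tissue mean plus the ambient background mean;
#' background spots draw from the ambient mean only. Optional stripe
#' factors multiply the expected counts of whole rows/columns,
#' emulating unequal channel flow. Only barcoded spots receive counts.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default: derived from `config$seed`).
#' @return List of class `sim_truth`: `counts` ([spot_counts()], with
#'   metadata column `tissue_truth`), `gene_info` (data frame `gene`,
#'   `tissue_mean`, `is_contamination`), `grid`.
#' @export
simulate_truth_counts <- function(config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  grid <- build_spot_grid(layout)
  sp <- grid$spots[grid$spots$is_barcoded, , drop = FALSE]

  tissue <- rep(FALSE, nrow(sp))
  for (w in layout$section_origins$well_id) {
    disc <- .tissue_disc(layout, w, config$tissue_radius_frac)
    in_w <- sp$well_id == w
    tissue[in_w] <- (sp$x_um[in_w] - disc$center[1])^2 +
      (sp$y_um[in_w] - disc$center[2])^2 <= disc$radius^2
  }

  .with_seed(seed, {
    n_cont <- round(config$contamination_gene_fraction * config$n_genes)
    genes <- sprintf("gene%03d", seq_len(config$n_genes))
    is_cont <- seq_len(config$n_genes) <= n_cont
    mu_tissue <- ifelse(is_cont, 0,
                        stats::rlnorm(config$n_genes,
                                      config$gene_mean_meanlog,
                                      config$gene_mean_sdlog))
    rf <- config$stripe_row_factors %||% rep(1, layout$n_channels)
    cf <- config$stripe_col_factors %||% rep(1, layout$n_channels)
    spot_factor <- rf[sp$y_idx + 1L] * cf[sp$x_idx + 1L]
    # expected counts: genes x spots
    mu <- (outer(mu_tissue, as.numeric(tissue)) + config$background_lambda) *
      matrix(spot_factor, config$n_genes, nrow(sp), byrow = TRUE)
    n <- length(mu)
    counts <- if (config$expression_model == "poisson")
      stats::rpois(n, mu) else stats::rnbinom(n, size = config$nb_size, mu = mu)
    m <- matrix(counts, config$n_genes, nrow(sp),
                dimnames = list(genes, sp$spot_id))
    meta <- sp
    meta$tissue_truth <- tissue
    meta$total_reads <- NA_integer_
    meta$total_umis <- as.numeric(colSums(m))
    meta$n_genes <- as.integer(colSums(m > 0))
    structure(list(counts = spot_counts(m, meta),
                   gene_info = data.frame(gene = genes,
                                          tissue_mean = mu_tissue,
                                          is_contamination = is_cont),
                   grid = grid),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:\n")
  print(x$counts)
  cat(sprintf("  tissue spots: %d, contamination genes: %d\n",
              sum(x$counts$spots$tissue_truth),
              sum(x$gene_info$is_contamination)))
  invisible(x)
}

# k random UMIs with pairwise Hamming >= 2, so that truth molecules stay
# identifiable under Hamming-1 collapse.
.umis_separated <- function(k, len) {
  u <- .random_dna(k, len)
  if (k > 1L) repeat {
    d <- hamming_distances(u, u)
    diag(d) <- Inf
    conflict <- which(apply(d, 1L, min) < 2L)
    if (length(conflict) == 0L) break
    u[conflict[-1L]] <- .random_dna(length(conflict) - 1L, len)
  }
  u
}

# Inject substitution errors at per-base rate; returns modified reads.
.add_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1])
  n <- length(reads)
  n_err <- stats::rbinom(1L, n * L, rate)
  if (n_err == 0L) return(reads)
  flat <- sample.int(n * L, n_err)
  ri <- (flat - 1L) %/% L + 1L
  pos <- (flat - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  for (e in seq_len(n_err)) {
    old <- substr(reads[ri[e]], pos[e], pos[e])
    substr(reads[ri[e]], pos[e], pos[e]) <-
      sample(setdiff(bases, old), 1L)
  }
  reads
}

#' Simulate paired sequencing reads from ground-truth counts
#'
#' Every truth count becomes one molecule with a UMI (pairwise Hamming
#' >= 2 within each spot/gene group) sequenced `reads_per_umi` times.
#' Read 2 is assembled segment-by-segment per the read layout from the
#' legend's barcode sequences, fixed linkers and the UMI; read 1 is a
#' random substring of the gene's (exonic or intronic) reference
#' sequence. Per-base substitution errors and well-barcode swaps
#' (cross-contamination) are applied per read at the configured rates;
#' the truth table records every read's intended spot, gene, UMI and
#' contamination status.
#'
#' @param truth A [simulate_truth_counts()] result.
#' @param config The [sim_config()].
#' @param legend Optional [barcode_legend()] (default: generated from
#'   the config seed with indices on the barcoded channels).
#' @param reference Optional reference (default: generated from the
#'   config).
#' @param seed RNG seed (default derived from `config$seed`).
#' @return List of class `sim_reads`: `r1`, `r2` (named character
#'   vectors), `reads` (truth table), `legend`, `reference`, `linkers`.
#' @export
simulate_reads <- function(truth, config, legend = NULL, reference = NULL,
                           seed = config$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  layout <- config$layout
  bc <- barcoded_channels(layout)
  if (is.null(legend))
    legend <- make_legend(
      n_x = length(bc), n_y = length(bc),
      wells = layout$section_origins$well_id,
      barcodes_per_well = config$barcodes_per_well,
      barcode_len = .layout_segment(config$read_layout, "x_barcode")$length,
      min_hamming = config$legend_min_hamming,
      x_indices = bc, y_indices = bc,
      seed = config$seed
    )
  if (is.null(reference))
    reference <- simulate_reference(config$n_genes, config$transcript_len,
                                    if (config$intron_fraction > 0)
                                      config$intron_len else 0L,
                                    seed = config$seed)
  rl <- config$read_layout
  umi_len <- .layout_segment(rl, "umi")$length
  has_z <- .layout_has_z(rl)

  m <- truth$counts$counts
  sp <- truth$counts$spots
  nz <- Matrix::summary(m)           # i = gene, j = spot, x = count

  ref_names <- strsplit(names(reference), "|", fixed = TRUE)
  ref_gene <- vapply(ref_names, `[`, "", 1L)
  ref_region <- vapply(ref_names, `[`, "", 3L)

  .with_seed(seed, {
    # one row per molecule
    mol_gene <- rep(rownames(m)[nz$i], nz$x)
    mol_spot <- rep(nz$j, nz$x)
    n_mol <- length(mol_gene)
    # UMIs per (spot, gene) group with pairwise separation
    grp <- paste0(mol_spot, "_", mol_gene)
    umi <- character(n_mol)
    for (g in split(seq_len(n_mol), grp))
      umi[g] <- .umis_separated(length(g), umi_len)

    # read 1 source: exonic or intronic record of the molecule's gene
    region <- ifelse(stats::runif(n_mol) < config$intron_fraction &
                       any(ref_region == "intronic"), "intronic", "exonic")
    ref_idx <- match(paste0(mol_gene, ".", region),
                     paste0(ref_gene, ".", ref_region))
    # genes lacking an intron record fall back to the exonic one
    miss <- is.na(ref_idx)
    if (any(miss)) {
      region[miss] <- "exonic"
      ref_idx[miss] <- match(paste0(mol_gene[miss], ".exonic"),
                             paste0(ref_gene, ".", ref_region))
    }
    src_len <- nchar(reference)[ref_idx]
    start <- 1L + floor(stats::runif(n_mol) * (src_len - config$read1_len + 1L))
    mol_r1 <- substr(reference[ref_idx], start, start + config$read1_len - 1L)

    # expand molecules to reads
    d <- config$reads_per_umi
    idx <- rep(seq_len(n_mol), each = d)
    n_reads <- length(idx)
    spot <- sp[mol_spot[idx], ]
    wells <- layout$section_origins$well_id

    # z-barcode per read: own well's set, swapped on contamination
    z_seq <- rep(NA_character_, n_reads)
    contaminated <- rep(FALSE, n_reads)
    z_well <- spot$well_id
    if (has_z && !is.null(legend$z)) {
      n_w <- length(wells)
      wi <- match(spot$well_id, wells)
      contaminated <- stats::runif(n_reads) < config$contamination_rate &
        n_w > 1L
      # contaminating well: uniform over the other wells
      oi <- ceiling(stats::runif(n_reads) * (n_w - 1L))
      oi <- ifelse(oi >= wi, oi + 1L, oi)
      zwi <- ifelse(contaminated, oi, wi)
      z_well <- wells[zwi]
      zs <- split(legend$z$sequence, legend$z$well)[wells]
      nb <- lengths(zs)
      flat <- unlist(zs, use.names = FALSE)
      off <- cumsum(c(0L, nb))[zwi]
      z_seq <- flat[off + ceiling(stats::runif(n_reads) * nb[zwi])]
    }
    x_seq <- legend$x$sequence[match(spot$x_idx, legend$x$index)]
    y_seq <- legend$y$sequence[match(spot$y_idx, legend$y$index)]

    # fixed linker/ignore filler sequences per segment
    segs <- rl$segments
    linkers <- lapply(seq_len(nrow(segs)), function(i)
      if (segs$role[i] %in% c("linker", "ignore"))
        .random_dna(1L, segs$length[i]) else NULL)

    parts <- lapply(seq_len(nrow(segs)), function(i) {
      switch(segs$role[i],
             umi = umi[idx],
             x_barcode = x_seq,
             y_barcode = y_seq,
             z_barcode = z_seq,
             rep(linkers[[i]], n_reads))
    })
    r2 <- do.call(paste0, parts)
    r1 <- mol_r1[idx]
    r1 <- .add_errors(r1, config$error_rate)
    r2 <- .add_errors(r2, config$error_rate)

    ids <- sprintf("read_%07d", seq_len(n_reads))
    names(r1) <- names(r2) <- ids
    reads <- data.table::data.table(
      read_id = ids,
      library = spot$well_id,
      well_id = spot$well_id,
      x_idx = spot$x_idx,
      y_idx = spot$y_idx,
      gene = mol_gene[idx],
      umi = umi[idx],
      region = region[idx],
      z_well = z_well,
      contaminated = contaminated
    )
    structure(list(r1 = r1, r2 = r2, reads = reads, legend = legend,
                   reference = reference,
                   linkers = Filter(Negate(is.null), linkers)),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d paired reads, %d genes, %.2f%% contaminated\n",
              length(x$r1), length(unique(x$reads$gene)),
              100 * mean(x$reads$contaminated)))
  invisible(x)
}

#' Write sequences as FASTQ (constant quality)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; a `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(Biostrings::width(ss), function(w)
    paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Render synthetic alignment and high-resolution images
#'
#' Builds a micrometre-level scene for one capture area — nuclei at
#' random positions inside the tissue disc plus the alignment-mark frame
#' along the outermost channels — and rasterizes it twice under two true
#' similarity transforms: the alignment image (default 0.49 um/px) with
#' nuclei and marker channels, and the high-resolution image (default
#' 0.24 um/px) with the nuclei channel only. The truth transforms are
#' returned, so registration results can be scored exactly.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default derived from `config$seed`).
#' @return List of class `sim_images`: `alignment` (`nuclei`, `marker`
#'   matrices, `pixel_size`), `hires` (`nuclei`, `pixel_size`),
#'   `transforms` (`grid_to_alignment`, `grid_to_hires`,
#'   `alignment_to_hires`, global um -> px), `nuclei_um`, `well_id`.
#' @export
render_images <- function(config, seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  well <- config$render_well
  i <- match(well, layout$section_origins$well_id)
  origin <- c(layout$section_origins$x0[i], layout$section_origins$y0[i])
  W <- (layout$n_channels - 1L) * layout$pitch + layout$channel_width
  disc <- .tissue_disc(layout, well, config$tissue_radius_frac)

  .with_seed(seed, {
    # nuclei positions: uniform in the tissue disc (global um)
    n <- config$nuclei_per_area
    rr <- disc$radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    nuc <- cbind(disc$center[1] + rr * cos(th), disc$center[2] + rr * sin(th))

    mk_transform <- function(pixel_size, rot_deg, margin_px = 20) {
      tf0 <- compose_affine(
        affine_similarity(scale = 1 / pixel_size, angle_deg = rot_deg),
        affine_translation(-origin[1], -origin[2]))
      corners <- apply_affine(tf0, cbind(c(0, W, W, 0), c(0, 0, W, W)))
      shift <- margin_px - apply(corners, 2L, min)
      tf <- compose_affine(affine_translation(shift[1], shift[2]), tf0)
      dim_px <- ceiling(apply(apply_affine(
        tf, cbind(c(0, W, W, 0), c(0, 0, W, W))), 2L, max) + margin_px)
      list(tf = tf, dim = as.integer(dim_px))
    }
    al <- mk_transform(config$pixel_size_alignment,
                       config$rotation_alignment_deg)
    hi <- mk_transform(config$pixel_size_hires, config$rotation_hires_deg)

    render <- function(tfd, pixel_size, marker) {
      nx <- tfd$dim[1]; ny <- tfd$dim[2]
      inv <- invert_affine(tfd$tf)
      img <- matrix(0, nx, ny)
      # per-pixel um coordinates, column blocks to bound memory
      block <- max(1L, floor(2e6 / nx))
      for (j0 in seq(1L, ny, by = block)) {
        j1 <- min(ny, j0 + block - 1L)
        px <- cbind(rep(seq_len(nx) - 0.5, times = j1 - j0 + 1L),
                    rep(seq(j0, j1) - 0.5, each = nx))
        um <- apply_affine(inv, px)
        lx <- um[, 1] - origin[1]; ly <- um[, 2] - origin[2]
        if (marker) {
          val <- as.numeric(
            lx >= 0 & lx <= W & ly >= 0 & ly <= W &
              (lx <= layout$channel_width | lx >= W - layout$channel_width |
                 ly <= layout$channel_width | ly >= W - layout$channel_width))
        } else {
          val <- config$tissue_background *
            ((um[, 1] - disc$center[1])^2 + (um[, 2] - disc$center[2])^2 <=
               disc$radius^2)
        }
        img[, j0:j1] <- val
      }
      if (!marker) {
        # nuclei as Gaussian blobs
        ctr <- apply_affine(tfd$tf, nuc)
        sg <- config$nuclei_sigma_um / pixel_size
        hw <- ceiling(4 * sg)
        for (k in seq_len(nrow(ctr))) {
          xi <- max(1L, floor(ctr[k, 1] - hw)):min(nx, ceiling(ctr[k, 1] + hw))
          yi <- max(1L, floor(ctr[k, 2] - hw)):min(ny, ceiling(ctr[k, 2] + hw))
          if (!length(xi) || !length(yi)) next
          gx <- exp(-((xi - 0.5) - ctr[k, 1])^2 / (2 * sg^2))
          gy <- exp(-((yi - 0.5) - ctr[k, 2])^2 / (2 * sg^2))
          img[xi, yi] <- img[xi, yi] + outer(gx, gy)
        }
      }
      if (config$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nx * ny, 0, config$noise_sd), nx, ny)
      pmin(pmax(img, 0), 2)
    }

    alignment_nuclei <- render(al, config$pixel_size_alignment, marker = FALSE)
    alignment_marker <- render(al, config$pixel_size_alignment, marker = TRUE)
    hires_nuclei <- render(hi, config$pixel_size_hires, marker = FALSE)

    structure(list(
      alignment = list(nuclei = alignment_nuclei, marker = alignment_marker,
                       pixel_size = config$pixel_size_alignment),
      hires = list(nuclei = hires_nuclei,
                   pixel_size = config$pixel_size_hires),
      transforms = list(
        grid_to_alignment = al$tf,
        grid_to_hires = hi$tf,
        alignment_to_hires = compose_affine(hi$tf, invert_affine(al$tf))),
      nuclei_um = nuc,
      well_id = well
    ), class = "sim_images")
  })
}

#' @export
print.sim_images <- function(x, ...) {
  cat(sprintf(
    "sim_images (%s): alignment %dx%d px @ %.2f um/px, hires %dx%d px @ %.2f um/px\n",
    x$well_id, nrow(x$alignment$nuclei), ncol(x$alignment$nuclei),
    x$alignment$pixel_size, nrow(x$hires$nuclei), ncol(x$hires$nuclei),
    x$hires$pixel_size))
  invisible(x)
}

#' Write a full synthetic run to disk
#'
#' FASTQ pair (gzipped), legend CSV, layout YAML, truth tables (TSV),
#' rendered images (TIFF) and truth transforms (JSON).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param images Render and write images too (default TRUE)?
#' @return Invisible list of the generated in-memory objects.
#' @export
simulate_run <- function(config, out_dir, images = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth_counts(config)
  sim <- simulate_reads(truth, config)
  write_fastq(sim$r1, file.path(out_dir, "R1.fastq.gz"))
  write_fastq(sim$r2, file.path(out_dir, "R2.fastq.gz"))
  write_barcode_legend(sim$legend, file.path(out_dir, "legend.csv"))
  write_chip_layout(config$layout, file.path(out_dir, "layout.yaml"))
  data.table::fwrite(sim$reads, file.path(out_dir, "truth_reads.tsv"),
                     sep = "\t")
  write_spot_counts(truth$counts, file.path(out_dir, "truth_counts"))
  ref <- Biostrings::DNAStringSet(sim$reference)
  Biostrings::writeXStringSet(ref, file.path(out_dir, "reference.fasta"))
  img <- NULL
  if (images) {
    img <- render_images(config)
    EBImage::writeImage(EBImage::Image(img$alignment$nuclei / 2),
                        file.path(out_dir, "alignment_nuclei.tiff"))
    EBImage::writeImage(EBImage::Image(img$alignment$marker / 2),
                        file.path(out_dir, "alignment_marker.tiff"))
    EBImage::writeImage(EBImage::Image(img$hires$nuclei / 2),
                        file.path(out_dir, "hires_nuclei.tiff"))
    for (nm in names(img$transforms))
      write_affine_json(img$transforms[[nm]],
                        file.path(out_dir, paste0(nm, ".json")))
  }
  invisible(list(truth = truth, reads = sim, images = img))
}
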