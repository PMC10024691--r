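#' Extract UMI and barcode fields from read 2 sequences
#'
#' Pure substring extraction at the positions given by the read layout;
#' no error correction happens here. Reads shorter than the layout's
#' minimum length are flagged and yield `NA` fields.
#'
#' @param read2 Character vector of read 2 sequences.
#' @param layout A [read_layout()].
#' @param read_id Optional read identifiers (default `read_1 ... read_n`).
#' @return A `data.table` with columns `read_id`, `umi`, `x_seq`,
#'   `y_seq`, `z_seq` (`NA` if the layout has no z segment) and `short`
#'   (logical).
#' @export
extract_barcodes <- function(read2, layout, read_id = NULL) {
  stopifnot(inherits(layout, "read_layout"))
  read2 <- toupper(as.character(read2))
  if (is.null(read_id)) read_id <- paste0("read_", seq_along(read2))
  short <- nchar(read2) < layout$min_read_length
  grab <- function(role) {
    s <- .layout_segment(layout, role)
    if (is.null(s)) return(rep(NA_character_, length(read2)))
    out <- substr(read2, s$start + 1L, s$start + s$length)
    out[short] <- NA_character_
    out
  }
  data.table::data.table(
    read_id = read_id,
    umi = grab("umi"),
    x_seq = grab("x_barcode"),
    y_seq = grab("y_barcode"),
    z_seq = grab("z_barcode"),
    short = short
  )
}

# Match observed sequences against one legend axis by minimum Hamming
# distance. Returns an integer vector of row indices into `ref` (NA for no
# unique match within max_hamming). Ambiguity = tie at the minimal distance.
.match_axis <- function(seqs, ref, max_hamming) {
  out <- rep(NA_integer_, length(seqs))
  ok <- !is.na(seqs) & nchar(seqs) == nchar(ref[1]) & .is_dna(seqs)
  if (!any(ok)) return(out)
  u <- unique(seqs[ok])
  # exact matches resolve without a distance scan
  hit <- match(u, ref)
  need <- which(is.na(hit))
  if (length(need) && max_hamming > 0L) {
    d <- hamming_distances(u[need], ref)
    dmin <- apply(d, 1L, min)
    n_at_min <- rowSums(d == dmin)
    best <- apply(d, 1L, which.min)
    acc <- dmin <= max_hamming & n_at_min == 1L
    hit[need[acc]] <- best[acc]
  }
  out[ok] <- hit[match(seqs[ok], u)]
  out
}

#' Correct barcodes against a legend and assign spot coordinates
#'
#' Each extracted barcode is matched to the unique legend entry within
#' `max_hamming` mismatches (Hamming distance; ties at the minimal
#' distance are discarded as ambiguous). A read is `valid` only if the x
#' and y barcodes resolve, and the z barcode too when the layout defines
#' one. Reads failing an axis get status `invalid_x` / `invalid_y` /
#' `invalid_z` (first failing axis in that order); short reads keep
#' status `short`.
#'
#' @param fields Output of [extract_barcodes()].
#' @param legend A [barcode_legend()].
#' @param max_hamming Maximum mismatches tolerated per barcode
#'   (default 1).
#' @return A `data.table` with columns `read_id`, `umi`, `x_idx`,
#'   `y_idx`, `well_id`, `status`.
#' @export
correct_and_assign <- function(fields, legend, max_hamming = 1L) {
  stopifnot(inherits(legend, "barcode_legend"), max_hamming >= 0L)
  fields <- data.table::as.data.table(fields)
  use_z <- !is.null(legend$z) && any(!is.na(fields$z_seq))

  xi <- .match_axis(fields$x_seq, legend$x$sequence, max_hamming)
  yi <- .match_axis(fields$y_seq, legend$y$sequence, max_hamming)
  zi <- if (use_z) .match_axis(fields$z_seq, legend$z$sequence, max_hamming)
        else rep(NA_integer_, nrow(fields))

  status <- rep("valid", nrow(fields))
  if (use_z) status[is.na(zi)] <- "invalid_z"
  status[is.na(yi)] <- "invalid_y"
  status[is.na(xi)] <- "invalid_x"
  status[fields$short] <- "short"

  data.table::data.table(
    read_id = fields$read_id,
    umi = fields$umi,
    x_idx = legend$x$index[xi],
    y_idx = legend$y$index[yi],
    well_id = if (use_z) legend$z$well[zi] else NA_character_,
    status = status
  )
}

#' Drop reads whose well barcode disagrees with their library
#'
#' When samples are barcoded twice (well barcode during reverse
#' transcription, library index during library preparation), a read
#' sequenced in library L but carrying another well's z-barcode is a
#' cross-contamination event. Valid reads whose resolved well is not in
#' the library's allowed set are re-flagged with status `crosstalk`.
#' Without a z axis the filter is a pass-through.
#'
#' @param assignments Output of [correct_and_assign()].
#' @param library_id Library identifier per read (scalar or vector).
#' @param expected_wells Named list mapping library identifier to the
#'   character vector of allowed well ids. `NULL` disables the filter.
#' @return The assignments with updated `status` and a `library` column.
#' @export
filter_crosstalk <- function(assignments, library_id, expected_wells = NULL) {
  a <- data.table::as.data.table(assignments)
  a$library <- rep_len(library_id, nrow(a))
  if (is.null(expected_wells) || all(is.na(a$well_id))) return(a)
  unknown <- setdiff(unique(a$library), names(expected_wells))
  if (length(unknown))
    stop("no expected wells for library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad <- a$status == "valid" &
    !mapply(function(w, l) w %in% expected_wells[[l]], a$well_id, a$library)
  a$status[bad] <- "crosstalk"
  a
}

#' Assign reads to genes by unique exact prefix match
#'
#' A lightweight stand-in for genome alignment suitable for toy
#' transcript references: the first `min_prefix` nucleotides of read 1
#' must match exactly one reference transcript; zero or multiple matching
#' transcripts leave the read unassigned. Reference names follow
#' `gene|transcript|region` with region `exonic` or `intronic`.
#'
#' @param read1 Character vector or `DNAStringSet` of read 1 sequences.
#' @param reference Named character vector or `DNAStringSet` of
#'   transcript sequences; names as `gene|transcript|region`.
#' @param min_prefix Prefix length used for matching (default 30 nt).
#' @return A `data.table` with columns `gene`, `region`
#'   (`exonic`/`intronic`) and `assigned` (logical).
#' @export
assign_gene <- function(read1, reference, min_prefix = 30L) {
  if (length(reference) == 0L) stop("empty reference", call. = FALSE)
  ref <- if (inherits(reference, "DNAStringSet")) reference
         else Biostrings::DNAStringSet(
           stats::setNames(toupper(as.character(reference)), names(reference)))
  if (any(Biostrings::width(ref) < min_prefix))
    stop("all reference sequences must be >= min_prefix nt", call. = FALSE)
  meta <- strsplit(names(ref), "|", fixed = TRUE)
  if (any(lengths(meta) != 3L))
    stop("reference names must be gene|transcript|region", call. = FALSE)
  genes <- vapply(meta, `[`, "", 1L)
  regions <- vapply(meta, `[`, "", 3L)

  read1 <- toupper(as.character(read1))
  n <- length(read1)
  out <- data.table::data.table(gene = rep(NA_character_, n),
                                region = rep(NA_character_, n),
                                assigned = rep(FALSE, n))
  prefix <- substr(read1, 1L, min_prefix)
  ok <- nchar(read1) >= min_prefix & .is_dna(prefix)
  if (!any(ok)) return(out)
  u <- unique(prefix[ok])
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(u))
  hits <- Biostrings::vcountPDict(pd, ref)  # |u| x |ref|
  n_tx <- rowSums(hits > 0L)
  which_tx <- max.col(hits > 0L, ties.method = "first")
  uniq <- n_tx == 1L
  gene_u <- ifelse(uniq, genes[which_tx], NA_character_)
  region_u <- ifelse(uniq, regions[which_tx], NA_character_)
  m <- match(prefix[ok], u)
  out$gene[ok] <- gene_u[m]
  out$region[ok] <- region_u[m]
  out$assigned <- !is.na(out$gene)
  out
}

#' Process paired FASTQ reads into a spot-by-gene count matrix
#'
#' The full demultiplexing stage: extract UMI/barcodes from read 2,
#' Hamming-correct against the legend, optionally drop well/library
#' cross-contamination, assign genes from read 1 (or take a pre-tagged
#' read table), and collapse UMIs into counts.
#'
#' @param r1,r2 FASTQ file paths (plain or gzip), or character vectors /
#'   `DNAStringSet`s of sequences. `r1` may be `NULL` when `tagged_reads`
#'   is supplied.
#' @param legend A [barcode_legend()].
#' @param layout A [read_layout()] describing read 2.
#' @param reference Toy transcript reference for [assign_gene()], or
#'   `NULL` when `tagged_reads` is given or `spatial_only = TRUE`.
#' @param tagged_reads Optional data frame `read_id`, `gene`, `region`
#'   from an external aligner, replacing `reference`.
#' @param grid Optional [build_spot_grid()] used to attach micrometre
#'   coordinates to spots.
#' @param library_id Library identifier for this run (default "lib1").
#' @param expected_wells Passed to [filter_crosstalk()].
#' @param max_hamming Barcode correction radius (default 1).
#' @param min_prefix Gene-assignment prefix length (default 30).
#' @param include_intronic Count intronic-region reads (default TRUE)?
#' @param spatial_only Skip gene assignment and counting; return barcode
#'   assignments only (used for cross-contamination quantification).
#' @return A list of class `reads_to_counts`:
#'   `counts` ([spot_counts()]), `reads` (the tagged per-read table kept
#'   for saturation analysis), `metrics` (status tallies and per-spot
#'   summaries).
#' @export
reads_to_counts <- function(r1, r2, legend, layout = default_read_layout(),
                            reference = NULL, tagged_reads = NULL,
                            grid = NULL, library_id = "lib1",
                            expected_wells = NULL, max_hamming = 1L,
                            min_prefix = 30L, include_intronic = TRUE,
                            spatial_only = FALSE) {
  r2_seq <- .read_sequences(r2)
  fields <- extract_barcodes(r2_seq$seq, layout, read_id = r2_seq$id)
  assign <- correct_and_assign(fields, legend, max_hamming = max_hamming)
  assign <- filter_crosstalk(assign, library_id, expected_wells)

  if (spatial_only) {
    metrics <- list(status_counts = as.list(table(assign$status)),
                    n_reads = nrow(assign))
    return(structure(list(counts = NULL, reads = assign, metrics = metrics),
                     class = "reads_to_counts"))
  }

  if (!is.null(tagged_reads)) {
    tg <- data.table::as.data.table(tagged_reads)
    stopifnot(all(c("read_id", "gene", "region") %in% names(tg)))
    m <- match(assign$read_id, tg$read_id)
    assign$gene <- tg$gene[m]
    assign$region <- tg$region[m]
  } else {
    if (is.null(r1) || is.null(reference))
      stop("need r1 + reference, or tagged_reads", call. = FALSE)
    r1_seq <- .read_sequences(r1)
    ga <- assign_gene(r1_seq$seq, reference, min_prefix = min_prefix)
    assign$gene <- ga$gene
    assign$region <- ga$region
  }

  counts <- digital_expression(assign, grid = grid,
                               include_intronic = include_intronic)
  metrics <- rna_metrics(assign, counts)
  structure(list(counts = counts, reads = assign, metrics = metrics),
            class = "reads_to_counts")
}

#' @export
print.reads_to_counts <- function(x, ...) {
  cat("reads_to_counts result\n")
  st <- x$metrics$status_counts
  cat(sprintf("  reads: %d (%s)\n", x$metrics$n_reads,
              paste(sprintf("%s=%d", names(st), unlist(st)), collapse = ", ")))
  if (!is.null(x$counts)) print(x$counts)
  invisible(x)
}

# Accept a file path, character vector or DNAStringSet; return list(id, seq).
.read_sequences <- function(x) {
  if (inherits(x, "DNAStringSet"))
    return(list(id = names(x) %||% paste0("read_", seq_along(x)),
                seq = as.character(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x, format = "fastq")
    ids <- sub("\\s.*$", "", names(ss))
    return(list(id = ids, seq = unname(as.character(ss))))
  }
  list(id = names(x) %||% paste0("read_", seq_along(x)),
       seq = unname(as.character(x)))
}
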