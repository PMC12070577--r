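#' Read a per-read poly(A) summary table
#'
#' Parses the whitespace- or tab-delimited summary produced by extracting the
#' poly(A) tag from a basecalled BAM (columns: read id, read length, poly(A)
#' tail length; optional header). Tail-length values below 1 nt mean "not
#' estimated" and are stored as missing; the number of such sub-threshold
#' reads is recorded in the `sub_threshold` attribute.
#'
#' @param path Path to the summary file.
#' @param sample_id Sample identifier to stamp on every read.
#' @param metadata Optional sample metadata tibble with columns `sample_id`,
#'   `batch`, `condition` (see [read_sample_metadata()]); used to fill the
#'   batch and condition fields for `sample_id`.
#' @param batch,condition Used when `metadata` is not supplied.
#' @return A tibble of read records (`read_id`, `sample_id`, `batch`,
#'   `condition`, `gene_id` (NA), `read_length`, `polya_length`).
#' @export
read_polya_table <- function(path, sample_id = "sample1", metadata = NULL,
                             batch = "batch1", condition = "bacterial") {
  if (!file.exists(path)) {
    stop_polyatails(sprintf("cannot read poly(A) table '%s'.", path),
                    "polyatails_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop_polyatails("poly(A) table is empty.", "polyatails_io_error")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad_ncol <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad_ncol) > 0) {
    stop_polyatails(
      sprintf("line %d has fewer than 3 columns.", bad_ncol[1]),
      "polyatails_parse_error"
    )
  }
  # Optional single header line: both numeric columns non-numeric.
  first <- fields[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2]))) &&
    is.na(suppressWarnings(as.numeric(first[3])))
  data_idx <- if (has_header) seq_along(fields)[-1] else seq_along(fields)
  if (length(data_idx) == 0) {
    stop_polyatails("poly(A) table has a header but no data lines.",
                    "polyatails_io_error")
  }
  read_id <- vapply(fields[data_idx], `[[`, "", 1L)
  read_length <- suppressWarnings(as.numeric(vapply(fields[data_idx], `[[`, "", 2L)))
  polya <- suppressWarnings(as.numeric(vapply(fields[data_idx], `[[`, "", 3L)))
  bad <- which(is.na(read_length) | is.na(polya))
  if (length(bad) > 0) {
    stop_polyatails(
      sprintf("non-numeric length field on line %d.", data_idx[bad[1]]),
      "polyatails_parse_error"
    )
  }
  sub_thr <- sum(polya < 1)
  polya[polya < 1] <- NA_real_

  if (!is.null(metadata)) {
    row <- metadata[metadata$sample_id == sample_id, , drop = FALSE]
    if (nrow(row) != 1) {
      stop_polyatails(
        sprintf("sample '%s' not found (exactly once) in metadata.", sample_id),
        "polyatails_config_error"
      )
    }
    batch <- as.character(row$batch)
    condition <- as.character(row$condition)
  }
  out <- tibble(
    read_id = read_id,
    sample_id = sample_id,
    batch = batch,
    condition = as.character(condition_factor(condition)),
    gene_id = NA_character_,
    read_length = as.integer(round(read_length)),
    polya_length = polya
  )
  attr(out, "sub_threshold") <- sub_thr
  out
}

#' Read per-read poly(A) tail lengths from a tagged BAM
#'
#' Extracts the integer poly(A)-tail auxiliary tag written by the basecaller
#' (default tag `pt`) from primary alignments. Reads lacking the tag keep a
#' missing `polya_length`; tag values below 1 nt are treated as missing.
#'
#' @param path Path to an indexed or streamable BAM file.
#' @param tag Auxiliary tag carrying the integer tail length (default `"pt"`).
#' @param gene_map Gene assignment. `NULL`: the alignment reference name is
#'   used as the gene id (transcriptome alignment to gene-named references).
#'   A data frame with columns `transcript_id`, `gene_id`: reference names
#'   are transcript ids mapped to genes. A `GRanges` with a `gene_id`
#'   metadata column: genome alignments assigned by overlap with the
#'   supplied intervals.
#' @inheritParams read_polya_table
#' @return A tibble of read records. The attribute `bam_counts` holds the
#'   number of primary records seen (`total`), the number carrying the tag
#'   (`tagged`) and the number assigned to a gene (`assigned`).
#' @export
read_polya_bam <- function(path, tag = "pt", gene_map = NULL,
                           sample_id = "sample1", metadata = NULL,
                           batch = "batch1", condition = "bacterial") {
  if (!file.exists(path)) {
    stop_polyatails(sprintf("cannot read BAM '%s'.", path), "polyatails_io_error")
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "qwidth"),
    tag = tag
  )
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  tags <- rec$tag[[tag]]
  n <- length(rec$qname)
  if (is.null(tags)) tags <- rep(NA_integer_, n)
  if (!is.null(tags) && !is.numeric(tags)) {
    stop_polyatails(sprintf("tag '%s' is present but not numeric.", tag),
                    "polyatails_parse_error")
  }
  polya <- as.numeric(tags)
  tagged <- sum(!is.na(polya))
  polya[!is.na(polya) & polya < 1] <- NA_real_

  rname <- as.character(rec$rname)
  gene_id <- if (is.null(gene_map)) {
    rname
  } else if (is.data.frame(gene_map)) {
    gene_map$gene_id[match(rname, gene_map$transcript_id)]
  } else if (methods::is(gene_map, "GRanges")) {
    hits_gr <- GenomicRanges::GRanges(
      seqnames = rname,
      ranges = IRanges::IRanges(start = rec$pos, width = pmax(rec$qwidth, 1L))
    )
    ov <- GenomicRanges::findOverlaps(hits_gr, gene_map, select = "first")
    as.character(gene_map$gene_id[ov])
  } else {
    stop_polyatails("gene_map must be NULL, a data frame, or a GRanges.",
                    "polyatails_config_error")
  }

  if (!is.null(metadata)) {
    row <- metadata[metadata$sample_id == sample_id, , drop = FALSE]
    if (nrow(row) != 1) {
      stop_polyatails(
        sprintf("sample '%s' not found (exactly once) in metadata.", sample_id),
        "polyatails_config_error"
      )
    }
    batch <- as.character(row$batch)
    condition <- as.character(row$condition)
  }
  out <- tibble(
    read_id = rec$qname,
    sample_id = sample_id,
    batch = batch,
    condition = as.character(condition_factor(condition)),
    gene_id = gene_id,
    read_length = as.integer(rec$qwidth),
    polya_length = polya
  )
  attr(out, "bam_counts") <- c(total = n, tagged = tagged,
                               assigned = sum(!is.na(gene_id)))
  out
}

#' Read gene models from a GTF/GFF annotation
#'
#' Builds per-gene models: the set of transcripts, the length of the union of
#' exons (computed on a half-open internal representation of the 1-based
#' inclusive GTF coordinates; strand-symmetric), GC fraction over union exons
#' when a genome FASTA is supplied, and a mitochondrial flag for genes on
#' MT/chrM/chrMT.
#'
#' @param gtf_path Path to a GTF/GFF3 file with exon features carrying
#'   `gene_id` (and optionally `transcript_id`) attributes.
#' @param fasta_path Optional genome FASTA; enables `gc_fraction`.
#' @return A tibble with columns `gene_id`, `chromosome`, `transcript_ids`
#'   (list column), `union_exon_length`, `gc_fraction`, `is_mitochondrial`.
#' @export
read_annotation <- function(gtf_path, fasta_path = NULL) {
  if (!file.exists(gtf_path)) {
    stop_polyatails(sprintf("cannot read annotation '%s'.", gtf_path),
                    "polyatails_io_error")
  }
  gr <- tryCatch(
    rtracklayer::import(gtf_path),
    error = function(e) {
      stop_polyatails(sprintf("malformed annotation: %s", conditionMessage(e)),
                      "polyatails_format_error")
    }
  )
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    stop_polyatails("annotation lacks gene_id attributes.",
                    "polyatails_format_error")
  }
  exons <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(exons) == 0) {
    stop_polyatails("annotation contains no exon features.",
                    "polyatails_format_error")
  }
  genes_present <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(genes_present) > 0) {
    txs <- gr[tolower(as.character(gr$type)) == "transcript"]
    unknown <- setdiff(unique(txs$gene_id), unique(genes_present$gene_id))
    if (length(unknown) > 0) {
      stop_polyatails(
        sprintf("transcript(s) reference unknown gene(s): %s",
                paste(unknown, collapse = ", ")),
        "polyatails_format_error"
      )
    }
  }

  by_gene <- S4Vectors::split(exons, exons$gene_id)
  reduced <- GenomicRanges::reduce(by_gene, ignore.strand = TRUE)
  union_len <- sum(GenomicRanges::width(reduced))

  tx_tbl <- tibble(
    gene_id = as.character(exons$gene_id),
    transcript_id = if ("transcript_id" %in% names(S4Vectors::mcols(exons))) {
      as.character(exons$transcript_id)
    } else NA_character_
  )
  tx_by_gene <- tx_tbl |>
    dplyr::filter(!is.na(.data$transcript_id)) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(transcript_ids = list(sort(.data$transcript_id)))
  tx_one_gene <- tx_tbl |>
    dplyr::filter(!is.na(.data$transcript_id)) |>
    dplyr::distinct(.data$transcript_id, .data$gene_id) |>
    dplyr::count(.data$transcript_id)
  if (any(tx_one_gene$n > 1)) {
    stop_polyatails("a transcript_id maps to more than one gene.",
                    "polyatails_format_error")
  }

  chrom <- vapply(
    S4Vectors::split(as.character(GenomicRanges::seqnames(exons)), exons$gene_id),
    function(x) x[[1]], ""
  )
  gene_ids <- names(union_len)

  gc <- rep(NA_real_, length(gene_ids))
  if (!is.null(fasta_path)) {
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    gc <- vapply(seq_along(gene_ids), function(i) {
      rr <- reduced[[i]]
      chr <- chrom[gene_ids[i]]
      if (!chr %in% names(genome)) return(NA_real_)
      seqs <- Biostrings::DNAStringSet(lapply(seq_along(rr), function(j) {
        Biostrings::subseq(genome[[chr]],
                           start = GenomicRanges::start(rr)[j],
                           end = GenomicRanges::end(rr)[j])
      }))
      counts <- colSums(Biostrings::letterFrequency(seqs, c("G", "C")))
      sum(counts) / sum(Biostrings::width(seqs))
    }, numeric(1))
  }

  tibble(
    gene_id = gene_ids,
    chromosome = unname(chrom[gene_ids]),
    union_exon_length = as.integer(unname(union_len[gene_ids])),
    gc_fraction = gc,
    is_mitochondrial = tolower(unname(chrom[gene_ids])) %in% c("mt", "chrm", "chrmt")
  ) |>
    dplyr::left_join(tx_by_gene, by = "gene_id") |>
    dplyr::select("gene_id", "chromosome", "transcript_ids",
                  "union_exon_length", "gc_fraction", "is_mitochondrial")
}

#' Read a feature-by-sample abundance TSV
#'
#' @param path TSV whose first column is the feature id and whose remaining
#'   columns are per-sample abundances.
#' @inheritParams abundance_table
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, unit = c("counts", "CPM", "TPM"),
                           level = c("gene", "transcript"),
                           length_normalized = FALSE) {
  if (!file.exists(path)) {
    stop_polyatails(sprintf("cannot read abundance table '%s'.", path),
                    "polyatails_io_error")
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  abundance_table(tb, unit = match.arg(unit), level = match.arg(level),
                  length_normalized = length_normalized)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' @return A tibble with columns `set_id`, `description`, `genes` (list
#'   column of member gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_polyatails(sprintf("cannot read GMT '%s'.", path), "polyatails_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  empty <- which(vapply(fields, length, 1L) < 3L)
  if (length(empty) > 0) {
    stop_polyatails(sprintf("GMT set on line %d has no members.", empty[1]),
                    "polyatails_format_error")
  }
  tibble(
    set_id = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the sample metadata sidecar
#'
#' Phenotype metadata is not carried by BAM/TSV read files, so samples are
#' described by a TSV sidecar with columns `sample_id`, `batch`, `condition`.
#'
#' @param path TSV path.
#' @return A tibble with `sample_id`, `batch`, `condition`.
#' @export
read_sample_metadata <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "batch", "condition")
  if (!all(needed %in% names(tb))) {
    stop_polyatails("metadata must have columns sample_id, batch, condition.",
                    "polyatails_format_error")
  }
  tb$condition <- as.character(condition_factor(tb$condition))
  tb$sample_id <- as.character(tb$sample_id)
  tb$batch <- as.character(tb$batch)
  if (anyDuplicated(tb$sample_id)) {
    stop_polyatails("duplicate sample ids in metadata.", "polyatails_format_error")
  }
  tb[, needed]
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with a header; numeric values keep full double
#' precision so that a write/read round trip is faithful.
#'
#' @param x A data frame (an `abundance_tbl` keeps its layout).
#' @param path Output path.
#' @export
write_result_table <- function(x, path) {
  x <- as.data.frame(x)
  is_list <- vapply(x, is.list, logical(1))
  x[is_list] <- lapply(x[is_list], function(col) {
    vapply(col, function(v) paste(v, collapse = ";"), "")
  })
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
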