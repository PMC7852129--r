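# Readers and writers for the plain-text formats the pipeline consumes and
# emits. All 1-based formats (GFF3, alignment coords) are converted to the
# package's internal 0-based half-open convention at this boundary; internal
# code never sees 1-based coordinates.

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the sequence name.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a BED file
#'
#' Reads BED3/BED6(+) into a data.table with 0-based half-open coordinates
#' (BED is already in this convention; no shift is applied). Columns beyond
#' the sixth are kept under their supplied names when a header is absent they
#' are named `V7`, `V8`, ...
#'
#' @param path Path to a tab-separated BED file without header.
#' @return data.table with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(df, seq_len(min(ncol(df), 6L)), base[seq_len(min(ncol(df), 6L))])
  iv_check(df)
  df
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any additional columns in `extra_cols`
#' order as a headerless tab-separated BED file.
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @param extra_cols Character vector of additional columns to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, extra_cols = setdiff(names(df), c("chrom", "start", "end"))) {
  iv_check(df)
  out <- data.table::as.data.table(df)[, c("chrom", "start", "end", extra_cols), with = FALSE]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file through [rtracklayer::import()] and converts gene and
#' exon records to internal 0-based half-open coordinates.
#'
#' @param path Path to a GFF3 file.
#' @return data.table with `chrom`, `start`, `end`, `strand`, `type`, `id`,
#'   `parent` (NA for top-level records).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) if (length(p)) as.character(p[1]) else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(md$type),
    id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = parent
  )
}

#' Write gene models to GFF3
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`, `type`,
#'   `id`, `parent` in internal coordinates.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "misasm") {
  iv_check(genes)
  attrs <- ifelse(is.na(genes$parent) | genes$parent == "",
                  paste0("ID=", genes$id),
                  paste0("ID=", genes$id, ";Parent=", genes$parent))
  lines <- paste(genes$chrom, source, genes$type, genes$start + 1L, genes$end,
                 ".", ifelse(is.na(genes$strand), ".", genes$strand), ".", attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a read-placement table
#'
#' The placement table is the package's BAM-equivalent: one row per mapped,
#' deduplicated read with columns `read_id`, `chrom`, `start` (0-based),
#' `length` (bp) and `multimap` (0/1 flag for reads mapping to multiple
#' genomic locations).
#'
#' @param path Path to a tab-separated file with the five columns above
#'   (with header).
#' @return data.table of placements.
#' @export
read_placements <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("read_id", "chrom", "start", "length", "multimap")
  if (!all(need %in% names(df)))
    stop("placement table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a read-placement table
#'
#' @param placements data.table as returned by [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  data.table::fwrite(
    placements[, c("read_id", "chrom", "start", "length", "multimap")],
    path, sep = "\t")
  invisible(path)
}

#' Write per-bin read depth as bedGraph
#'
#' @param bins Bin table with `chrom`, `start`, `end` and the column `value_col`.
#' @param path Output path.
#' @param value_col Which column to emit (default `"rd"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, path, value_col = "rd") {
  out <- data.table::as.data.table(bins)[, c("chrom", "start", "end", value_col), with = FALSE]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write an alignment coords table
#'
#' Emits the MUMmer `show-coords -T`-style layout consumed by
#' [parse_coords()]: tab-separated, no header, columns `S1 E1 S2 E2 LEN1 LEN2
#' %IDY QUERY SUBJECT` with 1-based inclusive coordinates and reverse
#' subject alignments encoded as S2 > E2.
#'
#' @param blocks Alignment block table as returned by
#'   [emit_alignment_coords()] or [parse_coords()] (internal coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(blocks, path) {
  s2 <- ifelse(blocks$orientation == "+", blocks$sstart + 1L, blocks$send)
  e2 <- ifelse(blocks$orientation == "+", blocks$send, blocks$sstart + 1L)
  out <- data.table::data.table(
    S1 = blocks$qstart + 1L, E1 = blocks$qend,
    S2 = s2, E2 = e2,
    LEN1 = blocks$qend - blocks$qstart,
    LEN2 = blocks$send - blocks$sstart,
    IDY = blocks$identity,
    Q = blocks$qchrom, S = blocks$schrom
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
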