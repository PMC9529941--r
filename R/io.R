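#' Read assembled contigs from a FASTA file
#'
#' Loads contigs into a tibble, validating identifiers and sequence alphabet,
#' and applies the assembly admission filter: contigs whose length is less
#' than or equal to `min_length` are dropped (a 10,000 nt contig is excluded
#' at the default threshold, a 10,001 nt contig kept). Set `min_length = 0`
#' to keep everything.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param min_length Admission threshold in nt; contigs with
#'   `length <= min_length` are removed. Default 10000, the standard
#'   pre-identification cutoff for sediment viromes.
#' @param sample_site Optional site label attached to every record.
#' @param source_set One of `"assembly"`, `"blank_control"`, `"host_mag"`.
#' @return A tibble with columns `contig_id`, `sequence` (uppercase ACGTN),
#'   `length`, `sample_site`, `source_set`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", strrep("ACGT", 3000)), fa)
#' read_contigs(fa, min_length = 10000)
read_contigs <- function(path, min_length = 10000, sample_site = NA_character_,
                         source_set = c("assembly", "blank_control", "host_mag")) {
  source_set <- match.arg(source_set)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  stopifnot(min_length >= 0)
  seqs <- Biostrings::readDNAStringSet(path)
  contigs_tbl(
    contig_id = names(seqs) |> sub(pattern = "\\s.*$", replacement = ""),
    sequence = toupper(as.character(seqs)),
    sample_site = sample_site,
    source_set = source_set,
    min_length = min_length
  )
}

#' Build a validated contig tibble from in-memory sequences
#'
#' Same validation and admission filter as [read_contigs()], for sequences
#' already held as character vectors (e.g. from the synthetic generator).
#'
#' @inheritParams read_contigs
#' @param contig_id Character vector of unique identifiers.
#' @param sequence Character vector of DNA sequences (ACGTN, any case).
#' @return A tibble; see [read_contigs()].
#' @export
contigs_tbl <- function(contig_id, sequence, sample_site = NA_character_,
                        source_set = "assembly", min_length = 0) {
  contig_id <- unname(contig_id)
  sequence <- unname(toupper(sequence))
  if (anyDuplicated(contig_id)) {
    abort(sprintf("duplicate contig id(s): %s",
                  paste(unique(contig_id[duplicated(contig_id)]), collapse = ", ")))
  }
  if (any(nchar(sequence) == 0)) {
    abort(sprintf("empty sequence for record(s): %s",
                  paste(contig_id[nchar(sequence) == 0], collapse = ", ")))
  }
  check_dna_alphabet(sequence, contig_id)
  out <- tibble(
    contig_id = as.character(contig_id),
    sequence = sequence,
    length = nchar(sequence),
    sample_site = sample_site,
    source_set = source_set
  )
  filter(out, .data$length > min_length)
}

#' Write contigs to FASTA
#'
#' @param contigs Tibble with `contig_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  assert_columns(contigs, c("contig_id", "sequence"))
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$contig_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# column specs for the on-disk tables -----------------------------------------

#' Table schemas used by the pipeline readers
#'
#' Named list of required column names and readr column types for each table
#' kind understood by [read_table_checked()].
#'
#' @format A named list; each element has `required` (character vector) and
#'   `types` (named list of readr column types).
#' @export
table_schemas <- list(
  gene = list(
    required = c("gene_id", "contig_id", "start", "end", "strand", "product"),
    types = list(gene_id = "c", contig_id = "c", start = "i", end = "i",
                 strand = "c", product = "c")
  ),
  predictor = list(
    required = c("contig_id", "tool", "call"),
    types = list(contig_id = "c", tool = "c", call = "l")
  ),
  completeness = list(
    required = c("contig_id", "completeness"),
    types = list(contig_id = "c", completeness = "d")
  ),
  blank = list(
    required = c("contig_id", "blank_reads"),
    types = list(contig_id = "c", blank_reads = "i")
  ),
  depth = list(
    required = c("contig_id", "sample_id", "depth", "covered_fraction"),
    types = list(contig_id = "c", sample_id = "c", depth = "d",
                 covered_fraction = "d")
  ),
  sample_gb = list(
    required = c("sample_id", "gb"),
    types = list(sample_id = "c", gb = "d")
  ),
  transcript = list(
    required = c("gene_id", "contig_id", "reads"),
    types = list(gene_id = "c", contig_id = "c", reads = "d")
  ),
  amg = list(
    required = c("gene_id", "contig_id", "function_id", "source",
                 "auxiliary_score", "flags", "category"),
    types = list(gene_id = "c", contig_id = "c", function_id = "c",
                 source = "c", auxiliary_score = "i", flags = "c",
                 category = "c")
  )
)

#' Read a header-carrying TSV against a named schema
#'
#' The header must contain every required column of the schema (order does
#' not matter); extra columns are preserved as character. A missing required
#' column or an unparseable cell is a hard error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Either the name of an entry of [table_schemas] or a list
#'   with elements `required` and `types` in the same shape.
#' @return A tibble of typed rows.
#' @export
read_table_checked <- function(path, schema) {
  if (is.character(schema)) {
    if (!schema %in% names(table_schemas)) {
      abort(sprintf("unknown schema '%s'", schema))
    }
    schema <- table_schemas[[schema]]
  }
  if (!file.exists(path)) abort(sprintf("table file not found: %s", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(schema$required, header)
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  types <- do.call(readr::cols,
                   c(schema$types, list(.default = readr::col_character())))
  tbl <- readr::read_tsv(path, col_types = types, progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("%s: unparseable cell at row %d, column '%s'",
                  path, probs$row[1], header[probs$col[1]]))
  }
  message(sprintf("read %d rows from %s", nrow(tbl), path))
  tbl
}

#' Read a 12-column tabular alignment file (outfmt-6 dialect)
#'
#' Columns follow the classic tab-separated report: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end (1-based inclusive), e-value, bitscore. No header row.
#'
#' @param path Path to the alignment file.
#' @return A tibble with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gaps`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bitscore`.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  cn <- c("query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
          "gaps", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
  tbl <- readr::read_tsv(path, col_names = cn, progress = FALSE,
                         col_types = "ccdiiiiiiidd")
  if (nrow(tbl) > 0) {
    if (any(tbl$aln_length < 1)) abort("alignment length < 1 in alignment file")
    if (any(tbl$pct_identity < 0 | tbl$pct_identity > 100)) {
      abort("percent identity outside [0, 100] in alignment file")
    }
  }
  tbl
}

#' Write an alignment tibble back to the 12-column tabular format
#'
#' @param alignments Tibble in the shape returned by [read_alignment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(alignments, path) {
  assert_columns(alignments, c("query_id", "subject_id", "pct_identity",
                               "aln_length"))
  readr::write_tsv(alignments, path, col_names = FALSE)
  invisible(path)
}
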