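# Auxiliary-metabolic-gene screening: flag/score/curation filters plus the
# positional viral-context check.

#' Screen AMG candidates
#'
#' A candidate is removed, with the first failing rule recorded as its
#' verdict, when any of the following holds (checked in order):
#' \enumerate{
#'   \item `removed_flag`: it carries a T (transposon-associated) or B
#'     (flanking-gene) flag;
#'   \item `removed_score`: its auxiliary score exceeds
#'     `max_auxiliary_score` (default 3);
#'   \item `removed_not_curated`: its function id is not on the curated
#'     AMG list;
#'   \item `removed_context`: the viral-context check fails. Strict mode
#'     (default) requires at least one viral-specific gene on each side of
#'     the candidate on its contig; lenient mode requires at least one
#'     anywhere on the contig.
#' }
#' Candidates failing no rule are `retained`.
#'
#' @param candidates AMG candidate tibble: `gene_id`, `contig_id`,
#'   `function_id`, `auxiliary_score` (integer or NA), `flags` (string,
#'   e.g. `"T"`, `"B"`, `"none"` or `""`), optional `source`, `category`.
#' @param genes Gene tibble for the same contigs (`gene_id`, `contig_id`,
#'   `start`, `end`, `product`; `category` honoured if present). Candidate
#'   genes must appear here.
#' @param curated_functions Character vector of curated AMG function ids.
#' @param max_auxiliary_score Removal threshold, exclusive (default 3).
#' @param context_mode `"strict"` or `"lenient"`.
#' @return The candidate tibble with a `verdict` column.
#' @export
filter_amg_candidates <- function(candidates, genes, curated_functions,
                                  max_auxiliary_score = 3,
                                  context_mode = c("strict", "lenient")) {
  context_mode <- match.arg(context_mode)
  assert_columns(candidates, c("gene_id", "contig_id", "function_id",
                               "auxiliary_score", "flags"))
  assert_columns(genes, c("gene_id", "contig_id", "start", "end", "product"))
  unknown <- setdiff(candidates$contig_id, genes$contig_id)
  if (length(unknown) > 0) {
    abort(sprintf("candidate(s) on unknown contig(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (!"category" %in% names(genes)) {
    genes <- mutate(genes, category = classify_gene_product(.data$product))
  }
  gene_pos <- select(genes, "gene_id", "contig_id", "start", "end",
                     "category")

  verdict_one <- function(gene_id, contig_id, function_id, auxiliary_score,
                          flags, ...) {
    fl <- strsplit(gsub("\\s", "", flags %||% ""), "[,;]")[[1]]
    if (any(fl %in% c("T", "B"))) return("removed_flag")
    if (!is.na(auxiliary_score) && auxiliary_score > max_auxiliary_score) {
      return("removed_score")
    }
    if (!function_id %in% curated_functions) return("removed_not_curated")
    here <- filter(gene_pos, .data$contig_id == .env$contig_id)
    me <- filter(here, .data$gene_id == .env$gene_id)
    if (nrow(me) == 0) return("removed_context")  # candidate gene not in table
    viral <- filter(here, .data$category == "viral_specific")
    ok <- if (context_mode == "strict") {
      any(viral$end <= me$start[1]) && any(viral$start >= me$end[1])
    } else {
      nrow(viral) > 0
    }
    if (!ok) return("removed_context")
    "retained"
  }

  candidates %>%
    mutate(verdict = purrr::pmap_chr(
      list(gene_id = .data$gene_id, contig_id = .data$contig_id,
           function_id = .data$function_id,
           auxiliary_score = .data$auxiliary_score, flags = .data$flags),
      verdict_one))
}

#' Summarize retained AMGs
#'
#' Histogram of retained candidates per metabolic category and, when an
#' abundance table is supplied, per-group summed relative abundance of the
#' vOTUs carrying retained AMGs.
#'
#' @param verdicts Output of [filter_amg_candidates()].
#' @param abundance Optional long abundance tibble (see
#'   [normalize_abundance()]); AMG contigs are matched on `votu_id`.
#' @param groups Optional tibble `sample_id`, `group`.
#' @return A list with `category_counts` (tibble `category`, `n`) and,
#'   when abundance is given, `group_abundance` (tibble `group`,
#'   `relative`).
#' @export
summarize_amgs <- function(verdicts, abundance = NULL, groups = NULL) {
  assert_columns(verdicts, c("contig_id", "verdict"))
  retained <- filter(verdicts, .data$verdict == "retained")
  category_counts <- if ("category" %in% names(retained)) {
    count(retained, .data$category, name = "n", sort = TRUE)
  } else {
    tibble(category = character(), n = integer())
  }
  out <- list(category_counts = category_counts)
  if (!is.null(abundance) && !is.null(groups)) {
    assert_columns(abundance, c("votu_id", "sample_id", "relative"))
    assert_columns(groups, c("sample_id", "group"))
    out$group_abundance <- abundance %>%
      filter(.data$votu_id %in% retained$contig_id) %>%
      inner_join(groups, by = "sample_id") %>%
      group_by(.data$group) %>%
      summarise(relative = sum(.data$relative), .groups = "drop")
  }
  out
}
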