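# Contig-level viral triage: keyword gene classification, retain/reject
# rules, direct-terminal-repeat detection, quality tiers, decontamination.

#' Viral hallmark keywords recognized in gene product annotations
#'
#' Token (or phrase) list used by [classify_gene_product()]; matching is
#' case-insensitive on word boundaries, so "head" does not match "overhead".
#'
#' @format Character vector.
#' @export
viral_keywords <- c(
  "capsid", "phage", "terminase", "base plate", "baseplate", "prohead",
  "virion", "virus", "viral", "tape measure", "tapemeasure", "neck",
  "tail", "head", "bacteriophage", "prophage", "portal", "DNA packaging",
  "T4", "p22", "holin"
)

#' Classify a gene product annotation string
#'
#' Assigns each product string to one of four categories driving the triage
#' rules: `prokaryote_specific` (cellular marker, e.g. a ribosomal protein),
#' `viral_specific` (contains a hallmark keyword), `unknown`
#' (hypothetical/unknown-function/bare "Viruses" taxon annotations), or
#' `other`. Precedence: prokaryote_specific > viral_specific > unknown.
#'
#' @param product Character vector of annotation strings (may be empty
#'   strings).
#' @param keywords Viral keyword list; phrases allowed.
#' @param prokaryote_patterns Patterns (fixed strings, case-insensitive)
#'   marking prokaryote-specific genes.
#' @return Character vector of categories, same length as `product`.
#' @export
#' @examples
#' classify_gene_product(c("phage terminase large subunit",
#'                         "hypothetical protein",
#'                         "30S ribosomal protein S3"))
classify_gene_product <- function(product,
                                  keywords = viral_keywords,
                                  prokaryote_patterns = "ribosomal protein") {
  product <- as.character(product)
  low <- tolower(product)

  prok <- rep(FALSE, length(product))
  for (p in tolower(prokaryote_patterns)) {
    prok <- prok | stringr::str_detect(low, stringr::fixed(p))
  }

  viral <- rep(FALSE, length(product))
  for (k in tolower(keywords)) {
    # word-boundary token/phrase match: "head" must not hit "overhead"
    pat <- paste0("\\b", stringr::str_replace_all(k, "([\\W])", "\\\\\\1"), "\\b")
    viral <- viral | stringr::str_detect(low, stringr::regex(pat))
  }

  unknown <- stringr::str_detect(low, "hypothetical protein|unknown function") |
    stringr::str_detect(product, "\\bViruses\\b")

  dplyr::case_when(
    prok ~ "prokaryote_specific",
    viral ~ "viral_specific",
    unknown ~ "unknown",
    TRUE ~ "other"
  )
}

#' Triage contigs flagged by viral prediction tools
#'
#' Applies the decision rules that turn predictor-flagged contigs into
#' high-confidence viral contigs. A contig is retained iff all of:
#' \enumerate{
#'   \item it carries >= `viral_gene_quorum` viral-specific genes, OR it has
#'     at least one predictor call and >= `unknown_fraction_min` of its genes
#'     are hypothetical/unknown/Viruses;
#'   \item it carries no prokaryote-specific gene;
#'   \item a conservative signal exists: completeness was determined, or a
#'     viral-specific gene is present, or at least one call comes from the
#'     benchmarked conservative tool subset.
#' }
#' Every rule that fired is recorded as an ordered reason code.
#'
#' @param genes Gene tibble (`gene_id`, `contig_id`, `product`; a `category`
#'   column is honoured if present, otherwise computed by
#'   [classify_gene_product()]).
#' @param predictor_calls Tibble `contig_id`, `tool`, `call` (logical).
#' @param completeness Optional tibble `contig_id`, `completeness` (percent,
#'   `NA` allowed). Contigs absent from it count as undetermined.
#' @param contig_ids Optional character vector fixing the contig universe
#'   (contigs with no gene rows get `NO_EVIDENCE`). Defaults to the union of
#'   contigs seen in `genes` and `predictor_calls`.
#' @param config A [virome_config()].
#' @return Tibble, one row per contig: `contig_id`, `retained`, `reasons`
#'   (semicolon-joined codes), `n_genes`, `n_viral_specific`, `n_unknown`,
#'   `n_prokaryote`.
#' @export
triage_contigs <- function(genes, predictor_calls, completeness = NULL,
                           contig_ids = NULL, config = virome_config()) {
  assert_columns(genes, c("contig_id", "product"))
  assert_columns(predictor_calls, c("contig_id", "tool", "call"))
  if (!"category" %in% names(genes)) {
    genes <- mutate(genes, category = classify_gene_product(
      .data$product, prokaryote_patterns = config$prokaryote_patterns))
  }
  contig_ids <- contig_ids %||%
    union(unique(genes$contig_id), unique(predictor_calls$contig_id))

  counts <- genes %>%
    group_by(.data$contig_id) %>%
    summarise(
      n_genes = dplyr::n(),
      n_viral_specific = sum(.data$category == "viral_specific"),
      n_unknown = sum(.data$category == "unknown"),
      n_prokaryote = sum(.data$category == "prokaryote_specific"),
      .groups = "drop"
    )

  calls <- predictor_calls %>%
    filter(.data$call) %>%
    group_by(.data$contig_id) %>%
    summarise(
      n_calls = dplyr::n(),
      n_conservative = sum(.data$tool %in% config$conservative_tools),
      .groups = "drop"
    )

  comp <- if (is.null(completeness)) {
    tibble(contig_id = character(), completeness = double())
  } else {
    assert_columns(completeness, c("contig_id", "completeness"))
    completeness
  }

  out <- tibble(contig_id = contig_ids) %>%
    left_join(counts, by = "contig_id") %>%
    left_join(calls, by = "contig_id") %>%
    left_join(select(comp, "contig_id", "completeness"), by = "contig_id") %>%
    mutate(across(c("n_genes", "n_viral_specific", "n_unknown",
                    "n_prokaryote", "n_calls", "n_conservative"),
                  ~ tidyr::replace_na(.x, 0L)))

  decide_one <- function(n_genes, nv, nu, np, n_calls, n_cons, completeness) {
    reasons <- character()
    if (n_genes == 0) {
      return(list(retained = FALSE, reasons = "NO_EVIDENCE"))
    }
    quorum <- nv >= config$viral_gene_quorum
    unknown_route <- n_calls >= 1 && nu / n_genes >= config$unknown_fraction_min
    if (quorum) reasons <- c(reasons, "VIRAL_GENE_QUORUM")
    if (unknown_route) reasons <- c(reasons, "UNKNOWN_MAJORITY")
    retained <- quorum || unknown_route
    if (!retained) reasons <- c(reasons, "NO_EVIDENCE")
    if (np > 0) {
      retained <- FALSE
      reasons <- c(reasons, "PROKARYOTE_GENE")
    }
    conservative_ok <- !is.na(completeness) || nv >= 1 || n_cons >= 1
    if (!conservative_ok) {
      retained <- FALSE
      reasons <- c(reasons, "CONSERVATIVE_SIGNAL_MISSING")
    }
    list(retained = retained, reasons = paste(reasons, collapse = ";"))
  }

  dec <- purrr::pmap(
    list(out$n_genes, out$n_viral_specific, out$n_unknown, out$n_prokaryote,
         out$n_calls, out$n_conservative, out$completeness %||% NA_real_),
    decide_one
  )
  out %>%
    mutate(
      retained = purrr::map_lgl(dec, "retained"),
      reasons = purrr::map_chr(dec, "reasons")
    ) %>%
    select("contig_id", "retained", "reasons", "n_genes",
           "n_viral_specific", "n_unknown", "n_prokaryote")
}

#' Detect a direct terminal repeat (DTR)
#'
#' Reports the longest exact prefix of the sequence that also ends it; a
#' repeat of at least `min_repeat` nt marks a complete (circularly permuted
#' or terminally redundant) viral genome.
#'
#' @param sequence A single DNA string.
#' @param min_repeat Minimum repeat length in nt (default 20).
#' @return A list with `dtr` (logical) and `repeat_length` (maximal exact
#'   terminal overlap, 0 if none of at least `min_repeat`).
#' @export
detect_dtr <- function(sequence, min_repeat = 20) {
  L <- nchar(sequence)
  if (L <= 2 * min_repeat) {
    abort(sprintf("sequence length %d too short for DTR detection at min_repeat %d",
                  L, min_repeat))
  }
  best <- 0L
  for (k in seq(min_repeat, floor(L / 2))) {
    if (substr(sequence, 1L, k) == substr(sequence, L - k + 1L, L)) best <- k
  }
  list(dtr = best >= min_repeat, repeat_length = best)
}

#' Assign genome quality tiers
#'
#' Partitions every (completeness, DTR) pair into one tier:
#' `complete` (100% completeness with a direct terminal repeat), `high`
#' (>90%), `medium` (50-90%, inclusive), `low` (<50%), `undetermined`
#' (completeness not estimable).
#'
#' @param completeness Numeric vector of percent completeness; `NA` means
#'   undetermined.
#' @param dtr Logical vector (recycled) of direct-terminal-repeat flags.
#' @return Character vector of tiers.
#' @export
#' @examples
#' assign_quality_tier(c(100, 95, 90, 49, NA), dtr = c(TRUE, FALSE, FALSE, FALSE, FALSE))
assign_quality_tier <- function(completeness, dtr = FALSE) {
  if (any(!is.na(completeness) & (completeness < 0 | completeness > 100))) {
    abort("completeness out of [0, 100]")
  }
  n <- max(length(completeness), length(dtr))
  completeness <- rep_len(completeness, n)
  dtr <- rep_len(dtr, n)
  dplyr::case_when(
    is.na(completeness) ~ "undetermined",
    completeness == 100 & dtr ~ "complete",
    completeness > 90 ~ "high",
    completeness >= 50 ~ "medium",
    TRUE ~ "low"
  )
}

#' Remove blank-control contaminants
#'
#' A retained viral contig that recruits at least one read from a blank
#' (negative-control) library is treated as a potential laboratory
#' contaminant and removed.
#'
#' @param retained Character vector of retained contig ids.
#' @param blank_hits Tibble `contig_id`, `blank_reads` (reads mapped from
#'   blank controls). Rows for contigs not in `retained` are ignored with a
#'   warning.
#' @return A list with `kept` and `removed` character vectors.
#' @export
decontaminate <- function(retained, blank_hits) {
  assert_columns(blank_hits, c("contig_id", "blank_reads"))
  if (any(blank_hits$blank_reads < 0)) abort("negative blank read count")
  unknown <- setdiff(blank_hits$contig_id, retained)
  if (length(unknown) > 0) {
    warn(sprintf("blank-hit table references %d contig(s) not in the retained set; ignored",
                 length(unknown)))
  }
  contaminated <- blank_hits %>%
    filter(.data$blank_reads >= 1) %>%
    pull("contig_id")
  list(
    kept = setdiff(retained, contaminated),
    removed = intersect(retained, contaminated)
  )
}
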