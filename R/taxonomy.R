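# Majority-rules family taxonomy and family-level abundance roll-up.

#' Majority-rules family assignment for vOTUs
#'
#' Primary pass: a protein votes for a family when its best database hit has
#' `bitscore >= bitscore_min`; a vOTU is assigned the unique family gathering
#' votes from at least `fraction_min` of its proteins. Fallback pass (only
#' for vOTUs the primary pass leaves unassigned): identical voting, but a
#' protein qualifies when its best hit's percent identity is at least
#' `identity_min`. A tie of two families at or above the voting threshold
#' leaves the vOTU unclassified ("majority" must be unique). A protein
#' contributes only its single best-scoring hit (ties broken toward the
#' lexicographically smaller family).
#'
#' @param proteins Tibble `protein_id`, `votu_id` listing every protein of
#'   every vOTU (hit or not).
#' @param hits Tibble `protein_id`, `family`, `pass` (`"primary_db"` or
#'   `"fallback_db"`), plus `bitscore` (primary rows) and/or `pct_identity`
#'   (fallback rows).
#' @param bitscore_min Primary qualifying bitscore (default 50).
#' @param identity_min Fallback qualifying percent identity (default 50).
#' @param fraction_min Voting fraction for assignment (default 0.5,
#'   inclusive).
#' @return Tibble `votu_id`, `family` (or `"unclassified"`),
#'   `supporting_fraction`, `pass` (`"primary_db"`, `"fallback_db"`,
#'   `"none"`).
#' @export
assign_family <- function(proteins, hits, bitscore_min = 50,
                          identity_min = 50, fraction_min = 0.5) {
  assert_columns(proteins, c("protein_id", "votu_id"))
  assert_columns(hits, c("protein_id", "family", "pass"))
  if (nrow(proteins) == 0) abort("empty protein list")
  unknown <- setdiff(hits$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    abort(sprintf("hit table references unknown protein(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }

  vote_pass <- function(pass_name, qualify_col, qualify_min) {
    h <- filter(hits, .data$pass == pass_name)
    if (!qualify_col %in% names(h)) return(NULL)
    h %>%
      filter(!is.na(.data[[qualify_col]]),
             .data[[qualify_col]] >= qualify_min) %>%
      group_by(.data$protein_id) %>%
      arrange(dplyr::desc(.data[[qualify_col]]), .data$family,
              .by_group = TRUE) %>%
      dplyr::slice(1) %>%            # one best hit per protein
      ungroup() %>%
      inner_join(proteins, by = "protein_id") %>%
      count(.data$votu_id, .data$family, name = "votes")
  }

  totals <- count(proteins, .data$votu_id, name = "n_proteins")

  call_from_votes <- function(votes, pass_name) {
    if (is.null(votes) || nrow(votes) == 0) {
      return(tibble(votu_id = character(), family = character(),
                    supporting_fraction = double(), pass = character()))
    }
    votes %>%
      inner_join(totals, by = "votu_id") %>%
      mutate(fraction = .data$votes / .data$n_proteins) %>%
      filter(.data$fraction >= fraction_min) %>%
      group_by(.data$votu_id) %>%
      summarise(
        family = if (dplyr::n() == 1) .data$family[1] else "unclassified",
        supporting_fraction = if (dplyr::n() == 1) .data$fraction[1] else 0,
        .groups = "drop"
      ) %>%
      filter(.data$family != "unclassified") %>%
      mutate(pass = pass_name)
  }

  primary <- call_from_votes(vote_pass("primary_db", "bitscore", bitscore_min),
                             "primary_db")
  fallback <- call_from_votes(vote_pass("fallback_db", "pct_identity",
                                        identity_min), "fallback_db") %>%
    anti_join(primary, by = "votu_id")

  totals %>%
    left_join(bind_rows(primary, fallback), by = "votu_id") %>%
    mutate(
      family = tidyr::replace_na(.data$family, "unclassified"),
      supporting_fraction = tidyr::replace_na(.data$supporting_fraction, 0),
      pass = tidyr::replace_na(.data$pass, "none")
    ) %>%
    select("votu_id", "family", "supporting_fraction", "pass") %>%
    arrange(.data$votu_id)
}

#' Sum vOTU relative abundances at family level
#'
#' @param calls Family-call tibble from [assign_family()].
#' @param abundance Long abundance tibble with `votu_id`, `sample_id`,
#'   `relative` (per-sample relative abundance; see
#'   [normalize_abundance()]).
#' @return A list with `family_abundance` (tibble `family`, `sample_id`,
#'   `relative`) and `classified_fraction` (tibble `sample_id`,
#'   `classified_fraction`). Column sums are conserved.
#' @export
summarize_family_abundance <- function(calls, abundance) {
  assert_columns(calls, c("votu_id", "family"))
  assert_columns(abundance, c("votu_id", "sample_id", "relative"))
  missing <- setdiff(unique(abundance$votu_id), calls$votu_id)
  if (length(missing) > 0) {
    abort(sprintf("vOTU(s) without a family call: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  fam <- abundance %>%
    inner_join(select(calls, "votu_id", "family"), by = "votu_id") %>%
    group_by(.data$family, .data$sample_id) %>%
    summarise(relative = sum(.data$relative), .groups = "drop")
  cf <- fam %>%
    group_by(.data$sample_id) %>%
    summarise(
      classified_fraction =
        sum(.data$relative[.data$family != "unclassified"]) /
          pmax(sum(.data$relative), .Machine$double.eps),
      .groups = "drop"
    )
  list(family_abundance = fam, classified_fraction = cf)
}
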