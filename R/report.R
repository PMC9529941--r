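# Stage summaries: the percentage roll-ups a survey reports (quality-tier
# fractions, taxonomy coverage, genus novelty, transcriptional activity,
# host-linkage yield).

#' Summarize genome quality tiers
#'
#' @param tiers Tibble with a `tier` column (`complete`, `high`, `medium`,
#'   `low`, `undetermined`), one row per vOTU.
#' @return A list: `counts` (tibble `tier`, `n`), `n_votus`,
#'   `tiered_fraction_pct` (percent of vOTUs assigned to the four
#'   determinate tiers, raw value), `tiered_pct_rounded` (nearest integer).
#' @export
report_quality_tiers <- function(tiers) {
  assert_columns(tiers, "tier")
  lv <- c("complete", "high", "medium", "low", "undetermined")
  counts <- tiers %>%
    count(tier = factor(.data$tier, levels = lv), name = "n",
          .drop = FALSE) %>%
    mutate(tier = as.character(.data$tier))
  n <- nrow(tiers)
  tiered <- sum(counts$n[counts$tier != "undetermined"])
  list(
    counts = counts,
    n_votus = n,
    tiered_fraction_pct = 100 * tiered / n,
    tiered_pct_rounded = round(100 * tiered / n)
  )
}

#' Summarize genus-level novelty
#'
#' @param genera Tibble with one row per genus and a logical `overlaps_reference`
#'   column (TRUE when the genus clusters with any external reference set).
#' @return A list: `n_genera`, `n_distinct_genera`,
#'   `distinct_fraction_pct` (raw), `distinct_pct_rounded`.
#' @export
report_genus_novelty <- function(genera) {
  assert_columns(genera, "overlaps_reference")
  n <- nrow(genera)
  distinct_n <- sum(!genera$overlaps_reference)
  list(
    n_genera = n,
    n_distinct_genera = distinct_n,
    distinct_fraction_pct = 100 * distinct_n / n,
    distinct_pct_rounded = round(100 * distinct_n / n)
  )
}

#' Summarize transcriptional activity
#'
#' @param activity Output of [transcribed_activity()].
#' @return A list: `n_votus`, `n_active`, `active_fraction_pct` (raw),
#'   `active_pct_rounded`.
#' @export
report_activity <- function(activity) {
  assert_columns(activity, "active")
  n <- nrow(activity)
  list(
    n_votus = n,
    n_active = sum(activity$active),
    active_fraction_pct = 100 * sum(activity$active) / n,
    active_pct_rounded = round(100 * sum(activity$active) / n)
  )
}

#' Summarize host-linkage yield
#'
#' @param predictions Output of [integrate_host_evidence()].
#' @param n_votus Total number of vOTUs screened.
#' @return A list: `n_linked_votus` (vOTUs with a high-confidence host),
#'   `linked_fraction_pct`, `n_host_genomes`.
#' @export
report_host_linkage <- function(predictions, n_votus) {
  assert_columns(predictions, c("virus_id", "host_id", "high_confidence"))
  hc <- filter(predictions, .data$high_confidence)
  list(
    n_linked_votus = n_distinct(hc$virus_id),
    linked_fraction_pct = 100 * n_distinct(hc$virus_id) / n_votus,
    n_host_genomes = n_distinct(hc$host_id)
  )
}
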