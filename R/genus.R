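# Genus-level clustering via a gene-sharing network: genomes sharing more
# protein clusters (PCs) than expected by chance are connected, and the
# connected components of the thresholded graph are reported as genera.

#' Significance-weighted gene-sharing edges between genomes
#'
#' For two genomes holding `a` and `b` distinct protein clusters of a
#' universe of `M`, sharing `c`, the probability of sharing at least `c`
#' under random draws is the hypergeometric tail
#' \eqn{P = \sum_{i=c}^{\min(a,b)} \binom{b}{i}\binom{M-b}{a-i}/\binom{M}{a}}.
#' The edge score is \eqn{-\log_{10}(P \cdot n_{pairs})} with
#' \eqn{n_{pairs} = N(N-1)/2} a Bonferroni-style correction over all genome
#' pairs; edges at or above `score_min` are kept.
#'
#' @param pc_membership Tibble `protein_id`, `pc_id`.
#' @param genome_of Tibble `protein_id`, `genome_id` (each protein belongs
#'   to exactly one genome).
#' @param score_min Minimum edge score (default 1).
#' @return Tibble `genome_a`, `genome_b`, `shared_pcs`, `p_value`, `score`,
#'   one row per retained edge.
#' @export
gene_sharing_edges <- function(pc_membership, genome_of, score_min = 1) {
  assert_columns(pc_membership, c("protein_id", "pc_id"))
  assert_columns(genome_of, c("protein_id", "genome_id"))
  if (anyDuplicated(genome_of$protein_id)) {
    abort("a protein maps to more than one genome")
  }
  prot <- inner_join(pc_membership, genome_of, by = "protein_id")
  pcs_of <- prot %>%
    distinct(.data$genome_id, .data$pc_id) %>%
    group_by(.data$genome_id) %>%
    summarise(pcs = list(.data$pc_id), .groups = "drop")
  genomes <- sort(unique(genome_of$genome_id))
  M <- n_distinct(pc_membership$pc_id)
  N <- length(genomes)
  n_pairs <- N * (N - 1) / 2
  if (n_pairs == 0) {
    return(tibble(genome_a = character(), genome_b = character(),
                  shared_pcs = integer(), p_value = double(), score = double()))
  }
  sets <- setNames(pcs_of$pcs, pcs_of$genome_id)

  combs <- utils::combn(genomes, 2)
  rows <- purrr::map(seq_len(ncol(combs)), function(k) {
    ga <- combs[1, k]; gb <- combs[2, k]
    A <- sets[[ga]] %||% character(0)
    B <- sets[[gb]] %||% character(0)
    cshared <- length(intersect(A, B))
    if (cshared > min(length(A), length(B))) {
      abort("shared PC count exceeds a genome's PC count (inconsistent input)")
    }
    if (cshared == 0) return(NULL)
    p <- phyper(cshared - 1, length(B), M - length(B), length(A),
                lower.tail = FALSE)
    score <- -log10(pmax(p * n_pairs, .Machine$double.xmin))
    tibble(genome_a = ga, genome_b = gb, shared_pcs = cshared,
           p_value = p, score = score)
  })
  bind_rows(rows) %>% filter(.data$score >= score_min)
}

#' Genus clusters from gene-sharing edges
#'
#' Connected components of the thresholded gene-sharing graph. Genomes with
#' no retained edge form singleton clusters; whether singletons count as
#' genera in summaries is controlled by `count_singletons`.
#'
#' @param edges Edge tibble from [gene_sharing_edges()].
#' @param genomes Character vector of all genome ids (so isolated genomes
#'   are represented).
#' @param count_singletons Count singletons as genera in the attached
#'   summary (default TRUE).
#' @return Tibble `genus_id`, `genome_id`, `n_members`; the attribute
#'   `n_genera` holds the genus count under the chosen singleton policy and
#'   `n_multi_member` the count of multi-member genera.
#' @export
genus_clusters <- function(edges, genomes, count_singletons = TRUE) {
  genomes <- sort(unique(genomes))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges) > 0) edges[, c("genome_a", "genome_b")] else
      data.frame(genome_a = character(), genome_b = character()),
    directed = FALSE,
    vertices = data.frame(name = genomes)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[genomes]
  out <- tibble(genome_id = genomes, component = as.integer(membership)) %>%
    group_by(.data$component) %>%
    mutate(n_members = dplyr::n()) %>%
    ungroup() %>%
    arrange(dplyr::desc(.data$n_members), .data$genome_id) %>%
    mutate(genus_id = sprintf("genus_%04d",
                              match(.data$component, unique(.data$component)))) %>%
    select("genus_id", "genome_id", "n_members")
  n_multi <- n_distinct(out$genus_id[out$n_members > 1])
  n_single <- n_distinct(out$genus_id[out$n_members == 1])
  attr(out, "n_multi_member") <- n_multi
  attr(out, "n_genera") <- if (count_singletons) n_multi + n_single else n_multi
  out
}
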