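# Two-group community simulator: lognormal vOTU abundances across slope and
# bottom-axis samples with a tunable group effect, per-sample sequencing
# sizes, the covered-fraction structure that exercises the zeroing rule,
# blank-control contamination and metatranscriptome gene counts.

#' Simulate a two-group viral community
#'
#' Base per-vOTU abundances are lognormal (`meanlog`, `sdlog`); a
#' `group_effect` fraction of vOTUs is multiplied by `group_factor` in the
#' bottom-axis group, emulating the slope vs bottom-axis design of hadal
#' sediment surveys (defaults: 20 slope and 17 bottom-axis samples).
#' Per-contig covered fractions follow Poisson coverage
#' (`1 - exp(-depth)`), so vOTUs below ~0.105x depth trip the <10%
#' zeroing rule. A configurable fraction of vOTUs receives blank-control
#' reads, and metatranscriptome gene counts are planted so that a known
#' subset of vOTUs meets the ">=20% of genes with >1 read" activity rule.
#'
#' @param n_votus Number of vOTUs (>= 2).
#' @param n_slope,n_bottom Samples per group (>= 2 each).
#' @param meanlog,sdlog Lognormal parameters of the base abundance
#'   (defaults 0 and 1.5).
#' @param sample_sdlog Lognormal per-sample noise (sdlog).
#' @param group_effect Fraction of vOTUs with group-biased abundance.
#' @param group_factor Multiplicative bottom-axis effect for biased vOTUs.
#' @param blank_fraction Fraction of vOTUs receiving >= 1 blank-control
#'   read.
#' @param genes_per_votu Genes per vOTU in the metatranscriptome table.
#' @param active_fraction Fraction of vOTUs planted as transcriptionally
#'   active.
#' @param seed Integer seed.
#' @return A list: `depths` (tibble `contig_id`, `sample_id`, `depth`,
#'   `covered_fraction`), `sample_gb`, `groups` (tibble `sample_id`,
#'   `group`), `blank_hits`, `gene_counts`, and `truth` (per-vOTU planted
#'   group bias, blank contamination and activity flags).
#' @export
sim_communities <- function(n_votus = 100, n_slope = 20, n_bottom = 17,
                            meanlog = 0, sdlog = 1.5, sample_sdlog = 0.5,
                            group_effect = 0.5, group_factor = 10,
                            blank_fraction = 0.05, genes_per_votu = 10,
                            active_fraction = 0.19, seed = 1) {
  stopifnot(n_votus >= 2, n_slope >= 2, n_bottom >= 2)
  if (sdlog <= 0 || sample_sdlog < 0) abort("non-positive dispersion")
  local_seed(seed, {
    votus <- sprintf("vOTU_%04d", seq_len(n_votus))
    samples <- c(sprintf("slope_%02d", seq_len(n_slope)),
                 sprintf("axis_%02d", seq_len(n_bottom)))
    group <- c(rep("slope", n_slope), rep("bottom_axis", n_bottom))

    base <- rlnorm(n_votus, meanlog, sdlog)
    biased <- runif(n_votus) < group_effect
    noise <- matrix(rlnorm(n_votus * length(samples), 0, sample_sdlog),
                    nrow = n_votus)
    depth <- base * noise
    depth[biased, group == "bottom_axis"] <-
      depth[biased, group == "bottom_axis"] * group_factor

    depths <- tibble(
      contig_id = rep(votus, times = length(samples)),
      sample_id = rep(samples, each = n_votus),
      depth = as.vector(depth),
    ) %>%
      mutate(covered_fraction = 1 - exp(-.data$depth))

    sample_gb <- tibble(sample_id = samples,
                        gb = rlnorm(length(samples), log(10), 0.3))

    blank <- runif(n_votus) < blank_fraction
    blank_hits <- tibble(contig_id = votus[blank],
                         blank_reads = 1L + stats::rpois(sum(blank), 2))

    active <- runif(n_votus) < active_fraction
    n_active_genes <- ceiling(0.2 * genes_per_votu)
    gene_counts <- purrr::map2_dfr(votus, active, function(v, act) {
      reads <- integer(genes_per_votu)
      if (act) {
        reads[seq_len(n_active_genes)] <- sample(2:10, n_active_genes,
                                                 replace = TRUE)
      } else {
        reads[1] <- sample(0:1, 1)  # at most one read: never expressed
      }
      tibble(gene_id = sprintf("%s_g%02d", v, seq_len(genes_per_votu)),
             votu_id = v, reads = reads)
    })

    list(
      depths = depths,
      sample_gb = sample_gb,
      groups = tibble(sample_id = samples, group = group),
      blank_hits = blank_hits,
      gene_counts = gene_counts,
      truth = tibble(votu_id = votus, group_biased = biased,
                     blank_contaminated = blank, active = active)
    )
  })
}
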