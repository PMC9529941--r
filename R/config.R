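#' Pipeline run configuration
#'
#' Builds the flat configuration record holding every tunable threshold of
#' the pipeline, each defaulting to the value used in the published
#' hadal-sediment workflow this package implements. The object serializes to
#' YAML and round-trips identically, so a run is reproducible from its
#' config echo alone.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `virome_config`.
#' @details Defaults:
#' \describe{
#'   \item{min_contig_length}{10000 nt; contigs at or below are not admitted.}
#'   \item{viral_gene_quorum}{2; minimum viral-specific genes to retain.}
#'   \item{unknown_fraction_min}{0.70; hypothetical/unknown fraction route.}
#'   \item{dtr_min_repeat}{20 nt; minimum exact terminal repeat.}
#'   \item{ani_min / af_min}{95 (%) / 0.85; species clustering thresholds.}
#'   \item{ani_fragment}{500 nt; fragment size for ANI estimation.}
#'   \item{edge_score_min}{1; gene-sharing network edge threshold.}
#'   \item{family_bitscore_min / family_fraction_min}{50 / 0.5; taxonomy.}
#'   \item{homology_min_length / homology_min_identity /
#'     homology_max_host_cov}{2500 nt / 70 (%) / 0.90.}
#'   \item{spacer_max_mismatch}{1.}
#'   \item{markov_order}{3 (configurable up to 7).}
#'   \item{host_score_min}{3; high-confidence host prediction threshold.}
#'   \item{min_read_identity / min_read_aln_length}{0.95 / 50; read filters.}
#'   \item{min_covered_fraction}{0.10; below this depth is reported as zero.}
#'   \item{activity_min_reads / activity_min_gene_fraction}{2 / 0.20;
#'     a gene is expressed at >1 read, a vOTU active at >=20% expressed genes.}
#'   \item{amg_max_auxiliary_score}{3; candidates with score >3 are removed.}
#'   \item{amg_context_mode}{"strict"; viral genes required on each side.}
#'   \item{n_permutations}{999; PERMANOVA permutations.}
#'   \item{count_singleton_genera}{TRUE; singletons counted as genera.}
#'   \item{conservative_tools}{the benchmarked predictor subset consulted
#'     when neither completeness nor a viral-specific gene is available.}
#' }
#' @export
#' @examples
#' cfg <- virome_config(ani_min = 97)
#' cfg$ani_min
virome_config <- function(...) {
  defaults <- list(
    min_contig_length = 10000L,
    viral_gene_quorum = 2L,
    unknown_fraction_min = 0.70,
    prokaryote_patterns = "ribosomal protein",
    dtr_min_repeat = 20L,
    ani_min = 95,
    af_min = 0.85,
    ani_fragment = 500L,
    ani_fragment_min_identity = 80,
    edge_score_min = 1,
    family_bitscore_min = 50,
    family_identity_min = 50,
    family_fraction_min = 0.5,
    homology_min_length = 2500L,
    homology_min_identity = 70,
    homology_max_host_cov = 0.90,
    spacer_max_mismatch = 1L,
    spacer_min_length = 20L,
    markov_order = 3L,
    host_score_min = 3,
    host_points = list(crispr0 = 5, crispr1 = 3, homology = 3, trna = 2,
                       kmer = 1),
    min_read_identity = 0.95,
    min_read_aln_length = 50L,
    min_covered_fraction = 0.10,
    trimmed_mean_trim = 0.05,
    activity_min_reads = 2L,
    activity_min_gene_fraction = 0.20,
    amg_max_auxiliary_score = 3L,
    amg_context_mode = "strict",
    n_permutations = 999L,
    count_singleton_genera = TRUE,
    conservative_tools = c("DeepVirFinder", "VirSorter", "VirSorter2",
                           "MARVEL", "VIBRANT"),
    seed = 1L,
    log_level = "info",
    output_dir = "."
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_virome_config(cfg)
  structure(cfg, class = c("virome_config", "list"))
}

validate_virome_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste("invalid config:", msg))
  chk(cfg$min_contig_length >= 0, "min_contig_length must be >= 0")
  chk(cfg$viral_gene_quorum >= 0, "viral_gene_quorum must be >= 0")
  chk(cfg$unknown_fraction_min >= 0 && cfg$unknown_fraction_min <= 1,
      "unknown_fraction_min must be in [0, 1]")
  chk(cfg$ani_min > 0 && cfg$ani_min <= 100, "ani_min must be in (0, 100]")
  chk(cfg$af_min > 0 && cfg$af_min <= 1, "af_min must be in (0, 1]")
  chk(cfg$markov_order >= 0 && cfg$markov_order <= 7,
      "markov_order must be in [0, 7]")
  chk(cfg$min_covered_fraction >= 0 && cfg$min_covered_fraction <= 1,
      "min_covered_fraction must be in [0, 1]")
  chk(cfg$amg_context_mode %in% c("strict", "lenient"),
      "amg_context_mode must be 'strict' or 'lenient'")
  chk(cfg$n_permutations >= 99, "n_permutations must be >= 99")
  invisible(cfg)
}

#' Write / read a run configuration
#'
#' YAML serialization with exact round-trip of every field.
#'
#' @param cfg A [virome_config()] object.
#' @param path File path.
#' @return `write_virome_config()` returns `path` invisibly;
#'   `read_virome_config()` returns a `virome_config`.
#' @export
write_virome_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "virome_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_virome_config
#' @export
read_virome_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$conservative_tools <- as.character(raw$conservative_tools)
  do.call(virome_config, raw)
}

#' @export
print.virome_config <- function(x, ...) {
  cat("<virome_config>\n")
  flat <- vapply(unclass(x), function(v) paste(unlist(v), collapse = ","),
                 character(1))
  cat(sprintf("  %-26s %s", names(flat), flat), sep = "\n")
  invisible(x)
}
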