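# Coverage-based abundance and community ecology: read filters, the <10%
# covered-fraction zeroing rule, per-gigabase normalization, pseudo-counts,
# alpha/beta diversity, PCoA ordination, group tests, and the
# metatranscriptomic activity rule.

#' Per-contig mean sequencing depth from read-mapping summaries
#'
#' Reads qualify at identity >= `min_identity` and aligned length >=
#' `min_aln_length`; mean depth is qualifying aligned bases over contig
#' length. A contig covered over less than `min_covered_fraction` of its
#' positions in a sample is reported as zero depth.
#'
#' @param reads Tibble `contig_id`, `sample_id`, `identity` (fraction),
#'   `aln_length` (nt), one row per mapped read.
#' @param contig_lengths Tibble `contig_id`, `length`.
#' @param covered Tibble `contig_id`, `sample_id`, `covered_fraction`
#'   (fraction of positions covered by qualifying reads). Pairs absent from
#'   it count as fully covered.
#' @param min_identity,min_aln_length,min_covered_fraction Filter settings
#'   (defaults 0.95, 50, 0.10).
#' @return Depth tibble `contig_id`, `sample_id`, `depth`,
#'   `covered_fraction`.
#' @export
compute_depth <- function(reads, contig_lengths, covered = NULL,
                          min_identity = 0.95, min_aln_length = 50,
                          min_covered_fraction = 0.10) {
  assert_columns(reads, c("contig_id", "sample_id", "identity", "aln_length"))
  assert_columns(contig_lengths, c("contig_id", "length"))
  if (any(reads$aln_length < 0)) abort("negative aligned length")
  depths <- reads %>%
    filter(.data$identity >= min_identity,
           .data$aln_length >= min_aln_length) %>%
    group_by(.data$contig_id, .data$sample_id) %>%
    summarise(bases = sum(as.numeric(.data$aln_length)), .groups = "drop") %>%
    inner_join(contig_lengths, by = "contig_id") %>%
    mutate(depth = .data$bases / .data$length)
  out <- tidyr::expand_grid(contig_id = contig_lengths$contig_id,
                            sample_id = unique(reads$sample_id)) %>%
    left_join(select(depths, "contig_id", "sample_id", "depth"),
              by = c("contig_id", "sample_id")) %>%
    mutate(depth = tidyr::replace_na(.data$depth, 0))
  if (!is.null(covered)) {
    assert_columns(covered, c("contig_id", "sample_id", "covered_fraction"))
    out <- out %>%
      left_join(covered, by = c("contig_id", "sample_id")) %>%
      mutate(covered_fraction = tidyr::replace_na(.data$covered_fraction, 1))
  } else {
    out <- mutate(out, covered_fraction = 1)
  }
  mutate(out, depth = if_else(.data$covered_fraction < min_covered_fraction,
                              0, .data$depth))
}

#' Apply the covered-fraction zeroing rule to a precomputed depth table
#'
#' @param depths Tibble `contig_id`, `sample_id`, `depth`,
#'   `covered_fraction`.
#' @param min_covered_fraction Zeroing threshold (default 0.10, exclusive).
#' @return The same tibble with `depth` set to 0 wherever
#'   `covered_fraction < min_covered_fraction`.
#' @export
zero_low_coverage <- function(depths, min_covered_fraction = 0.10) {
  assert_columns(depths, c("depth", "covered_fraction"))
  if (any(depths$depth < 0)) abort("negative depth")
  mutate(depths,
         depth = if_else(.data$covered_fraction < min_covered_fraction,
                         0, .data$depth))
}

#' Mean or trimmed-mean depth from a per-base depth table
#'
#' @param per_base Tibble `contig_id`, `sample_id`, `pos`, `depth` with one
#'   row per covered position (positions absent count as zero depth).
#' @param contig_lengths Tibble `contig_id`, `length`.
#' @param method `"mean"` (viral default) or `"trimmed_mean"` (host
#'   default).
#' @param trim Fraction trimmed from each tail for `"trimmed_mean"`
#'   (default 0.05).
#' @return Tibble `contig_id`, `sample_id`, `depth`, `covered_fraction`.
#' @export
depth_from_basedepth <- function(per_base, contig_lengths,
                                 method = c("mean", "trimmed_mean"),
                                 trim = 0.05) {
  method <- match.arg(method)
  assert_columns(per_base, c("contig_id", "sample_id", "pos", "depth"))
  assert_columns(contig_lengths, c("contig_id", "length"))
  per_base %>%
    inner_join(contig_lengths, by = "contig_id") %>%
    group_by(.data$contig_id, .data$sample_id, .data$length) %>%
    summarise(
      covered_fraction = sum(.data$depth > 0) / .data$length[1],
      mean_depth = {
        full <- rep(0, .data$length[1])
        full[.data$pos] <- .data$depth
        if (method == "mean") mean(full) else mean(full, trim = trim)
      },
      .groups = "drop"
    ) %>%
    select("contig_id", "sample_id", depth = "mean_depth", "covered_fraction")
}

#' Normalize depths per gigabase and derive relative/pseudo-count views
#'
#' Normalized coverage is depth per gigabase of sample sequencing;
#' per-sample relative abundances divide by the sample's normalized total
#' (an all-zero sample stays all-zero); pseudo-counts are
#' `ceiling(10 * normalized)`, the integerized view feeding the
#' rare-frequency richness estimators.
#'
#' @param depths Depth tibble `contig_id`, `sample_id`, `depth` (post
#'   zeroing rule). The contig column is treated as the vOTU identifier.
#' @param sample_gb Tibble `sample_id`, `gb` (gigabases sequenced, > 0).
#' @return Long abundance tibble `votu_id`, `sample_id`, `depth`,
#'   `normalized`, `relative`, `pseudo_count`.
#' @export
normalize_abundance <- function(depths, sample_gb) {
  assert_columns(depths, c("contig_id", "sample_id", "depth"))
  assert_columns(sample_gb, c("sample_id", "gb"))
  if (any(sample_gb$gb <= 0)) abort("sample gigabases must be > 0")
  missing <- setdiff(unique(depths$sample_id), sample_gb$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("missing gigabase size for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  depths %>%
    inner_join(sample_gb, by = "sample_id") %>%
    mutate(normalized = .data$depth / .data$gb) %>%
    group_by(.data$sample_id) %>%
    mutate(relative = if (sum(.data$normalized) > 0) {
      .data$normalized / sum(.data$normalized)
    } else {
      0
    }) %>%
    ungroup() %>%
    mutate(pseudo_count = as.integer(ceiling(10 * .data$normalized))) %>%
    rename(votu_id = "contig_id") %>%
    select("votu_id", "sample_id", "depth", "normalized", "relative",
           "pseudo_count")
}

# closed-form richness estimators ---------------------------------------------

chao1_index <- function(counts) {
  counts <- counts[counts > 0]
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))  # bias-corrected
}

ace_index <- function(counts, rare_cutoff = 10) {
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_cutoff]
  abund <- counts[counts > rare_cutoff]
  if (length(rare) == 0) return(length(abund))      # no rare heterogeneity
  f1 <- sum(rare == 1)
  n_rare <- sum(rare)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    # all rare species are singletons; fall back to bias-corrected Chao1
    return(chao1_index(counts))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  gamma2 <- max(
    length(rare) / c_ace * sum(seq_len(rare_cutoff) *
                                 (seq_len(rare_cutoff) - 1) * fi) /
      (n_rare * (n_rare - 1)) - 1,
    0)
  length(abund) + length(rare) / c_ace + f1 / c_ace * gamma2
}

#' Alpha diversity of one sample
#'
#' Observed richness, bias-corrected Chao1 and ACE (rare cutoff 10) from the
#' integer pseudo-counts, Shannon (natural log) and inverse Simpson from the
#' count proportions.
#'
#' @param counts Non-negative integer vector (pseudo-counts), at least one
#'   positive entry.
#' @return One-row tibble `observed`, `chao1`, `ace`, `shannon`,
#'   `inv_simpson`.
#' @export
#' @examples
#' alpha_diversity(c(1, 1, 2))
alpha_diversity <- function(counts) {
  if (any(counts < 0)) abort("negative counts")
  if (all(counts == 0)) abort("all-zero count vector")
  pos <- counts[counts > 0]
  p <- pos / sum(pos)
  tibble(
    observed = length(pos),
    chao1 = chao1_index(counts),
    ace = ace_index(counts),
    shannon = -sum(p * log(p)),
    inv_simpson = 1 / sum(p^2)
  )
}

#' Per-sample alpha diversity from a long abundance table
#'
#' Chao1/ACE use the pseudo-counts; Shannon and inverse Simpson use the
#' relative abundances directly.
#'
#' @param abundance Long abundance tibble from [normalize_abundance()].
#' @return Tibble, one row per sample, columns `sample_id`, `observed`,
#'   `chao1`, `ace`, `shannon`, `inv_simpson`.
#' @export
sample_alpha_diversity <- function(abundance) {
  assert_columns(abundance, c("votu_id", "sample_id", "relative",
                              "pseudo_count"))
  abundance %>%
    group_by(.data$sample_id) %>%
    summarise(
      observed = sum(.data$pseudo_count > 0),
      chao1 = chao1_index(.data$pseudo_count),
      ace = ace_index(.data$pseudo_count),
      shannon = {
        p <- .data$relative[.data$relative > 0]
        -sum(p * log(p))
      },
      inv_simpson = {
        p <- .data$relative[.data$relative > 0]
        1 / sum(p^2)
      },
      .groups = "drop"
    )
}

#' Bray-Curtis dissimilarity and principal-coordinate ordination
#'
#' Builds the Bray-Curtis matrix on per-sample relative abundances and its
#' classical PCoA (eigendecomposition of the double-centered squared
#' distance matrix, coordinates scaled by the square root of each positive
#' eigenvalue; axes with negative eigenvalues are reported and dropped).
#'
#' @param abundance Long abundance tibble from [normalize_abundance()]
#'   covering at least 3 samples; no sample may have zero total.
#' @return Object of class `virome_pcoa`: list with `distances` (dist),
#'   `coordinates` (tibble `sample_id`, `axis1`, `axis2`, ...),
#'   `eigenvalues`, `relative_eig`.
#' @export
beta_ordination <- function(abundance) {
  assert_columns(abundance, c("votu_id", "sample_id", "relative"))
  wide <- abundance %>%
    select("votu_id", "sample_id", "relative") %>%
    tidyr::pivot_wider(names_from = "votu_id", values_from = "relative",
                       values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  if (nrow(m) < 3) abort("beta ordination needs at least 3 samples")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(sprintf("sample(s) with zero total abundance: %s",
                  paste(rownames(m)[zero], collapse = ", ")))
  }
  d <- vegan::vegdist(m, method = "bray")
  pc <- suppressWarnings(cmdscale(d, k = nrow(m) - 1, eig = TRUE))
  eig <- pc$eig
  keep <- which(eig > sqrt(.Machine$double.eps))
  coords <- pc$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("axis", seq_along(keep))
  structure(
    list(
      distances = d,
      coordinates = dplyr::bind_cols(tibble(sample_id = rownames(m)),
                                     as_tibble(coords)),
      eigenvalues = eig,
      relative_eig = pmax(eig, 0) / sum(pmax(eig, 0))
    ),
    class = "virome_pcoa"
  )
}

# pseudo-F used by the exhaustive route and cross-checked against vegan
permanova_pseudo_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (gl in unique(groups)) {
    idx <- which(groups == gl)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  g <- length(unique(groups))
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

#' Group comparison: PERMANOVA plus per-index t and Wilcoxon tests
#'
#' PERMANOVA on the Bray-Curtis matrix with free label permutations and
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`; classic two-sample
#' two-sided t tests (equal variances) and two-sided Wilcoxon rank-sum tests
#' (exact null for small groups) on each alpha-diversity index.
#'
#' @param abundance Long abundance tibble from [normalize_abundance()].
#' @param groups Tibble `sample_id`, `group` (exactly two groups, each with
#'   at least 2 samples).
#' @param n_perm Number of permutations (default 999). With `exhaustive =
#'   TRUE` all distinct size-preserving labelings are enumerated instead and
#'   the p-value is the fraction with `F >= F_obs`.
#' @param seed Integer seed driving the permutations.
#' @param exhaustive Enumerate all labelings (only sensible for tiny n).
#' @return Object of class `virome_group_tests`: list with `permanova`
#'   (statistic, p), `alpha_tests` (tibble index x test), `alpha` (per-sample
#'   index values), `n_perm`, `groups`.
#' @export
group_tests <- function(abundance, groups, n_perm = 999, seed = 1,
                        exhaustive = FALSE) {
  assert_columns(groups, c("sample_id", "group"))
  if (n_distinct(groups$group) != 2) abort("exactly two groups required")
  sizes <- count(groups, .data$group)
  if (any(sizes$n < 2)) abort("each group needs at least 2 samples")
  ord <- beta_ordination(abundance)
  d <- ord$distances
  ids <- attr(d, "Labels")
  gl <- groups$group[match(ids, groups$sample_id)]
  if (any(is.na(gl))) abort("group labels missing for some samples")

  if (exhaustive) {
    f_obs <- permanova_pseudo_f(d, gl)
    g1 <- unique(gl)[1]
    n1 <- sum(gl == g1)
    sel <- utils::combn(length(gl), n1)
    f_all <- apply(sel, 2, function(idx) {
      lab <- rep("b", length(gl)); lab[idx] <- "a"
      permanova_pseudo_f(d, lab)
    })
    perm <- list(statistic = f_obs,
                 p_value = mean(f_all >= f_obs - 1e-12),
                 n_labelings = ncol(sel))
  } else {
    set.seed(seed)
    fit <- vegan::adonis2(d ~ grp, data = data.frame(grp = gl),
                          permutations = n_perm)
    perm <- list(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
                 n_labelings = NA_integer_)
  }

  alpha <- sample_alpha_diversity(abundance) %>%
    left_join(groups, by = "sample_id")
  idx_cols <- c("observed", "chao1", "ace", "shannon", "inv_simpson")
  alpha_tests <- purrr::map_dfr(idx_cols, function(ix) {
    x <- alpha[[ix]][alpha$group == sizes$group[1]]
    y <- alpha[[ix]][alpha$group == sizes$group[2]]
    tt <- tryCatch(t.test(x, y, var.equal = TRUE), error = function(e) NULL)
    wt <- tryCatch(
      suppressWarnings(wilcox.test(x, y, exact = (length(x) <= 10 &&
                                                    length(y) <= 10))),
      error = function(e) NULL)
    tibble(index = ix,
           mean_diff = mean(x) - mean(y),
           t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           t_p = if (is.null(tt)) NA_real_ else tt$p.value,
           wilcoxon_p = if (is.null(wt)) NA_real_ else wt$p.value)
  })

  structure(
    list(permanova = perm, alpha_tests = alpha_tests, alpha = alpha,
         n_perm = if (exhaustive) NA_integer_ else n_perm,
         groups = groups, ordination = ord),
    class = "virome_group_tests"
  )
}

#' Metatranscriptomic activity of vOTUs
#'
#' A gene counts as expressed when mapped by more than one metatranscriptome
#' read (>= 2); a vOTU is active when at least `min_gene_fraction` of its
#' genes are expressed.
#'
#' @param gene_counts Tibble `gene_id`, `votu_id`, `reads`.
#' @param min_reads Expression threshold in reads (default 2, i.e. strictly
#'   more than 1).
#' @param min_gene_fraction Active-vOTU threshold (default 0.20, inclusive).
#' @return Tibble `votu_id`, `n_genes`, `n_expressed`, `expressed_fraction`,
#'   `active`.
#' @export
transcribed_activity <- function(gene_counts, min_reads = 2,
                                 min_gene_fraction = 0.20) {
  assert_columns(gene_counts, c("gene_id", "votu_id", "reads"))
  if (nrow(gene_counts) == 0) abort("empty gene count table")
  gene_counts %>%
    group_by(.data$votu_id) %>%
    summarise(
      n_genes = dplyr::n(),
      n_expressed = sum(.data$reads >= min_reads),
      .groups = "drop"
    ) %>%
    mutate(
      expressed_fraction = .data$n_expressed / .data$n_genes,
      active = .data$expressed_fraction >= min_gene_fraction
    )
}
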