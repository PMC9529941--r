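# broom-style accessors and print methods for the result objects

#' Tidy the group-comparison results
#'
#' @param x A `virome_group_tests` object from [group_tests()].
#' @param ... Unused.
#' @return A tibble with one row per test (the PERMANOVA plus the t and
#'   Wilcoxon test of each alpha-diversity index).
#' @exportS3Method generics::tidy
tidy.virome_group_tests <- function(x, ...) {
  bind_rows(
    tibble(test = "permanova", index = "bray_curtis",
           statistic = x$permanova$statistic, p_value = x$permanova$p_value),
    x$alpha_tests %>%
      select("index", statistic = "t_statistic", p_value = "t_p") %>%
      mutate(test = "t", .before = 1),
    x$alpha_tests %>%
      select("index", p_value = "wilcoxon_p") %>%
      mutate(test = "wilcoxon", statistic = NA_real_, .before = 1)
  )
}

#' One-row summary of the group comparison
#'
#' @param x A `virome_group_tests` object.
#' @param ... Unused.
#' @return A one-row tibble: PERMANOVA statistic and p, sample sizes, and
#'   the smallest alpha-index t-test p-value.
#' @exportS3Method generics::glance
glance.virome_group_tests <- function(x, ...) {
  sizes <- count(x$groups, .data$group)
  tibble(
    permanova_f = x$permanova$statistic,
    permanova_p = x$permanova$p_value,
    n_group1 = sizes$n[1],
    n_group2 = sizes$n[2],
    min_alpha_t_p = min(x$alpha_tests$t_p),
    n_perm = x$n_perm
  )
}

#' @export
print.virome_group_tests <- function(x, ...) {
  cat("Viral community group comparison\n")
  cat(sprintf("  PERMANOVA (Bray-Curtis): F = %.3f, p = %.4g\n",
              x$permanova$statistic, x$permanova$p_value))
  cat("  alpha-diversity tests (two-sided):\n")
  for (i in seq_len(nrow(x$alpha_tests))) {
    r <- x$alpha_tests[i, ]
    cat(sprintf("    %-12s t p = %.4g, Wilcoxon p = %.4g\n",
                r$index, r$t_p, r$wilcoxon_p))
  }
  invisible(x)
}

#' Tidy PCoA coordinates
#'
#' @param x A `virome_pcoa` object from [beta_ordination()].
#' @param ... Unused.
#' @return The coordinate tibble with the relative eigenvalue share of each
#'   axis as an attribute.
#' @exportS3Method generics::tidy
tidy.virome_pcoa <- function(x, ...) {
  out <- x$coordinates
  attr(out, "relative_eig") <- x$relative_eig
  out
}

#' @export
print.virome_pcoa <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat(sprintf("PCoA of %d samples (%d positive axes)\n",
              nrow(x$coordinates), k))
  cat(sprintf("  axis 1-2 variance share: %.1f%%, %.1f%%\n",
              100 * x$relative_eig[1], 100 * x$relative_eig[2]))
  invisible(x)
}
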