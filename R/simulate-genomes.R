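# Ground-truthed genome simulator: viral and host contigs with annotated
# genes, predictor calls, planted terminal repeats, CRISPR arrays, shared
# tRNAs, homologous segments and composition bias. Every planted feature is
# recorded in the returned truth tables and recoverable from the emitted
# records by exact search.

PREDICTOR_TOOLS <- c("MARVEL", "VirFinder", "PPR-Meta", "VirSorter",
                     "MetaPhinder", "DeepVirFinder", "VIBRANT", "VirNet",
                     "Phigaro", "VirSorter2", "Seeker")

sample_products <- function(n, viral_fraction, unknown_fraction,
                            ribosomal = FALSE) {
  other_products <- c("ATP synthase subunit beta", "DNA polymerase III",
                      "MFS transporter", "glycosyltransferase family 2",
                      "sulfatase domain protein")
  cats <- sample(c("viral", "unknown", "other"), n, replace = TRUE,
                 prob = c(viral_fraction, unknown_fraction,
                          max(1 - viral_fraction - unknown_fraction, 0)))
  if (ribosomal) {
    # plant at least one unmistakable cellular marker
    cats[sample(n, max(1, round(n * 0.15)))] <- "ribosomal"
  }
  vapply(cats, function(ct) {
    switch(ct,
      viral = sprintf("putative %s protein",
                      sample(setdiff(viral_keywords, c("T4", "p22")), 1)),
      unknown = "hypothetical protein",
      ribosomal = sprintf("%s ribosomal protein %s",
                          sample(c("30S", "50S"), 1),
                          sample(c("S3", "L2", "L11"), 1)),
      other = sample(other_products, 1)
    )
  }, character(1))
}

tile_genes <- function(contig_id, genome_length, n_genes) {
  # non-overlapping 0-based half-open intervals tiled along the genome
  max_len <- floor(genome_length / n_genes)
  lens <- pmax(150L, pmin(as.integer(runif(n_genes, 600, 1200)), max_len))
  offsets <- cumsum(c(0L, head(rep(max_len, n_genes), -1)))
  tibble(
    gene_id = sprintf("%s_g%03d", contig_id, seq_len(n_genes)),
    contig_id = contig_id,
    start = offsets,
    end = offsets + lens,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

#' Simulate annotated viral and host genomes with planted host links
#'
#' Generates viral contigs (20-60 genes each, configurable product mix,
#' optional exact direct terminal repeats), non-viral contigs carrying
#' ribosomal marker genes, and host genomes carrying CRISPR arrays whose
#' spacers are lifted verbatim from linked viral genomes, shared tRNA genes,
#' integrated homologous segments, and host-specific base-composition bias.
#' Per-tool predictor calls are sampled with configurable
#' sensitivity/specificity. Deterministic under `seed`.
#'
#' @param n_viral,n_host,n_nonviral Numbers of viral contigs, host genomes,
#'   and non-viral (cellular) contigs.
#' @param viral_length_range,host_length_range Genome length bounds, nt.
#' @param viral_gene_fraction,unknown_gene_fraction Product mix of viral
#'   genomes.
#' @param dtr_fraction Fraction of viral genomes receiving an exact direct
#'   terminal repeat of `dtr_length` nt.
#' @param dtr_length Terminal repeat length, nt.
#' @param crispr_fraction Fraction of hosts carrying a CRISPR array (4
#'   copies of a 30 nt repeat, 3 spacers of `spacer_length` nt copied from a
#'   randomly linked viral genome).
#' @param spacer_length Planted spacer length, nt (26-50).
#' @param trna_fraction Fraction of hosts sharing a 75 nt tRNA with a linked
#'   virus.
#' @param homology_fraction Fraction of hosts receiving an integrated
#'   segment (`homology_length` nt) copied from a linked virus at
#'   `homology_identity` identity.
#' @param homology_length,homology_identity Planted prophage-like segment
#'   size and identity.
#' @param gc_range Host GC content spread endpoints; hosts are spaced evenly
#'   across it (composition signal for the Markov scorer).
#' @param sensitivity,specificity Per-tool predictor call probabilities
#'   (scalars or vectors over the 11 tools).
#' @param seed Integer seed.
#' @return A list: `contigs` (all records, `source_set` marking hosts),
#'   `genes`, `predictor_calls`, `truth` (per-contig labels and planted
#'   features), `host_links` (planted virus-host evidence rows).
#' @export
sim_genomes <- function(n_viral = 10, n_host = 4, n_nonviral = 5,
                        viral_length_range = c(15000, 35000),
                        host_length_range = c(60000, 120000),
                        viral_gene_fraction = 0.25,
                        unknown_gene_fraction = 0.6,
                        dtr_fraction = 0.3, dtr_length = 30,
                        crispr_fraction = 0.75, spacer_length = 32,
                        trna_fraction = 0.5,
                        homology_fraction = 0.5, homology_length = 3000,
                        homology_identity = 0.85,
                        gc_range = c(0.35, 0.65),
                        sensitivity = 0.8, specificity = 0.95,
                        seed = 1) {
  stopifnot(n_viral >= 0, n_host >= 0, n_nonviral >= 0,
            viral_length_range[1] >= 1000, host_length_range[1] >= 1000)
  if (spacer_length > viral_length_range[1]) {
    abort("planted spacer longer than the shortest possible viral genome")
  }
  if (homology_length > viral_length_range[1]) {
    abort("planted homologous segment longer than the shortest viral genome")
  }
  local_seed(seed, {
    viral_ids <- sprintf("virus_%03d", seq_len(n_viral))
    host_ids <- sprintf("host_%03d", seq_len(n_host))
    nonviral_ids <- sprintf("cell_%03d", seq_len(n_nonviral))

    v_len <- as.integer(runif(n_viral, viral_length_range[1],
                              viral_length_range[2]))
    viral_seqs <- vapply(v_len, random_dna, character(1))
    dtr_flag <- runif(n_viral) < dtr_fraction
    for (i in which(dtr_flag)) {
      rep_seq <- substr(viral_seqs[i], 1, dtr_length)
      substr(viral_seqs[i], v_len[i] - dtr_length + 1L, v_len[i]) <- rep_seq
    }

    nv_len <- as.integer(runif(n_nonviral, viral_length_range[1],
                               viral_length_range[2]))
    nonviral_seqs <- vapply(nv_len, random_dna, character(1))

    # hosts with evenly spaced GC content (composition signal)
    gc <- if (n_host > 1) seq(gc_range[1], gc_range[2], length.out = n_host)
          else mean(gc_range)
    h_len <- as.integer(runif(n_host, host_length_range[1],
                              host_length_range[2]))
    host_seqs <- vapply(seq_len(n_host), function(i) {
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      random_dna(h_len[i], p)
    }, character(1))

    links <- list()
    plant_in_host <- function(i, insert) {
      # append planted material; keeps prior planted coordinates valid
      host_seqs[i] <<- paste0(host_seqs[i], insert)
    }

    if (n_host > 0 && n_viral > 0) {
      # CRISPR arrays: >=3 exact repeat copies, spacers lifted verbatim
      for (i in which(runif(n_host) < crispr_fraction)) {
        v <- sample(n_viral, 1)
        rep_seq <- random_dna(30)
        sp_start <- sample(v_len[v] - spacer_length, 3)
        spacers <- substring(viral_seqs[v], sp_start,
                             sp_start + spacer_length - 1L)
        while (anyDuplicated(spacers)) {
          sp_start <- sample(v_len[v] - spacer_length, 3)
          spacers <- substring(viral_seqs[v], sp_start,
                               sp_start + spacer_length - 1L)
        }
        array <- paste0(rep_seq, paste0(spacers, rep_seq, collapse = ""))
        plant_in_host(i, array)
        links[[length(links) + 1]] <- tibble(
          virus_id = viral_ids[v], host_id = host_ids[i], method = "crispr",
          detail = paste(spacers, collapse = ";"))
      }
      # shared tRNAs: exact 75 nt copy in both genomes
      for (i in which(runif(n_host) < trna_fraction)) {
        v <- sample(n_viral, 1)
        trna <- random_dna(75)
        plant_in_host(i, trna)
        pos <- sample(v_len[v] - 75, 1)
        substr(viral_seqs[v], pos, pos + 74L) <- trna
        links[[length(links) + 1]] <- tibble(
          virus_id = viral_ids[v], host_id = host_ids[i], method = "trna",
          detail = trna)
      }
      # integrated homologous (prophage-like) segments
      for (i in which(runif(n_host) < homology_fraction)) {
        v <- sample(n_viral, 1)
        pos <- sample(v_len[v] - homology_length, 1)
        seg <- substr(viral_seqs[v], pos, pos + homology_length - 1L)
        seg <- substitute_positions(seg, 1 - homology_identity)
        plant_in_host(i, seg)
        links[[length(links) + 1]] <- tibble(
          virus_id = viral_ids[v], host_id = host_ids[i], method = "homology",
          detail = sprintf("%d@%.2f", homology_length, homology_identity))
      }
    }

    genes <- bind_rows(
      purrr::map(seq_len(n_viral), function(i) {
        g <- tile_genes(viral_ids[i], v_len[i], sample(20:60, 1))
        mutate(g, product = sample_products(nrow(g), viral_gene_fraction,
                                            unknown_gene_fraction))
      }),
      purrr::map(seq_len(n_nonviral), function(i) {
        g <- tile_genes(nonviral_ids[i], nv_len[i], sample(20:60, 1))
        mutate(g, product = sample_products(nrow(g), 0.02, 0.4,
                                            ribosomal = TRUE))
      })
    )

    sens <- rep_len(sensitivity, length(PREDICTOR_TOOLS))
    spec <- rep_len(specificity, length(PREDICTOR_TOOLS))
    call_ids <- c(viral_ids, nonviral_ids)
    is_viral <- c(rep(TRUE, n_viral), rep(FALSE, n_nonviral))
    predictor_calls <- tidyr::expand_grid(
      contig_id = call_ids, tool = PREDICTOR_TOOLS) %>%
      mutate(
        viral = is_viral[match(.data$contig_id, call_ids)],
        p = if_else(.data$viral, sens[match(.data$tool, PREDICTOR_TOOLS)],
                    1 - spec[match(.data$tool, PREDICTOR_TOOLS)]),
        call = runif(dplyr::n()) < .data$p
      ) %>%
      select("contig_id", "tool", "call")

    contigs <- bind_rows(
      contigs_tbl(viral_ids, viral_seqs, source_set = "assembly"),
      contigs_tbl(nonviral_ids, nonviral_seqs, source_set = "assembly"),
      if (n_host > 0) contigs_tbl(host_ids, host_seqs,
                                  source_set = "host_mag")
    )

    keyword_counts <- genes %>%
      mutate(category = classify_gene_product(.data$product)) %>%
      group_by(.data$contig_id) %>%
      summarise(n_keyword_genes = sum(.data$category == "viral_specific"),
                n_ribosomal = sum(.data$category == "prokaryote_specific"),
                .groups = "drop")

    truth <- tibble(
      contig_id = c(viral_ids, nonviral_ids),
      is_viral = is_viral,
      dtr = c(dtr_flag, rep(FALSE, n_nonviral)),
      dtr_length = if_else(c(dtr_flag, rep(FALSE, n_nonviral)),
                           as.integer(dtr_length), 0L)
    ) %>%
      left_join(keyword_counts, by = "contig_id") %>%
      mutate(across(c("n_keyword_genes", "n_ribosomal"),
                    ~ tidyr::replace_na(.x, 0L)))

    list(
      contigs = contigs,
      genes = genes,
      predictor_calls = predictor_calls,
      truth = truth,
      host_links = if (length(links)) bind_rows(links) else
        tibble(virus_id = character(), host_id = character(),
               method = character(), detail = character())
    )
  })
}

# substitute a fraction of positions, each to one of the 3 other bases
substitute_positions <- function(sequence, rate) {
  L <- nchar(sequence)
  n_sub <- round(rate * L)
  if (n_sub == 0) return(sequence)
  pos <- sample(L, n_sub)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(DNA_BASES, b), 1),
                       character(1))
  paste(chars, collapse = "")
}

#' Build a controlled-similarity variant of a seed sequence
#'
#' Retains a homologous block covering `target_af` of the seed's length
#' (the remainder of the variant is unrelated random sequence of the same
#' total length) and substitutes positions inside the block at rate
#' `1 - target_ani`, each to one of the three alternative bases; no indels,
#' so an exact dynamic-programming alignment of the homologous block
#' recovers the planted identity directly.
#'
#' @param seed_seq Seed DNA string.
#' @param target_ani Target identity of the homologous block, fraction in
#'   (0.5, 1].
#' @param target_af Target aligned fraction of the variant, fraction in
#'   (0, 1].
#' @param seed Integer seed.
#' @return A list: `sequence` (the variant), `realized_ani` (planted block
#'   identity, percent), `realized_af` (planted homologous fraction),
#'   `block_length`.
#' @export
sim_variant <- function(seed_seq, target_ani = 0.95, target_af = 1.0,
                        seed = 1) {
  if (target_ani < 0.5) abort("target_ani < 0.5 is outside model validity")
  stopifnot(target_ani <= 1, target_af > 0, target_af <= 1)
  local_seed(seed, {
    L <- nchar(seed_seq)
    block_len <- max(1L, round(target_af * L))
    block <- substr(seed_seq, 1, block_len)
    n_sub <- round((1 - target_ani) * block_len)
    block <- substitute_positions(block, n_sub / block_len)
    filler <- random_dna(L - block_len)
    list(
      sequence = paste0(block, filler),
      realized_ani = 100 * (1 - n_sub / block_len),
      realized_af = block_len / L,
      block_length = block_len
    )
  })
}

#' Simulate an AMG annotation table with intended verdicts
#'
#' Rows vary auxiliary score (1-5), flags (none/T/B), curated-list
#' membership, and genomic position (interior, flanked by viral-specific
#' genes on both sides, vs terminal with no upstream viral gene). Each row
#' lives on its own three-gene contig so positional context is unambiguous.
#' The intended verdict per row is recorded using the screening rules
#' spelled out independently of the filter implementation.
#'
#' @param n_rows Number of candidate rows (>= 1).
#' @param seed Integer seed.
#' @return A list: `candidates` (AMG table), `genes` (matching gene table),
#'   `curated_functions`, `truth` (tibble `gene_id`, `intended_verdict`
#'   for strict context mode).
#' @export
sim_amg_table <- function(n_rows = 100, seed = 1) {
  stopifnot(n_rows >= 1)
  curated <- sprintf("K%05d", 1:20)
  uncurated <- sprintf("K%05d", 900 + 1:20)
  local_seed(seed, {
    rows <- purrr::map(seq_len(n_rows), function(i) {
      contig_id <- sprintf("amgc_%04d", i)
      score <- sample(1:5, 1)
      flag <- sample(c("none", "T", "B"), 1, prob = c(0.6, 0.2, 0.2))
      in_list <- runif(1) < 0.7
      interior <- runif(1) < 0.7
      fn <- if (in_list) sample(curated, 1) else sample(uncurated, 1)

      flank_product <- c("phage terminase large subunit",
                         "major capsid protein")
      other_product <- c("ATP synthase subunit beta", "MFS transporter")
      products <- if (interior) {
        c(flank_product[1], "candidate", flank_product[2])
      } else {
        # terminal: candidate first, viral gene only downstream
        c("candidate", flank_product[2], other_product[1])
      }
      cand_idx <- which(products == "candidate")
      products[cand_idx] <- "sulfate adenylyltransferase"
      genes <- tibble(
        gene_id = sprintf("%s_g%d", contig_id, 1:3),
        contig_id = contig_id,
        start = c(0L, 1200L, 2400L),
        end = c(1000L, 2200L, 3400L),
        strand = "+",
        product = products
      )
      gene_id <- genes$gene_id[cand_idx]

      intended <- if (flag %in% c("T", "B")) {
        "removed_flag"
      } else if (score > 3) {
        "removed_score"
      } else if (!in_list) {
        "removed_not_curated"
      } else if (!interior) {
        "removed_context"
      } else {
        "retained"
      }

      list(
        candidate = tibble(
          gene_id = gene_id, contig_id = contig_id, function_id = fn,
          source = sample(c("vibrant", "dramv"), 1),
          auxiliary_score = score, flags = flag,
          category = sample(c("amino acid metabolism",
                              "carbohydrate metabolism",
                              "sulfur metabolism",
                              "cofactor and vitamin metabolism"), 1)),
        genes = genes,
        truth = tibble(gene_id = gene_id, intended_verdict = intended)
      )
    })
    list(
      candidates = bind_rows(purrr::map(rows, "candidate")),
      genes = bind_rows(purrr::map(rows, "genes")),
      curated_functions = curated,
      truth = bind_rows(purrr::map(rows, "truth"))
    )
  })
}
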