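#' Count in-frame codons over a strand's ORFs
#'
#' Accumulates the in-frame triplets of every ORF's coding stretch (start codon
#' included, stop codon excluded) into a single codon-count table for the
#' strand. Codons from different ORFs are pooled.
#'
#' @param orfs ORF tibble for one strand, with 0-based half-open `start`/`end`
#'   columns on `strand_sequence`'s own 5'->3' axis.
#' @param strand_sequence The strand's sequence (for the reverse strand, the
#'   reverse complement of the contig).
#' @return Named integer vector over the 64 codons (canonical order).
#' @export
count_codons <- function(orfs, strand_sequence) {
  L <- nchar(strand_sequence)
  if (nrow(orfs) > 0L && (any(orfs$start < 0L) || any(orfs$end > L))) {
    abort("ORF coordinates fall outside the strand sequence")
  }
  .count_codons_core(orfs$start, orfs$end, strand_sequence)
}

# fast path shared with extract_features: 0-based half-open ORF coordinates
.count_codons_core <- function(start, end, strand_sequence) {
  all_codons <- .all_codons()
  counts <- setNames(integer(length(all_codons)), all_codons)
  if (length(start) == 0L) {
    return(counts)
  }
  starts <- unlist(lapply(seq_along(start), function(i) {
    seq.int(start[i] + 1L, end[i] - 2L, by = 3L)
  }))
  codons <- substring(strand_sequence, starts, starts + 2L)
  hit <- tabulate(match(codons, all_codons), nbins = length(all_codons))
  counts[] <- hit
  counts
}

#' Relative synonymous codon usage from a codon-count table
#'
#' For each amino-acid family i with synonymous codons j = 1..n_i, RSCU is the
#' observed count of codon j divided by the expected count under uniform usage
#' within the family: `f_ij = x_ij / ((1/n_i) * sum_j x_ij)`. A value of 1
#' means no bias; the maximum possible value equals the family size. Families
#' with zero total count yield 0 for all their codons, encoding "absent" while
#' keeping the feature matrix dense. ATG, TGG and the stop codons are excluded,
#' leaving 59 features in the canonical order of [rscu_codon_order()].
#'
#' @param counts Named integer vector over the 64 codons (see
#'   [count_codons()]).
#' @return Named numeric vector of 59 RSCU values.
#' @examples
#' counts <- setNames(integer(64), codon_table()$codon)
#' counts[c("TTT", "TTC")] <- c(3L, 1L)
#' rscu_vector(counts)[c("TTT", "TTC")]
#' @export
rscu_vector <- function(counts) {
  all_codons <- .all_codons()
  if (is.null(names(counts)) || !setequal(names(counts), all_codons)) {
    abort("`counts` must be named over all 64 codons")
  }
  counts <- counts[all_codons]
  if (any(counts < 0)) abort("codon counts must be non-negative")
  aa <- .codon_to_aa()
  fam_size <- .codon_family_size()
  fam_total <- tapply(counts, aa, sum)[aa]
  expected <- fam_total / fam_size
  rscu <- ifelse(fam_total > 0, counts / expected, 0)
  rscu <- setNames(as.numeric(rscu), all_codons)
  rscu[rscu_codon_order()]
}

#' Extract per-strand RSCU feature rows from labeled contigs
#'
#' Runs the full feature-extraction protocol: both strands of every contig are
#' scanned for ORFs of at least `min_coding_nt` coding nucleotides, strands
#' with fewer than `min_orfs` ORFs are discarded, and each retained strand
#' becomes one sample whose pooled ORF codon counts are converted to a
#' 59-dimensional RSCU vector. A contig with qualifying ORFs on both strands
#' contributes two rows (the two directions are independent samples).
#'
#' @param contigs Tibble with columns `id`, `sequence`, `experiment_id`,
#'   `label`.
#' @param min_coding_nt Minimum ORF coding length in nucleotides (default 120).
#' @param min_orfs Minimum ORFs per retained strand (default 2).
#' @param quiet Suppress the informational summary of retained/discarded
#'   counts.
#' @return A tibble with columns `contig_id`, `strand`, `experiment_id`,
#'   `label`, `n_orfs`, `total_codons`, followed by the 59 codon-named RSCU
#'   columns in canonical order.
#' @export
extract_features <- function(contigs, min_coding_nt = 120L, min_orfs = 2L, quiet = FALSE) {
  stopifnot(is.data.frame(contigs), all(c("id", "sequence") %in% names(contigs)))
  feature_codons <- rscu_codon_order()
  n_max <- nrow(contigs) * 2L
  rscu_mat <- matrix(0, nrow = n_max, ncol = length(feature_codons),
                     dimnames = list(NULL, feature_codons))
  meta_contig <- character(n_max)
  meta_strand <- character(n_max)
  meta_exp <- character(n_max)
  meta_label <- character(n_max)
  meta_norfs <- integer(n_max)
  meta_codons <- integer(n_max)
  k <- 0L
  n_discarded <- 0L
  has_exp <- "experiment_id" %in% names(contigs)
  has_label <- "label" %in% names(contigs)
  min_coding_nt <- .assert_scalar_int(min_coding_nt, "min_coding_nt", min = 3L)
  min_orfs <- .assert_scalar_int(min_orfs, "min_orfs")
  .assert_dna(contigs$sequence, "contig sequence")
  rc_all <- reverse_complement(contigs$sequence)
  for (i in seq_len(nrow(contigs))) {
    strands <- list(
      forward = list(seq = contigs$sequence[i]),
      reverse = list(seq = rc_all[i])
    )
    emitted <- FALSE
    for (str in names(strands)) {
      strand_seq <- strands[[str]]$seq
      orfs <- .find_orfs_core(strand_seq, min_coding_nt)
      if (length(orfs$start) < min_orfs) next
      counts <- .count_codons_core(orfs$start, orfs$end, strand_seq)
      emitted <- TRUE
      k <- k + 1L
      rscu_mat[k, ] <- rscu_vector(counts)
      meta_contig[k] <- contigs$id[i]
      meta_strand[k] <- str
      meta_exp[k] <- if (has_exp) contigs$experiment_id[i] else NA_character_
      meta_label[k] <- if (has_label) contigs$label[i] else "unlabeled"
      meta_norfs[k] <- length(orfs$start)
      meta_codons[k] <- as.integer(sum(counts))
    }
    if (!emitted) n_discarded <- n_discarded + 1L
  }
  if (k == 0L) {
    abort("no samples survived filtering: no contig strand carries the required number of ORFs")
  }
  keep <- seq_len(k)
  out <- bind_cols(
    tibble(
      contig_id = meta_contig[keep],
      strand = meta_strand[keep],
      experiment_id = meta_exp[keep],
      label = meta_label[keep],
      n_orfs = meta_norfs[keep],
      total_codons = meta_codons[keep]
    ),
    as_tibble(rscu_mat[keep, , drop = FALSE])
  )
  if (!quiet) {
    inform(sprintf(
      "extract_features: %d contigs read, %d discarded by the %d-ORF rule, %d strand samples produced",
      nrow(contigs), n_discarded, min_orfs, nrow(out)
    ))
  }
  out
}

# column names of the 59 RSCU features in a feature table
feature_columns <- function(features) {
  intersect(rscu_codon_order(), names(features))
}

# numeric matrix of the feature columns, canonical order
.feature_matrix <- function(features) {
  as.matrix(features[, rscu_codon_order()])
}

#' Write / read a feature table
#'
#' TSV with the metadata columns followed by the 59 codon-named RSCU columns
#' in canonical order; the column order is part of the file contract.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature tibble.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  features <- readr::read_tsv(path, col_types = readr::cols(
    contig_id = readr::col_character(),
    strand = readr::col_character(),
    experiment_id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ))
  missing_codons <- setdiff(rscu_codon_order(), names(features))
  if (length(missing_codons) > 0L) {
    abort(sprintf(
      "feature table %s lacks %d codon column(s) (first: %s)",
      path, length(missing_codons), missing_codons[1]
    ))
  }
  features
}
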