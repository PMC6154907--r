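# Independent oracles used across the suite. Each is written as a naive,
# readable reference implementation, structurally different from the package
# code paths it checks.

# Brute-force ORF oracle: an explicit state machine walking codon by codon.
# For each frame it tracks the first ATG seen since the last break (stop codon
# or N-containing triplet); when a stop codon arrives, it emits the candidate
# if the coding stretch (ATG inclusive, stop exclusive) is long enough. An
# N-triplet discards the candidate; reaching the sequence end emits nothing.
oracle_find_orfs <- function(sequence, min_coding_nt = 120L) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:2) {
    candidate <- NA_integer_ # codon index of the opening ATG
    i <- frame + 1L
    while (i + 2L <= nchar(sequence)) {
      codon <- substr(sequence, i, i + 2L)
      if (grepl("N", codon, fixed = TRUE)) {
        candidate <- NA_integer_
      } else if (codon %in% stops) {
        if (!is.na(candidate) && (i - candidate) >= min_coding_nt) {
          out[[length(out) + 1L]] <- data.frame(
            frame = frame, start = candidate - 1L, end = i - 1L,
            coding_length_nt = i - candidate
          )
        }
        candidate <- NA_integer_
      } else if (codon == "ATG" && is.na(candidate)) {
        candidate <- i
      }
      i <- i + 3L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      frame = integer(0), start = integer(0), end = integer(0),
      coding_length_nt = integer(0)
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), , drop = FALSE]
}

# Direct RSCU recomputation straight from the definition, looping over amino
# acids of the standard genetic code.
oracle_rscu <- function(counts) {
  gc <- Biostrings::GENETIC_CODE
  feature_codons <- viroscu::rscu_codon_order()
  out <- setNames(numeric(length(feature_codons)), feature_codons)
  for (codon in feature_codons) {
    aa <- gc[[codon]]
    family <- names(gc)[gc == aa]
    total <- sum(counts[family])
    out[codon] <- if (total == 0) 0 else counts[codon] / (total / length(family))
  }
  out
}

# Pairwise-concordance AUROC oracle (Mann-Whitney with ties counted 1/2),
# by explicit enumeration of all positive/negative pairs.
oracle_auroc <- function(scores, labels) {
  y <- if (is.character(labels)) as.integer(labels == "virus") else as.integer(labels)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# random DNA sequences for property tests
random_dna <- function(n, len_range = c(200L, 3000L), alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(len_range[1]:len_range[2], 1L), replace = TRUE), collapse = "")
  }, character(1))
}

# small linearly separable two-class RSCU-like dataset: class shifts a few
# feature columns; returns a feature tibble accepted by the trainers
separable_features <- function(n = 200L, shift = 3, prevalence = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    codons <- viroscu::rscu_codon_order()
    label <- ifelse(runif(n) < prevalence, "virus", "non_virus")
    X <- matrix(runif(n * length(codons)), n, length(codons), dimnames = list(NULL, codons))
    X[label == "virus", 1:4] <- X[label == "virus", 1:4] + shift
    dplyr::bind_cols(
      tibble::tibble(
        contig_id = sprintf("c%03d", seq_len(n)),
        strand = "forward",
        experiment_id = sprintf("e%02d", seq_len(n) %% 4L),
        label = label
      ),
      tibble::as_tibble(X)
    )
  })
}

# codon-count vector covering all 64 codons from a named subset
counts_from <- function(...) {
  counts <- setNames(integer(64), viroscu::codon_table()$codon)
  given <- c(...)
  counts[names(given)] <- as.integer(given)
  counts
}

# random codon-count tables for oracle-equivalence sweeps
random_counts <- function(max_count = 20L) {
  counts <- setNames(
    as.integer(sample(0:max_count, 64L, replace = TRUE)),
    viroscu::codon_table()$codon
  )
  # sprinkle in zeroed families so the zero-count rule is exercised
  gc <- Biostrings::GENETIC_CODE
  for (aa in sample(unique(gc), 3L)) {
    counts[names(gc)[gc == aa]] <- 0L
  }
  counts
}
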