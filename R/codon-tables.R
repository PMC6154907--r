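# Standard genetic code bookkeeping shared across the package. The feature
# space is fixed: 64 codons minus ATG (Met), TGG (Trp) and the three stop
# codons, in a canonical order that is part of the on-disk file contract.

.codon_env <- new.env(parent = emptyenv())

.genetic_code_df <- function() {
  if (!is.null(.codon_env$code)) {
    return(.codon_env$code)
  }
  gc <- Biostrings::GENETIC_CODE
  df <- tibble(
    codon = names(gc),
    amino_acid = unname(gc)
  )
  df <- df[order(df$amino_acid, df$codon), ]
  fam <- table(df$amino_acid)
  df$family_size <- as.integer(fam[df$amino_acid])
  .codon_env$code <- df
  df
}

#' Codon table for the standard genetic code
#'
#' Returns one row per codon with its amino acid (single-letter code, `*` for
#' stop), the size of its synonymous family, and whether the codon is part of
#' the 59-dimensional RSCU feature space (all codons except ATG, TGG and the
#' three stop codons TAA/TAG/TGA).
#'
#' @return A tibble with columns `codon`, `amino_acid`, `family_size`,
#'   `is_feature`, ordered by amino acid then codon. This ordering, restricted
#'   to feature codons, is the canonical column order of every feature table
#'   the package writes.
#' @examples
#' codon_table()
#' @export
codon_table <- function() {
  df <- .genetic_code_df()
  df$is_feature <- !(df$codon %in% c("ATG", "TGG")) & df$amino_acid != "*"
  as_tibble(df)
}

#' Canonical order of the 59 RSCU feature codons
#'
#' Feature codons sorted by amino-acid single-letter code, then alphabetically
#' by codon. Single-codon amino acids (Met/ATG, Trp/TGG) and stop codons carry
#' no synonymous-usage information and are excluded.
#'
#' @return Character vector of length 59.
#' @export
rscu_codon_order <- function() {
  ct <- codon_table()
  ct$codon[ct$is_feature]
}

.stop_codons <- function() c("TAA", "TAG", "TGA")

.all_codons <- function() .genetic_code_df()$codon

# amino acid for each of the 64 codons, named vector
.codon_to_aa <- function() {
  df <- .genetic_code_df()
  setNames(df$amino_acid, df$codon)
}

# family size for each codon (number of synonymous codons), named vector
.codon_family_size <- function() {
  df <- .genetic_code_df()
  setNames(df$family_size, df$codon)
}

# amino acids with >1 codon, excluding stop ("*"): the 18 families that can
# carry codon-usage signal
.multi_codon_aas <- function() {
  df <- .genetic_code_df()
  sort(unique(df$amino_acid[df$family_size > 1L & df$amino_acid != "*"]))
}
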