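#' Reverse complement of a DNA sequence
#'
#' @param sequence Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(sequence) {
  .assert_dna(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Find open reading frames on the forward strand
#'
#' Scans the three reading frames of `sequence` left to right. In each frame an
#' ORF candidate opens at the first `ATG` after the previous in-frame stop (or
#' after the sequence start) and closes at the next in-frame stop codon
#' (TAA/TAG/TGA). The coding length counts from the first base of `ATG` up to,
#' but excluding, the stop codon; only ORFs whose coding length is at least
#' `min_coding_nt` are reported. A triplet containing `N` terminates the
#' current candidate without emitting it, and a candidate that reaches the end
#' of the sequence without a stop codon is not emitted. Nested later `ATG`s
#' inside an open candidate do not start additional ORFs, so no codon is
#' counted twice within a frame.
#'
#' @param sequence A single DNA string over `{A,C,G,T,N}`.
#' @param min_coding_nt Minimum coding length in nucleotides (a positive
#'   multiple of 3; default 120).
#' @return A tibble with columns `frame` (0/1/2), `start`, `end` (0-based,
#'   half-open, on the given strand's own 5'->3' axis; `end` excludes the stop
#'   codon) and `coding_length_nt`, sorted by `(frame, start)`.
#' @examples
#' find_orfs(paste0("ATG", strrep("AAA", 39), "TAA"))
#' @export
find_orfs <- function(sequence, min_coding_nt = 120L) {
  stopifnot(length(sequence) == 1L)
  .assert_dna(sequence)
  min_coding_nt <- .assert_scalar_int(min_coding_nt, "min_coding_nt", min = 3L)
  if (min_coding_nt %% 3L != 0L) {
    abort("`min_coding_nt` must be a multiple of 3")
  }
  res <- .find_orfs_core(sequence, min_coding_nt)
  tibble(
    frame = res$frame, start = res$start, end = res$end,
    coding_length_nt = res$end - res$start
  )
}

# scanner core without validation or tibble overhead; returns plain vectors
# sorted by (frame, start)
.find_orfs_core <- function(sequence, min_coding_nt) {
  L <- nchar(sequence)
  stops <- .stop_codons()
  frame_out <- integer(0)
  start_out <- integer(0)
  end_out <- integer(0)
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < 1L) next
    codon_start <- seq.int(f + 1L, by = 3L, length.out = n_codons)
    codons <- substring(sequence, codon_start, codon_start + 2L)
    is_stop <- codons %in% stops
    is_break <- is_stop | grepl("N", codons, fixed = TRUE)
    is_atg <- codons == "ATG"
    brk <- which(is_break)
    # segments run between consecutive breaks; only a segment terminated by a
    # genuine stop codon (not an N triplet, not the sequence end) can emit
    seg_start <- c(1L, brk + 1L)
    for (s in seq_along(brk)) {
      term <- brk[s]
      if (!is_stop[term]) next
      lo <- seg_start[s]
      if (lo > term - 1L) next
      atg_in_seg <- which(is_atg[lo:(term - 1L)])
      if (length(atg_in_seg) == 0L) next
      a <- lo + atg_in_seg[1L] - 1L
      if ((term - a) * 3L >= min_coding_nt) {
        frame_out <- c(frame_out, f)
        start_out <- c(start_out, codon_start[a] - 1L)
        end_out <- c(end_out, codon_start[term] - 1L)
      }
    }
  }
  ord <- order(frame_out, start_out)
  list(frame = frame_out[ord], start = start_out[ord], end = end_out[ord])
}

#' Find ORFs on both strands of a contig
#'
#' The forward list comes from [find_orfs()] on the contig sequence; the
#' reverse list from [find_orfs()] on its reverse complement. Reverse-strand
#' coordinates are expressed on the reverse complement's own 5'->3' axis, so
#' the two directions can be treated as two independent samples.
#'
#' @param contig One-row tibble (or list) with at least `id` and `sequence`.
#' @param min_coding_nt Minimum coding length in nucleotides.
#' @return A tibble of ORFs with columns `contig_id`, `strand`
#'   (`"forward"`/`"reverse"`), `frame`, `start`, `end`, `coding_length_nt`.
#' @export
strand_orfs <- function(contig, min_coding_nt = 120L) {
  fwd <- find_orfs(contig$sequence, min_coding_nt)
  rev <- find_orfs(reverse_complement(contig$sequence), min_coding_nt)
  tibble(
    contig_id = rep(contig$id, nrow(fwd) + nrow(rev)),
    strand = rep(c("forward", "reverse"), c(nrow(fwd), nrow(rev))),
    frame = c(fwd$frame, rev$frame),
    start = c(fwd$start, rev$start),
    end = c(fwd$end, rev$end),
    coding_length_nt = c(fwd$coding_length_nt, rev$coding_length_nt)
  )
}

#' Apply the per-strand sample-retention rule
#'
#' Each strand of a contig is an independent candidate sample; a strand is
#' retained only if it carries at least `min_orfs` qualifying ORFs. A contig
#' can therefore contribute zero, one or two strand samples.
#'
#' @param orfs ORF tibble from [strand_orfs()] (one contig).
#' @param min_orfs Minimum number of ORFs a strand must carry (default 2).
#' @return The subset of `orfs` on retained strands (possibly zero rows).
#' @export
retain_strand_samples <- function(orfs, min_orfs = 2L) {
  min_orfs <- .assert_scalar_int(min_orfs, "min_orfs")
  if (nrow(orfs) == 0L) {
    return(orfs)
  }
  key <- paste(orfs$contig_id, orfs$strand, sep = "\r")
  n_by_strand <- table(key)
  orfs[n_by_strand[key] >= min_orfs, ]
}

#' Write an ORF report table
#'
#' BED-like TSV with columns `contig_id`, `strand`, `frame`, `start`, `end`,
#' `coding_length_nt` (0-based half-open coordinates on each strand's own
#' 5'->3' axis).
#'
#' @param orfs ORF tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  readr::write_tsv(orfs, path)
  invisible(path)
}
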