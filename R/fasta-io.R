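#' Read assembled contigs from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a contig
#' table. Sequences are uppercased; any character outside `{A,C,G,T,N}` is a
#' parse error naming the offending record. Labels and experiment IDs are set
#' to placeholders until joined with a label table (see [attach_labels()]).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `experiment_id` (`NA`),
#'   `label` (`"unlabeled"`).
#' @seealso [write_contigs()], [read_labels()], [attach_labels()]
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort(sprintf("FASTA file %s contains no records", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf(
      "record %s contains characters outside {A,C,G,T,N}", ids[which(bad)[1]]
    ))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate contig ID in %s: %s", path, ids[duplicated(ids)][1]))
  }
  if (any(nchar(seqs) < 1L)) {
    abort(sprintf("record %s has an empty sequence", ids[which(nchar(seqs) < 1L)[1]]))
  }
  tibble(
    id = unname(ids),
    sequence = unname(seqs),
    experiment_id = NA_character_,
    label = "unlabeled"
  )
}

#' Write a contig table to FASTA
#'
#' @param contigs Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a contig label table
#'
#' The label table is a TSV with header columns `contig_id`, `experiment_id`
#' and `label`; `label` must be `virus` or `non_virus`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three columns.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("label file not found: %s", path))
  }
  labels <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("contig_id", "experiment_id", "label")
  missing_cols <- setdiff(needed, names(labels))
  if (length(missing_cols) > 0L) {
    abort(sprintf("label table %s lacks column(s): %s", path, paste(missing_cols, collapse = ", ")))
  }
  bad <- !labels$label %in% c("virus", "non_virus")
  if (any(bad)) {
    abort(sprintf(
      "label table %s has invalid label %s for contig %s (expected virus/non_virus)",
      path, labels$label[which(bad)[1]], labels$contig_id[which(bad)[1]]
    ))
  }
  labels[needed]
}

#' Write a contig label table
#'
#' @param contigs Tibble with columns `id`, `experiment_id`, `label`.
#' @param path Output path for the TSV.
#' @return `path`, invisibly.
#' @export
write_labels <- function(contigs, path) {
  readr::write_tsv(
    tibble(
      contig_id = contigs$id,
      experiment_id = contigs$experiment_id,
      label = contigs$label
    ),
    path
  )
  invisible(path)
}

#' Join contigs with their labels and experiment IDs
#'
#' @param contigs Contig tibble from [read_contigs()].
#' @param labels Label tibble from [read_labels()].
#' @param strict If `TRUE` (default), error when any contig has no label row;
#'   otherwise unlabeled contigs are kept with label `"unlabeled"`.
#' @return The contig tibble with `experiment_id` and `label` filled in.
#' @export
attach_labels <- function(contigs, labels, strict = TRUE) {
  joined <- left_join(
    contigs[c("id", "sequence")],
    rename(labels, id = "contig_id"),
    by = "id"
  )
  missing <- is.na(joined$label)
  if (any(missing)) {
    if (strict) {
      abort(sprintf(
        "%d contig(s) have no label row (first: %s)", sum(missing), joined$id[which(missing)[1]]
      ))
    }
    joined$label[missing] <- "unlabeled"
  }
  joined[c("id", "sequence", "experiment_id", "label")]
}

#' Validate a FASTA/label-table pair before running the pipeline
#'
#' Reports contigs without labels, label rows without contigs, and duplicate
#' IDs on either side. Duplicate contig records are fatal.
#'
#' @param fasta Path to the contig FASTA file.
#' @param labels Path to the label TSV.
#' @return A tibble with columns `issue`, `id`, `fatal`; zero rows for a clean
#'   dataset. Fatal issues raise an error instead of being returned.
#' @export
validate_inputs <- function(fasta, labels) {
  if (!file.exists(fasta)) abort(sprintf("FASTA file not found: %s", fasta))
  if (!file.exists(labels)) abort(sprintf("label file not found: %s", labels))
  raw <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate contig ID in %s: %s", fasta, ids[duplicated(ids)][1]))
  }
  lab <- read_labels(labels)
  if (anyDuplicated(lab$contig_id)) {
    abort(sprintf("duplicate contig ID in label table: %s", lab$contig_id[duplicated(lab$contig_id)][1]))
  }
  report <- bind_rows(
    tibble(issue = "contig_without_label", id = setdiff(ids, lab$contig_id), fatal = FALSE),
    tibble(issue = "label_without_contig", id = setdiff(lab$contig_id, ids), fatal = FALSE)
  )
  for (i in seq_len(nrow(report))) {
    warn(sprintf("%s: %s", report$issue[i], report$id[i]))
  }
  report
}
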