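#' Read CDS records from a FASTA file
#'
#' Each FASTA entry becomes one \code{\link{cds_record}}; the header token
#' before the first whitespace is the record id. Sequences are cleaned and
#' framed on read (see \code{\link{clean_and_frame}}).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param policy Cleaning policy passed to \code{\link{clean_and_frame}}.
#' @param class_label Optional class label applied to all records.
#' @return Named list of \code{cds_record}s keyed by id.
#' @export
read_cds_fasta <- function(path, policy = c("exclude", "strict"),
                           class_label = NA_character_) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  recs <- lapply(seq_along(seqs), function(i) {
    cds_record(ids[i], as.character(seqs[[i]]), class_label = class_label,
               policy = policy)
  })
  names(recs) <- ids
  recs
}

#' Write CDS records to a FASTA file
#'
#' @param records Named list of \code{cds_record}s or a named character
#'   vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cds_fasta <- function(records, path) {
  if (is.list(records)) {
    seqs <- vapply(records, function(r) r$raw_sequence, character(1))
    names(seqs) <- vapply(records, function(r) r$id, character(1))
  } else {
    seqs <- records
  }
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Load a pair manifest
#'
#' The manifest is a TSV with header columns \code{pair_id}, \code{ext_id},
#' \code{ctl_id} linking each extremophile CDS to its non-extremophile
#' homolog. When \code{records} is supplied every referenced id must
#' resolve.
#'
#' @param path Path to the TSV manifest.
#' @param records Optional named list of \code{cds_record}s for id
#'   validation.
#' @param dataset_label Label of the comparing dataset (e.g. \code{"T-M"}).
#' @return Object of class \code{pair_manifest}: data.frame with columns
#'   \code{pair_id}, \code{ext_id}, \code{ctl_id} and a
#'   \code{dataset_label} attribute.
#' @export
load_manifest <- function(path, records = NULL, dataset_label = "dataset") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse manifest %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  needed <- c("pair_id", "ext_id", "ctl_id")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop("manifest has no rows", call. = FALSE)
  if (anyDuplicated(df$pair_id)) {
    stop(sprintf("duplicate pair_id(s): %s",
                 paste(unique(df$pair_id[duplicated(df$pair_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  df <- df[, needed]
  if (!is.null(records)) {
    .check_manifest_ids(df, records)
  }
  structure(df, dataset_label = dataset_label, class = c("pair_manifest",
                                                         "data.frame"))
}

.check_manifest_ids <- function(df, records) {
  for (col in c("ext_id", "ctl_id")) {
    bad <- !(df[[col]] %in% names(records))
    if (any(bad)) {
      stop(sprintf("manifest %s not found in FASTA (pair_id %s): %s",
                   col, paste(df$pair_id[bad], collapse = ", "),
                   paste(df[[col]][bad], collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assemble a paired codon-frequency dataset
#'
#' Builds the two N x 64 percentage matrices (extremophile class and its
#' counterpart) whose row i in both matrices corresponds to the i-th
#' manifest pair. Columns follow the canonical codon order. N is the number
#' of homologous pairs in the comparing dataset.
#'
#' @param manifest A \code{pair_manifest}.
#' @param records Named list of \code{cds_record}s resolving every
#'   manifest id.
#' @param dataset_label Optional override of the manifest's label.
#' @param label_e,label_ne Class labels for the two sides (defaults
#'   \code{"extremophile"} / \code{"non-extremophile"}).
#' @return Object of class \code{paired_dataset}: list with
#'   \code{dataset_label}, \code{n_pairs}, \code{pair_ids},
#'   \code{matrix_e}, \code{matrix_ne} (both N x 64 percentages),
#'   \code{label_e}, \code{label_ne}.
#' @export
build_paired_dataset <- function(manifest, records, dataset_label = NULL,
                                 label_e = "extremophile",
                                 label_ne = "non-extremophile") {
  .check_manifest_ids(manifest, records)
  if (is.null(dataset_label)) {
    dataset_label <- attr(manifest, "dataset_label")
    if (is.null(dataset_label)) dataset_label <- "dataset"
  }
  freq_row <- function(id) count_codons(records[[id]]$codons)$percentages
  me <- t(vapply(manifest$ext_id, freq_row, numeric(64)))
  mn <- t(vapply(manifest$ctl_id, freq_row, numeric(64)))
  rownames(me) <- rownames(mn) <- manifest$pair_id
  colnames(me) <- colnames(mn) <- .codons()
  structure(
    list(dataset_label = dataset_label,
         n_pairs = nrow(manifest),
         pair_ids = manifest$pair_id,
         matrix_e = me, matrix_ne = mn,
         label_e = label_e, label_ne = label_ne),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %s: %d homologous pairs x 64 codons (%s vs %s)\n",
              x$dataset_label, x$n_pairs, x$label_e, x$label_ne))
  invisible(x)
}

#' Write a data.frame as a TSV table
#'
#' UTF-8, '.' decimal separator, header row, no row names; the standard
#' tabular output dialect of the package.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
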