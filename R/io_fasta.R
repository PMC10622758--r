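#' Read labelled protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) protein FASTA file into a record table.
#' Sequences are uppercased, a trailing stop character `*` is removed, and
#' non-standard residues are handled by `residue_policy`:
#'
#' * `"strip"` (default): characters outside the 20 standard amino-acid
#'   letters (e.g. B, J, O, U, X, Z, gaps) are deleted and a warning reports
#'   how many were removed. A record whose sequence becomes empty is an error.
#' * `"reject"`: any non-standard character fails the whole read, naming the
#'   offending record.
#'
#' Class labels are assigned from the `label` argument (one FASTA file per
#' class), not parsed from headers.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label for every record in the file
#'   (1 = allergenic, 0 = non-allergenic). `NULL` for prediction-only input.
#' @param residue_policy `"strip"` or `"reject"`.
#' @return A `data.frame` with columns `id` (first whitespace-delimited header
#'   token), `sequence` and `label` (`NA` when unlabelled), in file order.
#' @export
read_fasta <- function(path, label = NULL, residue_policy = c("strip", "reject")) {
  residue_policy <- match.arg(residue_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no FASTA records in ", path)

  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])

  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  records <- data.frame(id = ids, sequence = seqs,
                        stringsAsFactors = FALSE, row.names = NULL)
  records <- apply_residue_policy(records, residue_policy)

  if (!is.null(label)) {
    label <- as.integer(label)
    if (!label %in% c(0L, 1L)) stop("`label` must be 0 or 1")
    records$label <- label
  } else {
    records$label <- NA_integer_
  }
  records
}

# internal: enforce the 20-letter alphabet on a record table
apply_residue_policy <- function(records, residue_policy) {
  pattern <- paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]")
  bad <- grepl(pattern, records$sequence)
  if (any(bad)) {
    if (residue_policy == "reject")
      stop("non-standard residues in record: ", records$id[which(bad)[1L]])
    cleaned <- gsub(pattern, "", records$sequence[bad])
    n_removed <- nchar(records$sequence[bad]) - nchar(cleaned)
    warning(sprintf("stripped %d non-standard residue(s) from %d record(s)",
                    sum(n_removed), sum(bad)))
    records$sequence[bad] <- cleaned
  }
  empty <- !nzchar(records$sequence)
  if (any(empty))
    stop("sequence empty after residue filtering: ", records$id[which(empty)[1L]])
  records
}

#' Write protein records to a FASTA file
#'
#' Sequences are wrapped at 60 columns. Reading the file back with
#' [read_fasta()] reproduces ids and sequences exactly.
#'
#' @param records Record `data.frame` with columns `id` and `sequence`.
#' @param path Output file path.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) {
    if (!file.create(path)) stop("cannot write ", path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
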