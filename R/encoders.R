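#' @title Composition encoders
#' @description
#' The three sequence encoders share one convention: residues are indexed in
#' the fixed alphabetical order of [AA_ALPHABET20], feature names carry an
#' encoder prefix (`AAC:`, `DPC:`, `CKSAAP:k<g>:`) so fused matrices remain
#' auditable, and every row of an encoder output is a normalised frequency
#' vector.
#' @name encoders
NULL

# internal: validate a record table and split sequences into residue vectors
check_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) stop("no records to encode")
  if (anyDuplicated(records$id))
    stop("duplicate sequence id: ", records$id[duplicated(records$id)][1L])
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"),
               records$sequence)
  if (any(bad))
    stop("non-standard residues in record: ", records$id[which(bad)[1L]],
         " (apply a residue policy first, see read_fasta)")
  strsplit(records$sequence, "", fixed = TRUE)
}

record_labels <- function(records) {
  if ("label" %in% names(records) && !anyNA(records$label))
    as.integer(records$label) else NULL
}

# internal: count residue-pair occurrences (first member at position i, second
# at i + gap + 1) as a 400-vector in pair order
count_pairs <- function(chars, gap) {
  L <- length(chars)
  first <- factor(chars[seq_len(L - gap - 1L)], levels = AA_ALPHABET20)
  second <- factor(chars[seq_len(L - gap - 1L) + gap + 1L], levels = AA_ALPHABET20)
  tabulate((as.integer(first) - 1L) * 20L + as.integer(second), nbins = 400L)
}

#' Amino acid composition (AAC) encoder
#'
#' Encodes each sequence as the 20-vector of residue frequencies: the count
#' of each amino acid divided by the sequence length. Rows sum to 1.
#'
#' @param records Record `data.frame` with columns `id`, `sequence` and
#'   optionally `label` (see [read_fasta()]).
#' @return A [feature_matrix()] with 20 columns `AAC:A` ... `AAC:Y`.
#' @export
encode_aac <- function(records) {
  char_list <- check_records(records)
  values <- t(vapply(char_list, function(chars) {
    tabulate(factor(chars, levels = AA_ALPHABET20), nbins = 20L) / length(chars)
  }, numeric(20L)))
  dimnames(values) <- list(records$id, paste0("AAC:", AA_ALPHABET20))
  feature_matrix(values, labels = record_labels(records))
}

#' Dipeptide composition (DPC) encoder
#'
#' Encodes each sequence as the 400-vector of overlapping 2-mer frequencies:
#' the count of each ordered residue pair divided by the number of dipeptide
#' positions, L - 1. Rows sum to 1. Requires length >= 2.
#'
#' @inheritParams encode_aac
#' @return A [feature_matrix()] with 400 columns `DPC:AA` ... `DPC:YY`
#'   (first residue varying slowest).
#' @export
encode_dpc <- function(records) {
  char_list <- check_records(records)
  short <- lengths(char_list) < 2L
  if (any(short))
    stop("sequence shorter than 2 residues: ", records$id[which(short)[1L]])
  values <- t(vapply(char_list, function(chars) {
    count_pairs(chars, gap = 0L) / (length(chars) - 1L)
  }, numeric(400L)))
  dimnames(values) <- list(records$id, paste0("DPC:", aa_pairs()))
  feature_matrix(values, labels = record_labels(records))
}

#' Composition of k-spaced amino acid pairs (CKSAAP) encoder
#'
#' For each gap value k, counts ordered residue pairs separated by exactly k
#' intervening residues (the pair occupies positions i and i + k + 1) and
#' divides by the number of such pair positions, L - k - 1. Each per-gap
#' block of 400 columns sums to 1 per row. With the default gaps 1, 2, 3 the
#' encoder emits 1200 features. Requires length >= max(gaps) + 2.
#'
#' @inheritParams encode_aac
#' @param gaps Positive integers: numbers of intervening residues to count.
#' @return A [feature_matrix()] with `400 * length(gaps)` columns named
#'   `CKSAAP:k<g>:A.A` ... `CKSAAP:k<g>:Y.Y`, blocks ordered by gap.
#' @export
encode_cksaap <- function(records, gaps = c(1L, 2L, 3L)) {
  gaps <- as.integer(gaps)
  if (length(gaps) == 0L || any(gaps < 1L) || anyDuplicated(gaps))
    stop("`gaps` must be distinct positive integers")
  char_list <- check_records(records)
  max_gap <- max(gaps)
  short <- lengths(char_list) < max_gap + 2L
  if (any(short))
    stop("sequence too short for gap ", max_gap, ": ",
         records$id[which(short)[1L]])
  blocks <- lapply(gaps, function(g) {
    t(vapply(char_list, function(chars) {
      count_pairs(chars, gap = g) / (length(chars) - g - 1L)
    }, numeric(400L)))
  })
  values <- do.call(cbind, blocks)
  cols <- unlist(lapply(gaps, function(g)
    paste0("CKSAAP:k", g, ":", aa_pairs(sep = "."))))
  dimnames(values) <- list(records$id, cols)
  feature_matrix(values, labels = record_labels(records))
}

#' Fuse feature matrices by column concatenation
#'
#' Concatenates encoder outputs for the same samples into one wide matrix.
#' All inputs must list identical sample ids in identical order and have
#' disjoint feature names. Fusing the three default encoders yields
#' 20 + 400 + 1200 = 1620 columns.
#'
#' @param matrices List of [feature_matrix()] objects.
#' @return A single [feature_matrix()].
#' @export
fuse_features <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ref <- matrices[[1L]]
  for (m in matrices[-1L]) {
    if (nrow(m$values) != nrow(ref$values))
      stop("sample id mismatch: matrices have ", nrow(ref$values), " vs ",
           nrow(m$values), " samples")
    mismatch <- which(m$sample_ids != ref$sample_ids)
    if (length(mismatch))
      stop("sample id mismatch at position ", mismatch[1L], ": expected `",
           ref$sample_ids[mismatch[1L]], "`, got `", m$sample_ids[mismatch[1L]], "`")
  }
  all_names <- unlist(lapply(matrices, `[[`, "feature_names"))
  if (anyDuplicated(all_names))
    stop("duplicated feature name across matrices: ",
         all_names[duplicated(all_names)][1L])
  labels <- Filter(Negate(is.null), lapply(matrices, `[[`, "labels"))
  feature_matrix(do.call(cbind, lapply(matrices, `[[`, "values")),
                 labels = if (length(labels)) labels[[1L]] else NULL)
}

#' Encode records with a set of encoders and fuse the result
#'
#' Convenience wrapper running [encode_aac()], [encode_dpc()] and
#' [encode_cksaap()] (in that column order) and fusing the outputs; the
#' default configuration produces the 1620-feature fused representation.
#'
#' @inheritParams encode_aac
#' @param encoders Character subset of `c("AAC", "DPC", "CKSAAP")`.
#' @param gaps CKSAAP gap values.
#' @return A [feature_matrix()].
#' @export
encode_fused <- function(records, encoders = c("AAC", "DPC", "CKSAAP"),
                         gaps = c(1L, 2L, 3L)) {
  encoders <- match.arg(encoders, several.ok = TRUE)
  parts <- list()
  if ("AAC" %in% encoders) parts <- c(parts, list(encode_aac(records)))
  if ("DPC" %in% encoders) parts <- c(parts, list(encode_dpc(records)))
  if ("CKSAAP" %in% encoders) parts <- c(parts, list(encode_cksaap(records, gaps)))
  fuse_features(parts)
}
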