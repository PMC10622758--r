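#' Specification for a synthetic two-class sequence dataset
#'
#' Describes a generative model for labelled protein sequences in which the
#' class signal is a controllable shift in residue composition, optionally
#' augmented with a dipeptide motif enriched in positives. Sequences are
#' drawn i.i.d. per residue: negatives from `base_frequencies`, positives
#' from a perturbed copy in which the frequencies of `effect_residues` are
#' multiplied by `1 + effect_size` and the vector renormalised. With
#' `effect_size = 0` and no motif the classes are exchangeable (a null
#' dataset). The i.i.d. model carries no sequence-order signal, so the
#' motif channel is the only way positives can differ at the dipeptide
#' level without differing in single-residue composition.
#'
#' @param n_per_class Sequences per class.
#' @param length_range Integer `(min, max)`; lengths are uniform in this
#'   range. `min` must be at least 5 so the largest default CKSAAP gap fits.
#' @param base_frequencies 20-simplex residue frequency vector, in
#'   [AA_ALPHABET20] order (default [AA_BACKGROUND]).
#' @param effect_size Non-negative multiplicative perturbation applied to
#'   `effect_residues` in the positive class (1 doubles them).
#' @param effect_residues Residues carrying the compositional signal.
#' @param motif Optional dipeptide string inserted into positive sequences.
#' @param motif_rate Expected insertions per positive sequence (Poisson).
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 200L,
                           length_range = c(50L, 300L),
                           base_frequencies = AA_BACKGROUND,
                           effect_size = 1,
                           effect_residues = c("A", "C"),
                           motif = NULL, motif_rate = 0,
                           seed = 1L) {
  length_range <- as.integer(length_range)
  stopifnot(n_per_class >= 1L, length(length_range) == 2L,
            length_range[1L] >= 5L, length_range[1L] <= length_range[2L],
            effect_size >= 0, motif_rate >= 0)
  if (length(base_frequencies) != 20L || any(base_frequencies < 0) ||
      abs(sum(base_frequencies) - 1) > 1e-8)
    stop("`base_frequencies` must be a 20-vector on the simplex")
  if (!all(effect_residues %in% AA_ALPHABET20))
    stop("`effect_residues` must be standard amino-acid letters")
  if (!is.null(motif) &&
      (!is.character(motif) || nchar(motif) < 2L ||
       grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), motif)))
    stop("`motif` must be a string of >= 2 standard residues")
  structure(
    list(n_per_class = as.integer(n_per_class), length_range = length_range,
         base_frequencies = stats::setNames(as.numeric(base_frequencies),
                                            AA_ALPHABET20),
         effect_size = effect_size, effect_residues = effect_residues,
         motif = motif, motif_rate = motif_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Class-specific residue frequencies implied by a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return List with 20-simplex vectors `negative` and `positive`.
#' @export
class_frequencies <- function(spec) {
  neg <- spec$base_frequencies
  pos <- neg
  pos[spec$effect_residues] <- pos[spec$effect_residues] * (1 + spec$effect_size)
  pos <- pos / sum(pos)
  list(negative = neg, positive = pos)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` negative then `n_per_class` positive sequences under
#' the generative model of [synthetic_spec()]. Motif copies, when
#' configured, overwrite residues at Poisson-many uniformly chosen positions
#' of each positive sequence. Fully reproducible from the spec (including
#' its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return A record `data.frame` with columns `id` (`neg_...`/`pos_...`),
#'   `sequence` and `label`.
#' @export
generate_records <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  freqs <- class_frequencies(spec)
  set.seed(spec$seed)
  draw_class <- function(freq, prefix, with_motif) {
    lengths <- sample(seq(spec$length_range[1L], spec$length_range[2L]),
                      spec$n_per_class, replace = TRUE)
    seqs <- vapply(lengths, function(L) {
      chars <- sample(AA_ALPHABET20, L, replace = TRUE, prob = freq)
      if (with_motif && !is.null(spec$motif) && spec$motif_rate > 0) {
        m <- strsplit(spec$motif, "")[[1L]]
        n_ins <- stats::rpois(1L, spec$motif_rate)
        if (n_ins > 0L && L >= length(m)) {
          starts <- sample(L - length(m) + 1L, min(n_ins, L - length(m) + 1L))
          for (s in starts) chars[s:(s + length(m) - 1L)] <- m
        }
      }
      paste(chars, collapse = "")
    }, character(1))
    data.frame(id = sprintf("%s_%04d", prefix, seq_len(spec$n_per_class)),
               sequence = seqs,
               label = if (prefix == "pos") 1L else 0L,
               stringsAsFactors = FALSE)
  }
  rbind(draw_class(freqs$negative, "neg", with_motif = FALSE),
        draw_class(freqs$positive, "pos", with_motif = TRUE))
}

#' Pooled empirical residue frequencies of a record set
#'
#' Counts residues across all sequences and returns the pooled frequency
#' vector — useful for building realistic null generators from any dataset.
#'
#' @param records Record `data.frame` with a `sequence` column.
#' @return Named 20-simplex vector in [AA_ALPHABET20] order.
#' @export
empirical_frequencies <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  chars <- unlist(strsplit(records$sequence, "", fixed = TRUE))
  counts <- table(factor(chars, levels = AA_ALPHABET20))
  as.numeric(counts / sum(counts)) |> stats::setNames(AA_ALPHABET20)
}

#' Write a synthetic dataset as one FASTA file per class
#'
#' @param records Labelled record `data.frame`.
#' @param pos_path,neg_path Output FASTA paths for positives and negatives.
#' @export
write_class_fasta <- function(records, pos_path, neg_path) {
  write_fasta(records[records$label == 1L, , drop = FALSE], pos_path)
  write_fasta(records[records$label == 0L, , drop = FALSE], neg_path)
  invisible(c(pos_path, neg_path))
}
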