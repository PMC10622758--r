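# Independent brute-force oracles. These deliberately use plain loops and
# none of the package's counting code, so agreement with the encoders and
# curve functions is a genuine two-route check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_aac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  names(out) <- AA20
  for (ch in chars) out[ch] <- out[ch] + 1
  out / length(chars)
}

oracle_pair_freq <- function(seq, gap) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  pairs <- character(0)
  for (a in AA20) for (b in AA20) pairs <- c(pairs, paste0(a, b))
  out <- stats::setNames(numeric(400), pairs)
  n_pos <- L - gap - 1
  for (i in seq_len(n_pos))
    out[paste0(chars[i], chars[i + gap + 1])] <-
      out[paste0(chars[i], chars[i + gap + 1])] + 1
  out / n_pos
}

oracle_dpc <- function(seq) oracle_pair_freq(seq, gap = 0)

# AUC as exhaustive pairwise concordance, ties scoring 0.5
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

random_records <- function(n, len_range = c(10L, 60L), seed = 1L,
                           labels = NULL) {
  set.seed(seed)
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(
    id = sprintf("s%03d", seq_len(n)),
    sequence = vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1)),
    label = if (is.null(labels)) NA_integer_ else labels,
    stringsAsFactors = FALSE
  )
}

# small labelled feature matrix with one informative column
toy_labelled_fm <- function(n_per_class = 20L, p_noise = 5L, seed = 1L,
                            separation = 3) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_class)
  n <- length(labels)
  values <- matrix(rnorm(n * (p_noise + 1L)), nrow = n)
  values[, 1L] <- values[, 1L] + separation * labels
  dimnames(values) <- list(sprintf("t%03d", seq_len(n)),
                           c("signal", sprintf("noise%d", seq_len(p_noise))))
  feature_matrix(values, labels = labels)
}
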