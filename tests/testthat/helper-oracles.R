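# Independent oracles kept deliberately naive: they re-derive the target
# quantity by direct enumeration, never via the package's computational
# path.

# Brute-force mean pairwise differences: explicit double loop over pairs.
brute_force_pi <- function(mat) {
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(mat[i, ] != mat[j, ])
    }
  }
  total / (n * (n - 1) / 2)
}

# Random gap-free alignment as a character matrix.
random_alignment_matrix <- function(n, L, n_states = 4) {
  bases <- c("A", "C", "G", "T")[seq_len(n_states)]
  matrix(sample(bases, n * L, replace = TRUE), nrow = n,
         dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
}

matrix_to_core <- function(mat, locus_id = "rand") {
  structure(
    list(locus_id = locus_id, seq = mat,
         kept_columns = seq_len(ncol(mat)), L = ncol(mat)),
    class = "core_alignment"
  )
}

random_locus <- function(n, L, locus_id = "rand") {
  mat <- random_alignment_matrix(n, L)
  seqs <- apply(mat, 1, paste, collapse = "")
  aligned_locus(locus_id, seqs)
}

# Brute-force antiparallel penalty of one window, character by character,
# written as a direct transcription of the pairing rules.
brute_force_window_penalty <- function(mirna_chars, site_chars) {
  k <- length(mirna_chars)
  total <- 0
  for (i in seq_len(k)) {
    m <- mirna_chars[i]
    t <- site_chars[k - i + 1]
    wc <- (m == "A" && t == "T") || (m == "T" && t == "A") ||
      (m == "G" && t == "C") || (m == "C" && t == "G")
    gu <- (m == "G" && t == "T") || (m == "T" && t == "G")
    total <- total + if (wc) 0 else if (gu) 0.5 else 1
  }
  total
}

# Enumerate every window of every transcript and keep those within the cap.
brute_force_scan <- function(mirna, transcripts, max_penalty) {
  m <- strsplit(gsub("U", "T", toupper(mirna)), "")[[1]]
  k <- length(m)
  hits <- list()
  for (tx in names(transcripts)) {
    chars <- strsplit(gsub("U", "T", toupper(transcripts[[tx]])), "")[[1]]
    if (length(chars) < k) next
    for (s in seq_len(length(chars) - k + 1)) {
      pen <- brute_force_window_penalty(m, chars[s:(s + k - 1)])
      if (pen <= max_penalty) {
        hits[[length(hits) + 1]] <- data.frame(
          transcript_id = tx, site_start = s, penalty = pen,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(transcript_id = character(0), site_start = integer(0),
               penalty = numeric(0), stringsAsFactors = FALSE)
}

# Random DNA string
random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
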