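# Shared fixtures: everything is generated in code, nothing on disk.

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# A small labeled record set with real cluster structure, cheap to encode.
tiny_records <- function(seed = 7, n_families = 3, members = 8, L = 120) {
  generate_families(n_families = n_families, members_per_family = members,
                    seq_length = L, seed = seed)
}

# Independent enumeration of all words of length l in the canonical order
# (A < T < C < G), built by base-4 counting — no package code involved.
enumerate_words <- function(l) {
  digits <- c("A", "T", "C", "G")
  out <- character(4^l)
  for (i in seq_len(4^l)) {
    v <- i - 1L
    w <- character(l)
    for (pos in l:1) {
      w[pos] <- digits[v %% 4L + 1L]
      v <- v %/% 4L
    }
    out[i] <- paste(w, collapse = "")
  }
  out
}

# Naive dictionary-count document vector: substring every window, look the
# word up in the enumerated dictionary. The brute-force oracle.
naive_docvec <- function(s, l) {
  words <- enumerate_words(l)
  counts <- stats::setNames(numeric(length(words)), words)
  for (start in 1:(nchar(s) - l + 1)) {
    w <- substr(s, start, start + l - 1)
    if (w %in% words) counts[w] <- counts[w] + 1
  }
  counts
}

# Naive O(N^2) silhouette, straight from the definition.
naive_silhouette <- function(coords, labels) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { widths[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(lb)
      mean(D[i, labels == lb]), numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# An ae_params object with all-zero weights and biases, for closed-form
# checks of forward passes.
zero_ae_params <- function(n_in, n_hidden, ...) {
  p <- init_ae(layer_spec(n_in, n_hidden, ...), seed = 1)
  p$W_enc[] <- 0; p$W_dec[] <- 0
  p
}
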