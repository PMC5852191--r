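#' One-hot encode a DNA sequence
#'
#' Replaces each base by its 4-digit indicator vector and concatenates along
#' the sequence, using the fixed base order (A, T, C, G):
#' `A -> 1000`, `T -> 0100`, `C -> 0010`, `G -> 0001`.  A sequence of length
#' L becomes a binary vector of length `4 * L` (822 bp -> 3288).
#'
#' @param bases A single DNA string over `{A, C, G, T}` (case-insensitive),
#'   or a one-row record as returned by [generate_families()].
#' @param strict If `TRUE` (default), any character outside `{A, C, G, T}`
#'   is an error.  If `FALSE`, the offending position gets an all-zero
#'   4-block and is reported in the `masked` attribute.
#' @return A numeric 0/1 vector of length `4 * nchar(bases)` with attributes
#'   `base_order` and (in lenient mode) `masked`, the 1-based positions that
#'   were zeroed out.
#' @seealso [decode_one_hot()], [encode_dataset()]
#' @examples
#' encode_one_hot("ATCG")
#' @export
encode_one_hot <- function(bases, strict = TRUE) {
  bases <- as_base_string(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  idx <- match(chars, BASE_ORDER)
  bad <- which(is.na(idx))
  if (length(bad) > 0L && strict) {
    stop("non-ACGT character(s) at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "",
         " (use strict = FALSE to mask them)", call. = FALSE)
  }
  m <- matrix(0, nrow = 4L, ncol = length(chars))
  ok <- which(!is.na(idx))
  m[cbind(idx[ok], ok)] <- 1
  out <- as.vector(m)
  attr(out, "base_order") <- BASE_ORDER
  if (length(bad) > 0L) attr(out, "masked") <- bad
  out
}

#' Decode a one-hot vector back to a DNA string
#'
#' Inverse of [encode_one_hot()]: every consecutive 4-block must be a valid
#' single-base indicator (or all-zero in lenient mode, decoded as `"N"`).
#'
#' @param vec Numeric vector whose length is divisible by 4.
#' @param lenient If `TRUE`, an all-zero block decodes to `"N"`; otherwise it
#'   is an error.
#' @return A single DNA string; `decode_one_hot(encode_one_hot(s))`
#'   equals `s` for any ACGT string `s`.
#' @export
decode_one_hot <- function(vec, lenient = FALSE) {
  vec <- as.numeric(vec)
  if (length(vec) == 0L || length(vec) %% 4L != 0L) {
    stop("one-hot vector length must be a positive multiple of 4",
         call. = FALSE)
  }
  m <- matrix(vec, nrow = 4L)
  ones <- colSums(m == 1)
  zeros <- colSums(m == 0)
  is_digit <- ones == 1L & zeros == 3L
  is_blank <- zeros == 4L
  bad <- which(!(is_digit | (lenient & is_blank)))
  if (length(bad) > 0L) {
    stop("malformed one-hot block at sequence position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  chars <- rep("N", ncol(m))
  chars[is_digit] <- BASE_ORDER[apply(m[, is_digit, drop = FALSE] == 1,
                                      2L, which.max)]
  paste(chars, collapse = "")
}

#' Index of a k-mer word in the canonical enumeration
#'
#' Words of length `l` are enumerated with the fixed digit map
#' `A -> 0, T -> 1, C -> 2, G -> 3` read as a base-4 number, i.e. the order
#' `"AAAA", "AAAT", "AAAC", "AAAG", ..., "GGGC", "GGGG"` for `l = 4`.
#'
#' @param word Character vector of words, all of length `l`, over
#'   `{A, T, C, G}`.
#' @param l Word length.
#' @return Integer vector of 0-based indices in `[0, 4^l - 1]`.
#' @seealso [kmer_words()] for the full enumeration.
#' @examples
#' word_index(c("AAAA", "AAAT", "GGGG"), 4)
#' @export
word_index <- function(word, l) {
  stopifnot_scalar_count(l, "l")
  if (any(nchar(word) != l)) {
    stop("all words must have length l = ", l, call. = FALSE)
  }
  chars <- strsplit(toupper(word), "", fixed = TRUE)
  digits <- match(unlist(chars), BASE_ORDER) - 1L
  if (anyNA(digits)) {
    stop("words must contain only A, C, G, T", call. = FALSE)
  }
  m <- matrix(digits, nrow = l)
  as.integer(colSums(m * 4^((l - 1L):0L)))
}

#' All k-mer words of length `l` in canonical order
#'
#' @param l Word length (`4^l` words are returned; kept small, `l <= 8`).
#' @return Character vector of `4^l` words such that
#'   `word_index(kmer_words(l), l) == 0:(4^l - 1)`.
#' @export
kmer_words <- function(l) {
  stopifnot_scalar_count(l, "l")
  if (l > 8) stop("l > 8 not supported (4^l words would be too many)",
                  call. = FALSE)
  grid <- expand.grid(rep(list(BASE_ORDER), l),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the FIRST factor fastest; we need the LAST position
  # of the word to vary fastest, so build words with reversed columns.
  do.call(paste0, rev(grid))
}

#' Document-vector (k-mer histogram) encoding of a DNA sequence
#'
#' Slides a window of length `l` along the sequence and counts how often
#' each of the `4^l` possible words occurs.  In overlapping mode (the
#' default) the window advances one base at a time, giving `L - l + 1`
#' windows for a length-`L` sequence; in non-overlapping mode it advances
#' `l` bases.  Windows containing a non-ACGT character are skipped and
#' counted as invalid.  With `l = 5` the histogram has 1024 entries and is
#' independent of sequence length, which is what makes this representation
#' usable across loci of different sizes.
#'
#' @param bases A single DNA string (or one-row record), length `>= l`.
#' @param l Word length (default 5).
#' @param mode `"overlapping"` (default) or `"nonoverlapping"`.
#' @param normalize If `TRUE` (default), counts are divided by the number of
#'   valid windows so entries sum to 1; if `FALSE`, raw integer counts are
#'   returned.
#' @return Numeric vector of length `4^l`, named by [kmer_words()] for
#'   `l <= 6`, with attributes `word_length`, `mode`, `normalized` and
#'   `n_windows` (the number of valid windows counted).
#' @examples
#' v <- encode_docvec("ACGTACGT", l = 5, normalize = FALSE)
#' sum(v)  # 4 valid windows
#' @export
encode_docvec <- function(bases, l = 5,
                          mode = c("overlapping", "nonoverlapping"),
                          normalize = TRUE) {
  bases <- toupper(as_base_string(bases))
  mode <- match.arg(mode)
  stopifnot_scalar_count(l, "l")
  L <- nchar(bases)
  if (L < l) {
    stop("sequence length (", L, ") is shorter than the word length l = ",
         l, call. = FALSE)
  }
  step <- if (mode == "overlapping") 1L else as.integer(l)
  starts <- seq.int(1L, L - l + 1L, by = step)
  words <- substring(bases, starts, starts + l - 1L)
  valid <- !grepl("[^ATCG]", words)
  if (!any(valid)) {
    stop("no valid ACGT window of length ", l, " in the sequence",
         call. = FALSE)
  }
  idx <- word_index(words[valid], l)
  counts <- tabulate(idx + 1L, nbins = 4L^l)
  out <- if (normalize) counts / sum(counts) else as.numeric(counts)
  if (l <= 6) names(out) <- kmer_words(l)
  structure(out,
            word_length = as.integer(l), mode = mode,
            normalized = normalize, n_windows = sum(valid))
}

#' Encode a set of sequence records as a numeric matrix
#'
#' Applies one encoding scheme to every record and stacks the results into
#' an N x D matrix (rows in input order, rownames = ids) carrying the family
#' labels and scheme metadata needed by the downstream embedding and
#' plotting functions.
#'
#' @param records Data frame with columns `id`, `label`, `bases` (as
#'   produced by [generate_families()] or [read_fasta()]).
#' @param scheme `"onehot"` (requires all sequences to share one length;
#'   D = 4L) or `"docvec"` (D = `4^l`).
#' @param l Word length for the document-vector scheme.
#' @param mode,normalize Passed to [encode_docvec()].
#' @param strict Passed to [encode_one_hot()].
#' @return An `encoded_matrix`: a numeric matrix with attributes `scheme`,
#'   `labels` (aligned to rows) and `params`.
#' @examples
#' recs <- generate_families(n_families = 2, members_per_family = 3,
#'                           seq_length = 40, seed = 1)
#' dim(encode_dataset(recs, "docvec", l = 3))
#' @export
encode_dataset <- function(records, scheme = c("onehot", "docvec"), l = 5,
                           mode = c("overlapping", "nonoverlapping"),
                           normalize = TRUE, strict = TRUE) {
  validate_records(records)
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (scheme == "onehot") {
    lens <- nchar(records$bases)
    if (length(unique(lens)) > 1L) {
      ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
      off <- records$id[lens != ref]
      stop("one-hot encoding requires equal-length sequences; ",
           "offending id(s): ", paste(utils::head(off, 10L), collapse = ", "),
           if (length(off) > 10L) " ..." else "", call. = FALSE)
    }
    rows <- lapply(records$bases, encode_one_hot, strict = strict)
    params <- list(seq_length = lens[1])
  } else {
    rows <- lapply(records$bases, encode_docvec, l = l, mode = mode,
                   normalize = normalize)
    params <- list(l = as.integer(l), mode = mode, normalize = normalize)
  }
  X <- do.call(rbind, lapply(rows, as.numeric))
  rownames(X) <- records$id
  if (!is.null(names(rows[[1]]))) colnames(X) <- names(rows[[1]])
  encoded_matrix(X, scheme = scheme, labels = records$label, params = params)
}

encoded_matrix <- function(X, scheme, labels, params = list()) {
  stopifnot(is.matrix(X), length(labels) == nrow(X))
  structure(X, scheme = scheme, labels = labels, params = params,
            class = c("encoded_matrix", class(X)))
}

#' Family labels of an encoded matrix or embedding
#'
#' @param x An `encoded_matrix` or `embedding2d`.
#' @return Character vector of per-row labels.
#' @export
seq_labels <- function(x) {
  if (is.data.frame(x) && "label" %in% names(x)) return(x$label)
  attr(x, "labels")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("<encoded_matrix> %d sequences x %d dims (scheme: %s, %d labels)\n",
              nrow(x), ncol(x), attr(x, "scheme"),
              length(unique(attr(x, "labels")))))
  invisible(x)
}

# Accept either a plain string or a one-row records data frame.
as_base_string <- function(bases) {
  if (is.data.frame(bases)) {
    if (nrow(bases) != 1L || !"bases" %in% names(bases)) {
      stop("expected a single sequence (one-row data frame with a `bases` column)",
           call. = FALSE)
    }
    bases <- bases$bases
  }
  if (!is.character(bases) || length(bases) != 1L || !nzchar(bases)) {
    stop("`bases` must be one non-empty DNA string", call. = FALSE)
  }
  toupper(bases)
}
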