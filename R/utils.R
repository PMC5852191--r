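# Internal helpers shared across modules.

# Fixed base order used by BOTH encodings: one-hot digit rows and the
# k-mer word enumeration ("AAAA", "AAAT", "AAAC", "AAAG", ...).
# Note this is A, T, C, G -- not alphabetical.
BASE_ORDER <- c("A", "T", "C", "G")

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never clobber the user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != trunc(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
}

# Records are plain data frames with columns id, label, bases.
validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data.frame with columns id, label, bases",
         call. = FALSE)
  }
  need <- c("id", "label", "bases")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("`records` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("`records` contains no sequences", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(records$bases))) {
    stop("empty sequence(s): ",
         paste(records$id[!nzchar(records$bases)], collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}
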