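#' Generate synthetic allele-family DNA sequences
#'
#' Emulates the structure of a multi-allele locus dataset: one random
#' ancestral sequence; each family's founder carries
#' `floor(family_divergence * seq_length)` substitutions at positions that
#' are unique to that family (so families are separated in Hamming
#' distance); each member then receives `floor(within_noise * seq_length)`
#' further substitutions at random positions.  Substituted positions are
#' drawn without replacement and the replacement base uniformly from the
#' three alternatives.  Everything is determined by `seed`.
#'
#' The defaults (5 families of 40 members, 822 bp, 5\% family divergence,
#' 0.2\% within-family noise) define the package's standard benchmark: a
#' clean, strongly clustered dataset sized like a single HLA class-I locus
#' study.  For an imbalanced composition shaped like real per-allele sample
#' sizes, pass e.g. `members_per_family = hla_family_sizes`.
#'
#' @param n_families Number of families (ignored when `members_per_family`
#'   has length > 1).
#' @param members_per_family Either one count recycled to all families, or a
#'   vector of per-family counts.
#' @param seq_length Sequence length in bp.
#' @param family_divergence Fraction of positions substituted between the
#'   ancestor and each family founder.
#' @param within_noise Fraction of positions substituted between a founder
#'   and each member; must be smaller than `family_divergence`.
#' @param seed Integer seed; identical inputs give identical datasets.
#' @return Data frame with columns `id`, `label` (`"FAM1"`, `"FAM2"`, ...)
#'   and `bases`, one row per member; the ancestral sequence is attached as
#'   the `ancestor` attribute for validation.
#' @examples
#' recs <- generate_families(n_families = 3, members_per_family = 5,
#'                           seq_length = 60, seed = 7)
#' table(recs$label)
#' @export
generate_families <- function(n_families = 5, members_per_family = 40,
                              seq_length = 822, family_divergence = 0.05,
                              within_noise = 0.002, seed = 1) {
  stopifnot_scalar_count(n_families, "n_families", min = 2L)
  stopifnot_scalar_count(seq_length, "seq_length")
  if (length(members_per_family) == 1L) {
    members_per_family <- rep(members_per_family, n_families)
  }
  n_families <- length(members_per_family)
  for (m in members_per_family) stopifnot_scalar_count(m, "members_per_family")
  if (!is.numeric(family_divergence) || family_divergence <= 0 ||
      family_divergence > 1) {
    stop("`family_divergence` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(within_noise) || within_noise < 0 ||
      within_noise >= family_divergence) {
    stop("`within_noise` must satisfy 0 <= within_noise < family_divergence",
         call. = FALSE)
  }
  n_div <- floor(family_divergence * seq_length)
  n_noise <- floor(within_noise * seq_length)
  if (n_families * n_div > seq_length) {
    stop("family-diagnostic substitutions (", n_families, " x ", n_div,
         ") exceed the sequence length ", seq_length,
         "; lower `family_divergence` or fewer families", call. = FALSE)
  }

  with_seed(seed, {
    ancestor <- sample(BASE_ORDER, seq_length, replace = TRUE)
    # one global draw so each family's diagnostic positions are disjoint
    diag_pos <- sample.int(seq_length, n_families * n_div)
    out <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      founder <- ancestor
      pos <- diag_pos[((f - 1L) * n_div + 1L):(f * n_div)]
      founder[pos] <- substitute_bases(founder[pos])
      members <- character(members_per_family[f])
      for (m in seq_along(members)) {
        s <- founder
        if (n_noise > 0L) {
          npos <- sample.int(seq_length, n_noise)
          s[npos] <- substitute_bases(s[npos])
        }
        members[m] <- paste(s, collapse = "")
      }
      out[[f]] <- data.frame(
        id = sprintf("FAM%d_%03d", f, seq_along(members)),
        label = paste0("FAM", f),
        bases = members)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    # kept for validation: founder-to-ancestor distances are checkable
    attr(res, "ancestor") <- paste(ancestor, collapse = "")
    res
  })
}

# Replace each base by one of its three alternatives, uniformly.
substitute_bases <- function(bases) {
  offset <- sample.int(3L, length(bases), replace = TRUE)
  BASE_ORDER[(match(bases, BASE_ORDER) - 1L + offset) %% 4L + 1L]
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b DNA strings of equal length.
#' @return Integer count of mismatched positions.
#' @examples
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b) {
  a <- as_base_string(a); b <- as_base_string(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Per-allele sample sizes of a 12-allele HLA-A benchmark composition
#'
#' Named integer vector of the per-allele sequence counts (total 540) used
#' as the standard imbalanced composition for a single class-I locus; pass
#' it as `members_per_family` to [generate_families()] to obtain a dataset
#' shaped like a real per-allele sampling.
#'
#' @format Named integer vector of length 12.
#' @export
hla_family_sizes <- c(
  "A*01" = 30L, "A*02" = 164L, "A*03" = 28L, "A*11" = 60L,
  "A*23" = 12L, "A*24" = 96L, "A*26" = 41L, "A*29" = 15L,
  "A*30" = 20L, "A*31" = 30L, "A*32" = 14L, "A*33" = 30L)
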