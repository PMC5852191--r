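test_that("one-hot digits follow the fixed A,T,C,G base order", {
  expect_equal(as.numeric(encode_one_hot("A")), c(1, 0, 0, 0))
  expect_equal(as.numeric(encode_one_hot("T")), c(0, 1, 0, 0))
  expect_equal(as.numeric(encode_one_hot("C")), c(0, 0, 1, 0))
  expect_equal(as.numeric(encode_one_hot("G")), c(0, 0, 0, 1))
  expect_equal(as.numeric(encode_one_hot("ATCG")),
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(length(encode_one_hot(random_dna(50))), 200)
})

test_that("one-hot blocks are valid indicators and lenient mode masks", {
  set.seed(11)
  v <- encode_one_hot(random_dna(30))
  blocks <- matrix(v, nrow = 4)
  expect_true(all(colSums(blocks) == 1))
  expect_error(encode_one_hot("ACNGT"), "position")
  masked <- encode_one_hot("ACNGT", strict = FALSE)
  expect_equal(attr(masked, "masked"), 3L)
  expect_equal(sum(matrix(masked, nrow = 4)[, 3]), 0)
  expect_equal(decode_one_hot(masked, lenient = TRUE), "ACNGT")
})

test_that("decode inverts encode for random ACGT strings of many lengths", {
  expect_equal(decode_one_hot(c(1, 0, 0, 0)), "A")
  expect_equal(decode_one_hot(encode_one_hot("ACGTACGT")), "ACGTACGT")
  set.seed(42)
  for (L in c(1, 2, 3, sample(4:2000, 25))) {
    s <- random_dna(L)
    expect_equal(decode_one_hot(encode_one_hot(s)), s)
  }
  expect_error(decode_one_hot(c(1, 1, 0, 0)), "position")
  expect_error(decode_one_hot(c(1, 0, 0, 0, 0, 0, 0, 0)), "position.* 2")
  expect_error(decode_one_hot(c(1, 0, 0)), "multiple of 4")
})

test_that("word_index matches the printed enumeration and is bijective", {
  expect_equal(word_index("AAAA", 4), 0L)
  expect_equal(word_index("AAAT", 4), 1L)
  expect_equal(word_index("AAAC", 4), 2L)
  expect_equal(word_index("AAAG", 4), 3L)
  expect_equal(word_index("GGGC", 4), 254L)
  expect_equal(word_index("GGGG", 4), 255L)
  expect_equal(word_index("GGGGG", 5), 1023L)
  for (l in 2:5) {
    words <- enumerate_words(l)      # independent base-4 construction
    idx <- word_index(words, l)
    expect_equal(idx, 0:(4^l - 1))   # bijection onto [0, 4^l - 1], in order
    expect_equal(kmer_words(l), words)
  }
  expect_error(word_index("AAN", 3), "A, C, G, T")
  expect_error(word_index("AA", 3), "length")
})

test_that("document vectors count overlapping windows correctly", {
  v <- encode_docvec("AAAAA", l = 5, normalize = FALSE)
  expect_equal(sum(v), 1)
  expect_equal(as.numeric(v[1]), 1)  # index 0 = "AAAAA"

  v <- encode_docvec("ACGTACGT", l = 5, normalize = FALSE)
  expect_equal(sum(v), 4)            # 8 - 5 + 1 windows
  expect_equal(sort(names(v[v == 1])),
               sort(c("ACGTA", "CGTAC", "GTACG", "TACGT")))
  expect_equal(length(encode_docvec(random_dna(40), l = 5)), 1024)
})

test_that("docvec counts are conserved and match the brute-force oracle", {
  set.seed(3)
  for (i in 1:25) {
    L <- sample(10:200, 1)
    l <- sample(2:5, 1)
    s <- random_dna(L)
    raw <- encode_docvec(s, l = l, normalize = FALSE)
    expect_equal(sum(raw), L - l + 1)
    expect_equal(as.numeric(raw), as.numeric(naive_docvec(s, l)))
    expect_equal(sum(encode_docvec(s, l = l, normalize = TRUE)), 1)
  }
})

test_that("docvec agrees with Biostrings k-mer counting", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_dna(150)
    l <- sample(3:5, 1)
    mine <- encode_docvec(s, l = l, normalize = FALSE)
    bs <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                               width = l, step = 1)
    expect_equal(as.numeric(mine[names(bs)]), as.numeric(bs))
  }
})

test_that("docvec handles ambiguity and degenerate inputs", {
  v <- encode_docvec("ACGNACGT", l = 3, normalize = FALSE)
  expect_equal(sum(v), 3)            # windows 1, 5, 6 valid; 2-4 contain N
  expect_equal(attr(v, "n_windows"), 3L)
  expect_error(encode_docvec("ACG", l = 5), "shorter")
  expect_error(encode_docvec("NNNNNN", l = 5), "no valid")
  v2 <- encode_docvec("acgtacgt", l = 5, normalize = FALSE)
  expect_equal(sum(v2), 4)           # case-insensitive
  non <- encode_docvec("ACGTACGT", l = 4, mode = "nonoverlapping",
                       normalize = FALSE)
  expect_equal(sum(non), 2)
})

test_that("encode_dataset stacks rows in input order with labels aligned", {
  recs <- tiny_records(seed = 5)
  X <- encode_dataset(recs, "docvec", l = 5)
  expect_equal(dim(X), c(nrow(recs), 1024))
  expect_equal(rownames(X), recs$id)
  expect_equal(seq_labels(X), recs$label)
  expect_equal(as.numeric(X[4, ]),
               as.numeric(encode_docvec(recs$bases[4], l = 5)))

  Xoh <- encode_dataset(recs, "onehot")
  expect_equal(dim(Xoh), c(nrow(recs), 4 * 120))
  expect_equal(attr(Xoh, "scheme"), "onehot")
})

test_that("encode_dataset rejects bad input with specific messages", {
  recs <- tiny_records(seed = 5)
  recs$bases[3] <- substr(recs$bases[3], 1, 50)
  expect_error(encode_dataset(recs, "onehot"), recs$id[3], fixed = TRUE)
  expect_no_error(encode_dataset(recs, "docvec", l = 4))
  expect_error(encode_dataset(recs[0, ], "docvec"), "no sequences")
  recs2 <- tiny_records(seed = 5)
  recs2$id[2] <- recs2$id[1]
  expect_error(encode_dataset(recs2, "docvec"), "duplicate")
})
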