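test_that("FASTA and plain-text parsing normalizes, validates and preserves order", {
  f <- withr::local_tempfile(lines = c(">p1", "GIL", "DH", ">p2 some description", "acdef"))
  seqs <- read_peptides(f)
  expect_identical(unname(seqs), c("GILDH", "ACDEF"))
  expect_identical(names(seqs), c("p1", "p2"))

  expect_identical(unname(read_peptides("gildh")), "GILDH")
  expect_error(read_peptides(c(">p1", "GIX")), "'X' at position 3")
  expect_error(read_peptides(character(0)), "no sequences")
  expect_error(read_peptides(c("", "  ")), "no sequences")
  expect_error(validate_peptides("ACDU"), "'U' at position 4")
})

test_that("terminal regions keep N-to-C orientation", {
  expect_identical(terminal_region("ACDEFGHIKL", "N", 5), "ACDEF")
  expect_identical(terminal_region("ACDEFGHIKL", "C", 5), "GHIKL")
  expect_identical(terminal_region("ACDEF", "N", 5), "ACDEF")
  expect_error(terminal_region("ACD", "N", 5), "exceeds peptide length")
})

test_that("k-mer composition has fixed dimension and window-count normalization", {
  v1 <- kmer_composition(strrep("A", 10), 1)
  expect_length(v1, 20L)
  expect_equal(v1[["A"]], 1)
  expect_equal(sum(v1), 1)

  v2 <- kmer_composition("ACACA", 2)
  expect_length(v2, 400L)
  expect_equal(v2[["AC"]], 0.5)
  expect_equal(v2[["CA"]], 0.5)
  expect_equal(sum(v2 != 0), 2L)

  v3 <- kmer_composition("ACD", 3)
  expect_length(v3, 8000L)
  expect_equal(v3[["ACD"]], 1)

  expect_error(kmer_composition("AC", 3), "too short")
  # terminal-region composition equals composition of the extracted window
  expect_equal(kmer_composition("ACDEFGHIKL", 1, "nterm", 5),
               kmer_composition("ACDEF", 1))
  expect_equal(kmer_composition("ACDEFGHIKL", 2, "cterm", 5),
               kmer_composition("GHIKL", 2))
})

test_that("composition rows sum to one and are order-free; k-mer counts are consistent across k", {
  for (seed in 1:10) {
    p <- rand_peptides(1, 12, seed)
    for (k in 1:3) {
      v <- kmer_composition(p, k)
      expect_equal(sum(v), 1, tolerance = 1e-9)
      expect_true(all(v >= 0))
    }
    # k = 1 is invariant under reversal and permutation
    rev_p <- paste(rev(strsplit(p, "")[[1L]]), collapse = "")
    expect_identical(kmer_composition(p, 1), kmer_composition(rev_p, 1))
    expect_identical(kmer_composition(p, 1),
                     kmer_composition(shuffle_seq(p, seed), 1))
    # summing k = 2 features sharing a first letter recovers that letter's
    # k = 1 fraction up to the window bookkeeping bound 1/(L-1)
    v1 <- kmer_composition(p, 1)
    v2 <- kmer_composition(p, 2)
    first <- substr(names(v2), 1, 1)
    for (a in AA_ALPHABET) {
      expect_lt(abs(sum(v2[first == a]) - v1[[a]]), 1 / (12 - 1) + 1e-12)
    }
  }
})

test_that("binary profile is a one-hot encoding with Ala first and is invertible", {
  vA <- binary_profile("A")
  expect_identical(unname(vA), c(1, rep(0, 19)))

  p <- rand_peptides(1, 10, 3)
  v <- binary_profile(p)
  expect_length(v, 200L)
  blocks <- matrix(v, nrow = 20)
  expect_true(all(colSums(blocks) == 1))
  expect_true(all(v %in% c(0, 1)))
  expect_identical(decode_binary_profile(v), p)

  expect_length(binary_profile(rand_peptides(1, 16, 4)), 320L)
  expect_error(encode_peptides(c("ACDEF", "ACDEFG"), encoder("binary")),
               "uniform length")
})

test_that("dataset encoding is deterministic, aligned and has stable feature names", {
  ds <- simulate_hl_dataset(n = 189, length = 10, seed = 5)
  X <- encode_peptides(ds, encoder("dpc"))
  expect_identical(dim(X), c(189L, 400L))
  expect_identical(X, encode_peptides(ds, encoder("dpc")))

  # fixed lexicographic feature order (golden values)
  expect_identical(colnames(encode_peptides(ds$sequence[1], encoder("aac"))),
                   AA_ALPHABET)
  expect_identical(colnames(X)[1:3], c("AA", "AC", "AD"))
  expect_identical(colnames(X)[400], "YY")
  expect_identical(colnames(X)[69], "EK")
  Xb <- encode_peptides(ds, encoder("binary"))
  expect_identical(colnames(Xb)[1:2], c("p1.A", "p1.C"))
  expect_identical(colnames(Xb)[200], "p10.Y")

  # composition row is identical for a permuted peptide
  p <- ds$sequence[1]
  X2 <- encode_peptides(c(p, shuffle_seq(p, 7)), encoder("aac"))
  expect_equal(X2[1, ], X2[2, ])

  # per-record errors carry the record index
  expect_error(encode_peptides(c("ACDEF", "AC"), encoder("tpc")), "record 2")
})
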