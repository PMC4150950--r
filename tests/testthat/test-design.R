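test_that("mutant enumeration is complete, duplicate-free and ordered", {
  p <- rand_peptides(1, 10, 41)
  mut <- generate_mutants(p)
  expect_identical(nrow(mut), 190L)
  expect_identical(anyDuplicated(mut$mutant), 0L)
  expect_false(p %in% mut$mutant)
  # every mutant is at Hamming distance one from the parent
  pc <- strsplit(p, "")[[1L]]
  dists <- vapply(strsplit(mut$mutant, ""), function(mc)
    sum(mc != pc), numeric(1))
  expect_true(all(dists == 1))
  # position-major, residue-alphabetical order
  expect_identical(mut$position, rep(1:10, each = 19L))
  expect_identical(mut$substituted[mut$position == 1],
                   setdiff(AA_ALPHABET, pc[1]))

  m1 <- generate_mutants("A")
  expect_identical(nrow(m1), 19L)
  expect_false("A" %in% m1$mutant)
})

test_that("mutant ranking orders by prediction with documented tie-breaks", {
  ds <- toy_dataset(n = 10, seed = 43)
  # constant predictor: every mutant ties; order must be the tie-break
  const <- hlp_fit(ds, encoder("dpc"), learner = "dtable",
                   features = character(0))
  r <- rank_mutants(ds$sequence[1], const)
  expect_identical(r$mutants$position, rep(1:10, each = 19L))
  expect_false(any(r$mutants$improves_parent))
  expect_true(all(c("delta_net_charge_ph7", "delta_hydropathy") %in%
                    names(r$mutants)))

  # an instance-based model whose best training peptide is one specific
  # mutant: that mutant matches it at distance zero and must rank first
  parent <- strrep("A", 10)
  target_mut <- paste0("W", strrep("A", 9))   # position 1, A -> W
  set.seed(44)
  train <- hl_dataset(c(target_mut, rand_peptides(9, 10, 44)),
                      c(100, stats::runif(9, 0.1, 1)))
  m <- hlp_fit(train, encoder("dpc"), learner = "knn", k = 2,
               weighting = "inverse")
  top <- rank_mutants(parent, m, top = 5)
  expect_identical(nrow(top$mutants), 5L)
  expect_identical(top$mutants$mutant[1], target_mut)
  expect_equal(top$mutants$predicted_half_life_s[1], 100)
})

test_that("protein scanning produces all windows with 1-based inclusive coordinates", {
  ds <- toy_dataset(n = 10, seed = 45)
  m <- hlp_fit(ds, encoder("aac"), learner = "knn", k = 3)
  prot <- rand_peptides(1, 30, 46)
  sc <- scan_protein(prot, 10, m)
  expect_identical(nrow(sc$windows), 21L)
  expect_identical(sc$windows$start[1], 1L)
  expect_identical(sc$windows$end[21], 30L)
  expect_identical(sc$windows$subsequence[1], substr(prot, 1, 10))
  expect_identical(sc$windows$subsequence[21], substr(prot, 21, 30))
  # windows reassemble the protein: residues agree at every coordinate
  for (i in seq_len(nrow(sc$windows))) {
    expect_identical(sc$windows$subsequence[i],
                     substr(prot, sc$windows$start[i], sc$windows$end[i]))
  }
  expect_identical(sc$best$predicted_half_life_s,
                   max(sc$windows$predicted_half_life_s))

  whole <- scan_protein(prot, 30, m)
  expect_identical(nrow(whole$windows), 1L)
  expect_identical(whole$windows$subsequence, prot)
  expect_error(scan_protein(prot, 31, m), "exceeds protein length")
})

test_that("batch filtering respects thresholds, bounds and idempotence", {
  ds <- toy_dataset(n = 12, seed = 47)
  m <- hlp_fit(ds, encoder("aac"), learner = "knn", k = 3)
  peps <- rand_peptides(10, 10, 48)

  all_kept <- batch_filter(peps, m, min_half_life = 0)
  expect_identical(all_kept$n_kept, 10L)

  # kNN predictions cannot exceed the training maximum
  none <- batch_filter(peps, m, min_half_life = max(ds$half_life_s) + 1)
  expect_identical(none$n_kept, 0L)

  # net-charge constraint with hand-checkable signs: four basic peptides
  # (K-rich) are positive at pH 7, six acidic/neutral ones are not
  set.seed(48)
  basic <- vapply(1:4, function(i)
    paste0(strrep("K", 3), paste(sample(c("G", "A", "S", "L"), 7,
                                        replace = TRUE), collapse = "")),
    character(1))
  acidic <- vapply(1:6, function(i)
    paste0(strrep("E", 3), paste(sample(c("G", "S", "A", "D"), 7,
                                        replace = TRUE), collapse = "")),
    character(1))
  expect_true(all(vapply(basic, net_charge, numeric(1), pH = 7) > 0))
  expect_true(all(vapply(acidic, net_charge, numeric(1), pH = 7) < 0))
  b <- batch_filter(c(basic, acidic), m,
                    property_constraints = list(net_charge_ph7 = c(-Inf, 0)))
  expect_identical(b$n_kept, 6L)
  expect_setequal(b$kept$sequence, acidic)

  # filtering its own output changes nothing
  again <- batch_filter(b$kept$sequence, m,
                        property_constraints = list(net_charge_ph7 = c(-Inf, 0)))
  expect_identical(again$kept$sequence, b$kept$sequence)
  expect_identical(again$kept$predicted_half_life_s,
                   b$kept$predicted_half_life_s)

  expect_error(batch_filter(peps, m,
                            property_constraints = list(volume = c(2, 1))),
               "lower must not exceed upper")
  expect_error(batch_filter(peps, m,
                            property_constraints = list(bogus = c(0, 1))),
               "unknown property")
})
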