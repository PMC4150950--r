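test_that("kNN regression memorizes with k = 1 and degenerates to the mean with k >= n", {
  ds <- toy_dataset(n = 12)
  m1 <- hlp_fit(ds, encoder("dpc"), learner = "knn", k = 1)
  expect_equal(predict(m1, ds), ds$half_life_s)

  mall <- hlp_fit(ds, encoder("dpc"), learner = "knn", k = 12)
  q <- rand_peptides(3, 10, 999)
  expect_equal(predict(mall, q), rep(mean(ds$half_life_s), 3))

  # predictions always stay inside the training target range
  m3 <- hlp_fit(ds, encoder("dpc"), learner = "knn", k = 3)
  pred <- predict(m3, rand_peptides(20, 10, 1000))
  expect_true(all(pred >= min(ds$half_life_s) & pred <= max(ds$half_life_s)))
})

test_that("linear-kernel SVR recovers an exactly linear target", {
  seqs <- rand_peptides(40, 10, 9)
  X <- encode_peptides(seqs, encoder("aac"))
  set.seed(9)
  w <- stats::runif(20, -2, 2)
  y <- as.numeric(X %*% w)
  y <- y - min(y) + 1
  m <- hlp_fit(hl_dataset(seqs, y), encoder("aac"), learner = "svr",
               kernel = "linear", cost = 1e4, epsilon = 1e-5)
  expect_lt(max(abs(m$fitted_values - y) / abs(y)), 1e-3)
})

test_that("decision table predicts cell means with global-mean fallback", {
  # two well-separated clusters in one feature with distinct target levels
  seqs <- rand_peptides(6, 10, 21)
  X <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(10, 11, 12, 20, 21, 22)
  fit <- peplife:::fit_dtable(X, y, n_bins = 3)
  lo <- peplife:::dtable_keys(matrix(0, 1, 1), fit$cuts)
  hi <- peplife:::dtable_keys(matrix(1, 1, 1), fit$cuts)
  expect_equal(fit$cells[[lo]], 11)
  expect_equal(fit$cells[[hi]], 21)

  # query falling in an unseen cell combination returns the global mean
  X2 <- cbind(f1 = c(0, 0, 0, 1, 1, 1), f2 = c(0, 0, 0, 1, 1, 1))
  fit2 <- peplife:::fit_dtable(X2, y, n_bins = 3)
  unseen <- peplife:::dtable_keys(matrix(c(0, 1), 1, 2), fit2$cuts)
  expect_null(fit2$cells[[unseen]])

  # empty feature subset: every prediction is the training mean
  ds <- toy_dataset(n = 10)
  m0 <- hlp_fit(ds, encoder("dpc"), learner = "dtable",
                features = character(0))
  expect_equal(predict(m0, rand_peptides(4, 10, 5)),
               rep(mean(ds$half_life_s), 4))

  # all rows identical on the subset: single cell = global mean
  same <- hl_dataset(rep("ACDEFGHIKL", 2), c(1, 3))
  msame <- hlp_fit(rbind(same, toy_dataset(n = 4, seed = 77)),
                   encoder("dpc"), learner = "dtable", features = "AC")
  expect_true(is.finite(predict(msame, "ACDEFGHIKL")))
})

test_that("constant training targets give a constant predictor", {
  ds <- hl_dataset(rand_peptides(6, 10, 31), rep(2.5, 6))
  for (l in c("svr", "knn", "dtable")) {
    m <- hlp_fit(ds, encoder("aac"), learner = l)
    expect_equal(predict(m, rand_peptides(3, 10, 32)), rep(2.5, 3))
  }
  expect_error(hlp_fit(ds[1, ], encoder("aac")), "insufficient training data")
})

test_that("composition models are order-free; binary models enforce length", {
  ds <- toy_dataset(n = 12)
  m <- hlp_fit(ds, encoder("aac"), learner = "svr")
  p <- rand_peptides(1, 10, 51)
  pred <- predict(m, c(p, shuffle_seq(p, 3)))
  expect_equal(pred[1], pred[2])

  mb <- hlp_fit(ds, encoder("binary"), learner = "knn", k = 1)
  expect_error(predict(mb, rand_peptides(1, 12, 52)), "length 10")
})

test_that("fitting and prediction are deterministic under a fixed seed", {
  ds <- simulate_hl_dataset(n = 60, length = 10, seed = 8)
  q <- rand_peptides(10, 10, 88)
  for (l in c("svr", "knn", "dtable")) {
    m1 <- hlp_fit(ds, encoder("dpc"), learner = l,
                  features = names(DEFAULT_SYNTH_WEIGHTS), seed = 4)
    m2 <- hlp_fit(ds, encoder("dpc"), learner = l,
                  features = names(DEFAULT_SYNTH_WEIGHTS), seed = 4)
    expect_identical(predict(m1, q), predict(m2, q))
  }
})

test_that("target rescaling scales knn and decision-table predictions exactly", {
  ds <- simulate_hl_dataset(n = 50, length = 10, seed = 13)
  q <- rand_peptides(15, 10, 14)
  for (l in c("knn", "dtable")) {
    base <- hlp_fit(ds, encoder("dpc"), learner = l,
                    features = names(DEFAULT_SYNTH_WEIGHTS), k = 3)
    for (c_fac in c(10, 1000)) {
      scaled_ds <- hl_dataset(ds$sequence, ds$half_life_s * c_fac)
      scaled <- hlp_fit(scaled_ds, encoder("dpc"), learner = l,
                        features = names(DEFAULT_SYNTH_WEIGHTS), k = 3)
      expect_equal(predict(scaled, q), c_fac * predict(base, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("SVR is scale equivariant once cost and epsilon are rescaled", {
  ds <- simulate_hl_dataset(n = 60, length = 10, seed = 17)
  c_fac <- 10
  scaled_ds <- hl_dataset(ds$sequence, ds$half_life_s * c_fac)
  cv1 <- cross_validate(ds, encoder("dpc"), "svr",
                        features = names(DEFAULT_SYNTH_WEIGHTS),
                        kernel = "rbf", gamma = 1, cost = 100,
                        epsilon = 0.01, seed = 2)
  cv2 <- cross_validate(scaled_ds, encoder("dpc"), "svr",
                        features = names(DEFAULT_SYNTH_WEIGHTS),
                        kernel = "rbf", gamma = 1, cost = 100 * c_fac,
                        epsilon = 0.01 * c_fac, seed = 2)
  expect_equal(cv1$R, cv2$R, tolerance = 1e-6)
})

test_that("models round-trip through serialization", {
  ds <- toy_dataset(n = 10)
  m <- hlp_fit(ds, encoder("aac"), learner = "knn", k = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  q <- rand_peptides(5, 10, 61)
  expect_identical(predict(m, q), predict(m2, q))
})
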