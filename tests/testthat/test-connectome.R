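test_that("initial volumes are discarded exactly", {
  panel <- matrix(rnorm(240 * 3), 240, 3)
  expect_equal(nrow(discard_initial_volumes(panel, 10)), 230)
  expect_equal(discard_initial_volumes(panel, 0), panel)
  expect_equal(discard_initial_volumes(panel, 10), panel[-(1:10), ])
  expect_error(discard_initial_volumes(panel[1:5, ], 10), "discard")
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  tr <- 2
  t <- (0:511) * tr
  amp_ratio <- function(freq) {
    x <- sin(2 * pi * freq * t)
    y <- bandpass_filter(matrix(x), tr = tr)
    # compare RMS over the central part to avoid edge transients
    core <- 100:412
    sqrt(mean(y[core, 1]^2)) / sqrt(mean(x[core]^2))
  }
  expect_gt(amp_ratio(0.05), 0.9)   # mid-band preserved
  expect_lt(amp_ratio(0.2), 0.1)    # above-band rejected
  expect_lt(amp_ratio(0.003), 0.1)  # drift rejected

  const <- matrix(5, 256, 2)
  filt <- bandpass_filter(const, tr = tr)
  expect_lt(max(abs(filt)), 1e-6)   # DC removed

  expect_error(bandpass_filter(const, tr = 2, low = 0.01, high = 0.3),
               "Nyquist")
  expect_error(bandpass_filter(const, tr = 2, low = 0.2, high = 0.1),
               "low < high")
})

test_that("connectivity is the Pearson correlation matrix with guards", {
  x <- cbind(a = rnorm(50), b = rnorm(50))
  panel <- cbind(x, c = x[, "a"], d = -x[, "a"])
  fc <- compute_fc(panel)
  expect_equal(fc["a", "c"], 1)
  expect_equal(fc["a", "d"], -1)
  expect_true(isSymmetric(fc))
  expect_equal(diag(fc), setNames(rep(1, 4), colnames(panel)))
  expect_true(all(fc >= -1 & fc <= 1))

  # hand evaluation of the Pearson formula
  hand <- compute_fc(cbind(p = c(1, 2, 3), q = c(1, 3, 2), r = rnorm(3)))
  expect_equal(hand["p", "q"], 0.5)

  degenerate <- cbind(ok = rnorm(10), flat = rep(2, 10))
  expect_error(compute_fc(degenerate), "flat")
})

test_that("correlation is invariant to positive affine rescaling", {
  set.seed(42)
  panel <- matrix(rnorm(40 * 5), 40, 5)
  rescaled <- panel
  rescaled[, 3] <- 7.5 * panel[, 3] - 2
  expect_equal(compute_fc(rescaled), compute_fc(panel), tolerance = 1e-12)
})

test_that("vectorize returns network edges in canonical order", {
  atlas <- toy_atlas4()
  part <- partition_edges(atlas)
  fc <- diag(4)
  fc[upper.tri(fc)] <- c(0.12, 0.13, 0.23, 0.14, 0.24, 0.34) # fc[i,j] = 0.ij
  fc <- fc + t(fc); diag(fc) <- 1
  expect_equal(vectorize(fc, part, "Ho"),
               c("1-3" = fc[1, 3], "2-4" = fc[2, 4]))
  expect_equal(vectorize(fc, part, "LH"), c("1-2" = 0.12))
  expect_equal(unname(vectorize(diag(4), part, "He")), c(0, 0))
  expect_error(vectorize(diag(5), part, "LH"), "partition expects")
  expect_error(vectorize(fc, part, "XX"), "unknown network")
})

test_that("feature columns cover the full network on the bundled atlas", {
  atlas <- bna_atlas()
  part <- partition_edges(atlas)
  fc <- diag(246)
  expect_length(vectorize(fc, part, "LH"), 7503)
  expect_length(vectorize(fc, part, "He"), 15006)
})

test_that("relabelling ROIs together with the atlas keeps edge values attached", {
  atlas <- synthetic_atlas(4)
  set.seed(5)
  panel <- matrix(rnorm(60 * 8), 60, 8,
                  dimnames = list(NULL, atlas$abbrev))
  part <- partition_edges(atlas)
  v1 <- vectorize(compute_fc(panel), part, "RH")

  perm <- sample(8)
  relabeled <- as.data.frame(atlas)[perm, ]
  relabeled$node_id <- seq_len(8)
  relabeled$partner_id <- order(perm)[relabeled$partner_id]
  relabeled <- validate_atlas(relabeled)
  v2 <- vectorize(compute_fc(panel[, perm]), partition_edges(relabeled), "RH")
  # same named edges (by abbreviation pair) must carry the same value
  name_of <- function(v, at) {
    vapply(strsplit(names(v), "-"), function(ij) {
      paste(sort(at$abbrev[as.integer(ij)]), collapse = "|")
    }, "")
  }
  m1 <- setNames(as.numeric(v1), name_of(v1, atlas))
  m2 <- setNames(as.numeric(v2), name_of(v2, relabeled))
  expect_mapequal(as.list(m2), as.list(m1))
})

test_that("feature matrices stack subjects and recover planted means", {
  atlas <- synthetic_atlas(4)
  part <- partition_edges(atlas)
  cfg <- synthetic_config(80, n_timepoints = 150,
                          planted_edges = data.frame(i = 2, j = 4, beta = 1),
                          planted_base = 0.5, planted_spread = 0, seed = 8)
  coh <- generate_cohort(cfg, atlas)
  fcs <- lapply(coh$panels, compute_fc)
  feats <- feature_matrix(fcs, part, "RH")
  expect_equal(dim(feats), c(80, nrow(part$rh)))
  expect_equal(rownames(feats), coh$subjects$subject_id)
  # planted column mean converges to r_target = 0.5, others to the background
  expect_lt(abs(mean(feats[, "2-4"]) - 0.5), 0.06)
  others <- setdiff(colnames(feats), "2-4")
  expect_lt(abs(mean(feats[, others]) - 0.1), 0.06)
})

test_that("the optional Fisher z-transform is atanh on each feature", {
  atlas <- toy_atlas4()
  part <- partition_edges(atlas)
  fc <- compute_fc(matrix(rnorm(80), 20, 4,
                          dimnames = list(NULL, atlas$abbrev)))
  raw <- feature_matrix(list(S1 = fc), part, "Ho")
  z <- feature_matrix(list(S1 = fc), part, "Ho", fisher_z = TRUE)
  expect_equal(unclass(z)[1, ], atanh(unclass(raw)[1, ]))
  expect_identical(attr(z, "edges"), attr(raw, "edges"))
})

test_that("connectivity matrices round-trip through TSV", {
  fc <- compute_fc(matrix(rnorm(30 * 4), 30, 4,
                          dimnames = list(NULL, c("a", "b", "c", "d"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fc(fc, path)
  expect_equal(read_fc(path), fc, tolerance = 1e-12)
})
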