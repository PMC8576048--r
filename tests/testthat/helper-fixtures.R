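# Shared fixtures and independent oracles used across the suite.

# 4-node toy atlas: 1L, 2L, 3R, 4R with partners 1<->3, 2<->4.
toy_atlas4 <- function() {
  validate_atlas(data.frame(
    node_id = 1:4,
    name = c("A_L", "B_L", "A_R", "B_R"),
    abbrev = c("AL", "BL", "AR", "BR"),
    hemisphere = c("L", "L", "R", "R"),
    partner_id = c(3L, 4L, 1L, 2L),
    gyrus_id = c(1L, 2L, 1L, 2L),
    lobe_id = c(1L, 1L, 1L, 1L),
    is_cortical = TRUE,
    stringsAsFactors = FALSE
  ))
}

# Smallest valid atlas: one homotopic pair.
toy_atlas2 <- function() {
  validate_atlas(data.frame(
    node_id = 1:2, name = c("A_L", "A_R"), abbrev = c("AL", "AR"),
    hemisphere = c("L", "R"), partner_id = c(2L, 1L),
    gyrus_id = 1L, lobe_id = 1L, is_cortical = TRUE,
    stringsAsFactors = FALSE
  ))
}

# Random valid atlas for property tests: random pairing of 2H nodes into
# homotopic partners, random side assignment within each pair.
random_atlas <- function(n_per_hemisphere, seed) {
  set.seed(seed)
  n <- 2L * n_per_hemisphere
  perm <- sample(n)
  hemi <- character(n)
  partner <- integer(n)
  gyrus <- integer(n)
  for (k in seq_len(n_per_hemisphere)) {
    a <- perm[2L * k - 1L]
    b <- perm[2L * k]
    sides <- sample(c("L", "R"))
    hemi[a] <- sides[1]
    hemi[b] <- sides[2]
    partner[a] <- b
    partner[b] <- a
    gyrus[c(a, b)] <- sample.int(4L, 1L)
  }
  validate_atlas(data.frame(
    node_id = seq_len(n), name = paste0("N", seq_len(n)),
    abbrev = paste0("N", seq_len(n)), hemisphere = hemi,
    partner_id = partner, gyrus_id = gyrus, lobe_id = 1L,
    is_cortical = TRUE, stringsAsFactors = FALSE
  ))
}

# Brute-force partition oracle: classify every unordered pair with an
# explicit double loop.
brute_force_partition <- function(atlas) {
  n <- nrow(atlas)
  is <- integer(0); js <- integer(0); ks <- character(0)
  idx <- 0L
  is <- js <- integer(n * (n - 1L) / 2L)
  ks <- character(n * (n - 1L) / 2L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      hi <- atlas$hemisphere[i]
      hj <- atlas$hemisphere[j]
      idx <- idx + 1L
      is[idx] <- i
      js[idx] <- j
      ks[idx] <- if (hi == "L" && hj == "L") "lh"
      else if (hi == "R" && hj == "R") "rh"
      else if (atlas$partner_id[i] == j) "ho"
      else "he"
    }
  }
  out <- lapply(c(lh = "lh", rh = "rh", ho = "ho", he = "he"), function(k) {
    sel <- ks == k
    df <- data.frame(i = is[sel], j = js[sel])
    df[order(df$i, df$j), , drop = FALSE]
  })
  lapply(out, function(df) { rownames(df) <- NULL; df })
}

# Independent OOB-importance oracle: explicit loops over trees, OOB rows
# and features, predicting one stacked block per (tree, feature) with the
# documented (seed, tree, feature) permutation sub-streams.
brute_force_importance <- function(model, x, y, control = model$control) {
  x <- as.matrix(x)
  n_trees <- control$n_trees
  imp <- numeric(ncol(x))
  err1 <- numeric(n_trees)
  for (t in seq_len(n_trees)) {
    oob <- model$oob[[t]]
    se <- 0
    for (r in oob) {
      p <- predict(model$forest, data = x[r, , drop = FALSE],
                   predict.all = TRUE, num.threads = 1)$predictions[1, t]
      se <- se + (p - y[r])^2
    }
    err1[t] <- se / length(oob)
  }
  for (k in seq_len(ncol(x))) {
    total <- 0
    for (t in seq_len(n_trees)) {
      oob <- model$oob[[t]]
      xp <- x[oob, , drop = FALSE]
      set.seed(derive_seed(control$seed, "perturb", t, k))
      xp[, k] <- xp[sample.int(length(oob)), k]
      se <- 0
      for (r in seq_along(oob)) {
        p <- predict(model$forest, data = xp[r, , drop = FALSE],
                     predict.all = TRUE, num.threads = 1)$predictions[1, t]
        se <- se + (p - y[oob[r]])^2
      }
      total <- total + se / length(oob) - err1[t]
    }
    imp[k] <- total / n_trees
  }
  imp
}

# Independent ridge oracle: minimize J directly via the penalized normal
# equations on the raw (uncentred) design with explicit intercept column.
ridge_normal_equations <- function(x, y, alpha) {
  x <- as.matrix(x)
  n <- length(y)
  m <- cbind(1, x)
  d <- ncol(x)
  pen <- diag(c(0, rep(1, d)))
  b <- solve((2 / n) * crossprod(m) + alpha * pen, (2 / n) * crossprod(m, y))
  list(intercept = b[1], coefficients = b[-1])
}

# Small planted-signal cohort used by several tests.
small_planted_cohort <- function(n_subjects = 30, seed = 11) {
  atlas <- synthetic_atlas(6) # 12 nodes, RH has 15 edges
  pe <- data.frame(i = c(2, 6), j = c(4, 8), beta = c(0.5, 0.5))
  cfg <- synthetic_config(n_subjects, n_timepoints = 120,
                          planted_edges = pe, noise_sd = 0.05, seed = seed)
  coh <- generate_cohort(cfg, atlas)
  part <- partition_edges(atlas)
  fcs <- lapply(coh$panels,
                function(p) compute_fc(discard_initial_volumes(p, 10)))
  list(atlas = atlas, partition = part, cohort = coh,
       features = feature_matrix(fcs, part, "RH"),
       y = coh$subjects$improvement_rate, planted = pe)
}
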