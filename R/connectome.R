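# Connectome stage: volume discarding, band-pass filtering, per-subject
# Pearson connectivity matrices, and network-specific feature vectors.

#' Discard initial volumes of a time-series panel
#'
#' Removes the first `n` rows (scanner equilibration volumes; 10 by
#' convention for an 8-minute acquisition at TR 2 s, leaving 230 volumes).
#'
#' @param panel Numeric T x R matrix (time points x ROIs).
#' @param n Number of leading volumes to drop.
#' @return The panel without its first `n` rows.
#' @export
discard_initial_volumes <- function(panel, n = 10L) {
  panel <- as.matrix(panel)
  if (nrow(panel) <= n) {
    abort("cannot discard %d volumes from a panel with only %d", n, nrow(panel))
  }
  if (n == 0L) return(panel)
  panel[-seq_len(n), , drop = FALSE]
}

#' Band-pass filter ROI time series
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass identically
#' to every column, retaining the resting-state band 0.01-0.1 Hz by default.
#' Zero-phase filtering avoids lag distortion of inter-regional
#' correlations; DC and drifts (< low cutoff) and respiratory/cardiac range
#' frequencies (> high cutoff) are suppressed.
#'
#' @param panel Numeric T x R matrix.
#' @param tr Repetition time in seconds (sampling interval).
#' @param low,high Band edges in Hz; `high` must be below the Nyquist
#'   frequency `1 / (2 * tr)`.
#' @param order Butterworth order per edge (default 4).
#' @return Filtered panel, same dimensions.
#' @export
bandpass_filter <- function(panel, tr, low = 0.01, high = 0.1, order = 4L) {
  panel <- as.matrix(panel)
  nyq <- 1 / (2 * tr)
  if (low <= 0 || high <= low) abort("need 0 < low < high")
  if (high >= nyq) {
    abort("high cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
          high, nyq)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # remove the mean first: DC lies below the pass band anyway, and demeaning
  # avoids filter edge transients driven by the offset
  out <- apply(panel, 2, function(col) signal::filtfilt(bf, col - mean(col)))
  dimnames(out) <- dimnames(panel)
  out
}

#' Pearson functional connectivity matrix
#'
#' Computes the R x R matrix of Pearson correlations between all ROI pairs.
#' Zero-variance columns are rejected by name rather than propagated as
#' `NA`.
#'
#' @param panel Numeric T x R matrix with at least 3 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(panel) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 3L) abort("need at least 3 time points")
  v <- apply(panel, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)[1]
    nm <- colnames(panel)[bad]
    abort("ROI %s has zero variance; correlation undefined",
          if (is.null(nm)) as.character(bad) else nm)
  }
  fc <- stats::cor(panel)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Extract a network's feature vector from a connectivity matrix
#'
#' Returns the connectivity values of one network's edges in canonical
#' (i, j) order, fixing the feature-column identity shared by all subjects.
#'
#' @param fc Symmetric R x R connectivity matrix.
#' @param partition A `"network_partition"` over the same atlas.
#' @param network One of `"LH"`, `"RH"`, `"Ho"`, `"He"`.
#' @return Named numeric vector (names `"i-j"`), length = network size.
#' @export
vectorize <- function(fc, partition, network) {
  key <- .network_key(network)
  if (nrow(fc) != attr(partition, "atlas_size")) {
    abort("connectivity matrix is %d x %d but the partition expects %d nodes",
          nrow(fc), ncol(fc), attr(partition, "atlas_size"))
  }
  edges <- partition[[key]]
  vals <- fc[cbind(edges$i, edges$j)]
  names(vals) <- paste(edges$i, edges$j, sep = "-")
  vals
}

.network_key <- function(network) {
  key <- tolower(network)
  if (!key %in% c("lh", "rh", "ho", "he")) {
    abort("unknown network '%s' (expected LH, RH, Ho or He)", network)
  }
  key
}

#' Stack per-subject feature vectors into a feature matrix
#'
#' @param fc_list Named list of per-subject connectivity matrices (names =
#'   subject ids).
#' @param partition A `"network_partition"`.
#' @param network Network label.
#' @param fisher_z Apply the Fisher z-transform `atanh(r)` to the
#'   connectivity values (default `FALSE`: raw Pearson coefficients are
#'   the modelled features; the transform is offered as a variance
#'   stabilizing extension).
#' @return N x d numeric matrix of class `"fc_features"`, rownames =
#'   subject ids, with attributes `edges` (data.frame `i`, `j`) and
#'   `network`.
#' @export
feature_matrix <- function(fc_list, partition, network, fisher_z = FALSE) {
  key <- .network_key(network)
  rows <- lapply(fc_list, vectorize, partition = partition, network = network)
  x <- do.call(rbind, rows)
  if (fisher_z) x <- atanh(pmin(pmax(x, -1 + 1e-15), 1 - 1e-15))
  rownames(x) <- names(fc_list)
  structure(x, edges = partition[[key]], network = toupper(network),
            class = c("fc_features", class(x)))
}

#' Read / write connectivity matrices as delimited text
#'
#' Matrices are stored R x R with a header row of ROI abbreviations.
#'
#' @param fc Connectivity matrix.
#' @param path File path.
#' @return `read_fc()` returns the matrix; `write_fc()` returns `path`
#'   invisibly.
#' @export
write_fc <- function(fc, path) {
  utils::write.table(fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  if (nrow(m) != ncol(m)) abort("connectivity file %s is not square", path)
  rownames(m) <- colnames(m)
  m
}
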