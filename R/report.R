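# Gyrus-level reporting of the top predictive connections, following the
# rank-based "normalized connection value" convention: ranks 1..k map to
# 1.0, 0.9, ..., 0.1 for k = 10.

#' Report the top-k predictive connections with gyrus and lobe labels
#'
#' Ranks edges by importance (ties broken by canonical edge order), keeps
#' the top `k`, and annotates each with the gyrus id, gyrus name and lobe
#' of both endpoints. Each rank `r` is assigned a normalized connection
#' value `(m - r + 1) / m` where `m = min(k, available)`, so a full top-10
#' runs 1.0, 0.9, ..., 0.1; when fewer than `k` connections are available
#' all are reported with values renormalized over the actual count (with a
#' warning). The raw importance is kept alongside.
#'
#' @param importances An `"importance_table"` with edge columns `i`, `j`.
#' @param atlas The atlas the edges refer to.
#' @param k Number of connections to report (default 10).
#' @return Data.frame with columns `rank`, `i`, `j`, `gyrus_id_i`,
#'   `gyrus_i`, `lobe_i`, `gyrus_id_j`, `gyrus_j`, `lobe_j`, `importance`,
#'   `normalized_value`.
#' @export
report_top_connections <- function(importances, atlas, k = 10L) {
  if (nrow(importances) == 0L) abort("importance table is empty")
  if (k < 1L) abort("k must be >= 1")
  atlas <- validate_atlas(as.data.frame(atlas))
  ord <- order(-importances$importance, importances$i, importances$j)
  m <- min(k, nrow(importances))
  if (m < k) {
    warning(sprintf("only %d connection(s) available; reporting all with values renormalized over %d",
                    m, m), call. = FALSE)
  }
  top <- importances[ord[seq_len(m)], , drop = FALSE]
  data.frame(
    rank = seq_len(m),
    i = top$i, j = top$j,
    gyrus_id_i = atlas$gyrus_id[top$i],
    gyrus_i = gyrus_name(atlas$gyrus_id[top$i]),
    lobe_i = lobe_name(atlas$lobe_id[top$i]),
    gyrus_id_j = atlas$gyrus_id[top$j],
    gyrus_j = gyrus_name(atlas$gyrus_id[top$j]),
    lobe_j = lobe_name(atlas$lobe_id[top$j]),
    importance = top$importance,
    normalized_value = (m - seq_len(m) + 1) / m,
    stringsAsFactors = FALSE
  )
}
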