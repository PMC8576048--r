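# Atlas model: the bilateral parcellation, its validation, the four-network
# edge partition (LH / RH / Ho / He) and gyrus/lobe aggregation maps.

.LOBE_NAMES <- c("Frontal", "Temporal", "Parietal", "Insular", "Limbic",
                 "Occipital", "Subcortical Nuclei")

.ATLAS_COLS <- c("node_id", "name", "abbrev", "hemisphere", "partner_id",
                 "gyrus_id", "lobe_id", "is_cortical")

#' Load and validate a bilateral brain atlas
#'
#' Reads a tab-separated atlas definition with one row per region of interest
#' (ROI) and validates the structural invariants the four-network partition
#' relies on: node ids `1..n` without gaps, equally many left and right
#' nodes, an involutive homotopic partner map that always crosses the
#' midline, and gyrus labels shared between homotopic partners.
#'
#' @param path Path to a TSV file with columns `node_id`, `name`, `abbrev`,
#'   `hemisphere` (`"L"`/`"R"`), `partner_id` (node id of the geometrically
#'   corresponding region in the other hemisphere), `gyrus_id`
#'   (within-hemisphere gyrus index), `lobe_id`, `is_cortical`
#'   (`TRUE`/`FALSE`).
#' @return A `data.frame` of class `"brain_atlas"`, rows sorted by
#'   `node_id`.
#' @seealso [bna_atlas()] for the bundled 246-region parcellation,
#'   [partition_edges()] for the edge-set decomposition.
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) abort("atlas file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_atlas(df)
}

#' @rdname load_atlas
#' @param atlas A data.frame with the columns listed under `path`.
#' @export
validate_atlas <- function(atlas) {
  missing_cols <- setdiff(.ATLAS_COLS, names(atlas))
  if (length(missing_cols)) {
    abort("atlas is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  atlas <- atlas[order(atlas$node_id), .ATLAS_COLS, drop = FALSE]
  rownames(atlas) <- NULL
  n <- nrow(atlas)
  atlas$node_id <- as.integer(atlas$node_id)
  atlas$partner_id <- as.integer(atlas$partner_id)
  atlas$gyrus_id <- as.integer(atlas$gyrus_id)
  atlas$lobe_id <- as.integer(atlas$lobe_id)
  atlas$is_cortical <- as.logical(atlas$is_cortical)

  dup <- atlas$node_id[duplicated(atlas$node_id)]
  if (length(dup)) abort("duplicate node_id: %s", paste(dup, collapse = ", "))
  if (!identical(atlas$node_id, seq_len(n))) {
    abort("node_id must cover 1..%d without gaps", n)
  }
  bad_h <- which(!atlas$hemisphere %in% c("L", "R"))
  if (length(bad_h)) {
    abort("row %d: hemisphere must be 'L' or 'R' (got '%s')",
          bad_h[1], atlas$hemisphere[bad_h[1]])
  }
  n_l <- sum(atlas$hemisphere == "L")
  if (n_l * 2L != n) {
    abort("hemispheres are not an equal split: %d L vs %d R", n_l, n - n_l)
  }
  bad_p <- which(atlas$partner_id < 1L | atlas$partner_id > n |
                   atlas$partner_id == atlas$node_id)
  if (length(bad_p)) {
    abort("row %d: partner_id %d is out of range or self-referential",
          bad_p[1], atlas$partner_id[bad_p[1]])
  }
  not_invol <- which(atlas$partner_id[atlas$partner_id] != atlas$node_id)
  if (length(not_invol)) {
    i <- not_invol[1]
    abort("row %d: partner map is not an involution (partner(%d) = %d but partner(%d) = %d)",
          i, i, atlas$partner_id[i], atlas$partner_id[i],
          atlas$partner_id[atlas$partner_id[i]])
  }
  same_side <- which(atlas$hemisphere[atlas$partner_id] == atlas$hemisphere)
  if (length(same_side)) {
    abort("row %d: homotopic partner %d lies in the same hemisphere",
          same_side[1], atlas$partner_id[same_side[1]])
  }
  gy_mismatch <- which(atlas$gyrus_id[atlas$partner_id] != atlas$gyrus_id)
  if (length(gy_mismatch)) {
    abort("row %d: gyrus_id differs from its homotopic partner's",
          gy_mismatch[1])
  }
  class(atlas) <- c("brain_atlas", "data.frame")
  atlas
}

#' The bundled 246-region bilateral parcellation
#'
#' Loads the package's Brainnetome-style 246-ROI atlas: 210 cortical regions
#' (105 per hemisphere) and 36 subcortical regions (18 per hemisphere),
#' grouped into 24 gyri per hemisphere and 7 lobes (1-6 Frontal, 7-12
#' Temporal, 13-16 Parietal, 17 Insular, 18 Limbic, 19-20 Occipital, 21-24
#' Subcortical Nuclei). Homotopic partners follow the odd/even interleaving
#' of the bilateral labels (region 2k-1 is left, 2k is its right partner).
#' The table is derived programmatically from the published gyrus and
#' subregion counts of the parcellation; subregion display names are
#' systematic (`"SFG_L_1"`), not anatomical subregion names.
#'
#' @return A `"brain_atlas"` data.frame with 246 rows.
#' @export
#' @examples
#' atlas <- bna_atlas()
#' table(atlas$hemisphere)
bna_atlas <- function() {
  load_atlas(system.file("extdata", "bna246_atlas.tsv", package = "hemiconn",
                         mustWork = TRUE))
}

#' Gyrus and lobe display names for the bundled parcellation
#'
#' @param gyrus_id,lobe_id Integer label(s).
#' @return Character vector of names.
#' @export
lobe_name <- function(lobe_id) .LOBE_NAMES[lobe_id]

#' @rdname lobe_name
#' @export
gyrus_name <- function(gyrus_id) {
  nm <- c("Superior frontal gyrus (SFG)", "Middle frontal gyrus (MFG)",
          "Inferior frontal gyrus (IFG)", "Orbital gyrus (OrG)",
          "Precentral gyrus (PrG)", "Paracentral lobule (PCL)",
          "Superior temporal gyrus (STG)", "Middle temporal gyrus (MTG)",
          "Inferior temporal gyrus (ITG)", "Fusiform gyrus (FuG)",
          "Parahippocampal gyrus (PhG)",
          "Posterior superior temporal sulcus (pSTS)",
          "Superior parietal lobule (SPL)", "Inferior parietal lobule (IPL)",
          "Precuneus (PCun)", "Postcentral gyrus (PoG)",
          "Insular gyrus (INS)", "Cingulate gyrus (CG)",
          "Medioventral occipital cortex (MVOcC)",
          "Lateral occipital cortex (LOcC)", "Amygdala (Amyg)",
          "Hippocampus (Hipp)", "Basal ganglia (BG)", "Thalamus (Tha)")
  nm[gyrus_id]
}

#' Build a small synthetic bilateral atlas
#'
#' Constructs a reduced atlas with the same structure as the bundled
#' parcellation (odd/even left/right interleaving, involutive homotopic
#' partners, gyrus labels shared across the midline). Useful for fast
#' simulation studies and tests where the full 246-node edge sets would be
#' needlessly large.
#'
#' @param n_per_hemisphere Number of nodes per hemisphere.
#' @param n_gyri Number of gyri per hemisphere (labels recycle over nodes).
#' @param n_subcortical Number of subcortical nodes per hemisphere (taken
#'   from the end of the node list).
#' @return A `"brain_atlas"` data.frame with `2 * n_per_hemisphere` rows.
#' @export
#' @examples
#' synthetic_atlas(4)
synthetic_atlas <- function(n_per_hemisphere,
                            n_gyri = max(1L, n_per_hemisphere %/% 4L),
                            n_subcortical = 0L) {
  h <- as.integer(n_per_hemisphere)
  if (h < 1L) abort("n_per_hemisphere must be >= 1")
  if (n_subcortical > h) abort("n_subcortical cannot exceed n_per_hemisphere")
  n <- 2L * h
  node_id <- seq_len(n)
  hemi <- ifelse(node_id %% 2L == 1L, "L", "R")
  pair <- (node_id + 1L) %/% 2L # homotopic pair index 1..h
  gyrus <- ((pair - 1L) %% as.integer(n_gyri)) + 1L
  atlas <- data.frame(
    node_id = node_id,
    name = sprintf("Region_%s_%d", hemi, pair),
    abbrev = sprintf("R%s%d", hemi, pair),
    hemisphere = hemi,
    partner_id = ifelse(node_id %% 2L == 1L, node_id + 1L, node_id - 1L),
    gyrus_id = gyrus,
    lobe_id = ((gyrus - 1L) %% 7L) + 1L,
    is_cortical = pair <= (h - as.integer(n_subcortical)),
    stringsAsFactors = FALSE
  )
  validate_atlas(atlas)
}

#' Partition all region pairs into the four hemispheric networks
#'
#' Classifies every unordered ROI pair `(i, j)`, `i < j`, of an atlas into
#' one of four disjoint edge sets: both endpoints left (`lh`), both right
#' (`rh`), opposite hemispheres and homotopic partners (`ho`), opposite
#' hemispheres otherwise (`he`). For the bundled 246-node atlas the
#' cardinalities are 7503 / 7503 / 123 / 15006 (30135 pairs in total).
#'
#' @param atlas A validated `"brain_atlas"`.
#' @return An object of class `"network_partition"`: a list with elements
#'   `lh`, `rh`, `ho`, `he`, each a data.frame with integer columns `i`, `j`
#'   (`i < j`) in canonical row-major upper-triangle order.
#' @export
#' @examples
#' part <- partition_edges(synthetic_atlas(2))
#' sapply(part, nrow)
partition_edges <- function(atlas) {
  atlas <- validate_atlas(as.data.frame(atlas))
  n <- nrow(atlas)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, "row"]
  j <- ut[, "col"]
  # canonical order: sorted by (i, j)
  o <- order(i, j)
  i <- i[o]
  j <- j[o]
  hi <- atlas$hemisphere[i]
  hj <- atlas$hemisphere[j]
  cls <- ifelse(hi == "L" & hj == "L", "lh",
         ifelse(hi == "R" & hj == "R", "rh",
         ifelse(atlas$partner_id[i] == j, "ho", "he")))
  out <- lapply(c(lh = "lh", rh = "rh", ho = "ho", he = "he"), function(k) {
    sel <- cls == k
    data.frame(i = as.integer(i[sel]), j = as.integer(j[sel]),
               row.names = NULL)
  })
  structure(out, atlas_size = n, class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Network partition of %d nodes (%d edges)\n",
              attr(x, "atlas_size"), sum(vapply(x, nrow, 0L))))
  for (k in names(x)) cat(sprintf("  %s: %d edges\n", toupper(k), nrow(x[[k]])))
  invisible(x)
}

#' Write a network partition to a TSV file
#'
#' @param partition A `"network_partition"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- do.call(rbind, lapply(names(partition), function(k) {
    cbind(network = toupper(k), partition[[k]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate edge importances to gyrus pairs
#'
#' Maps each ROI-level edge of an importance table to its unordered
#' `(gyrus_i, gyrus_j)` pair and aggregates the importance within each pair
#' (default: maximum, preserving the identity of the top edge; `"mean"`
#' available). Rows are returned in decreasing aggregated importance.
#'
#' @param importances An importance table with columns `i`, `j`,
#'   `importance` (see [oob_importance()]).
#' @param atlas The atlas the edges refer to.
#' @param stat Aggregation statistic, `"max"` (default) or `"mean"`.
#' @return A data.frame with columns `gyrus_i`, `gyrus_j`, `importance`,
#'   `n_edges`, `top_i`, `top_j` (the edge attaining the maximum).
#' @export
aggregate_to_gyri <- function(importances, atlas, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  atlas <- validate_atlas(as.data.frame(atlas))
  if (nrow(importances) == 0L) {
    return(data.frame(gyrus_i = integer(), gyrus_j = integer(),
                      importance = numeric(), n_edges = integer(),
                      top_i = integer(), top_j = integer()))
  }
  bad <- which(importances$i > nrow(atlas) | importances$j > nrow(atlas) |
                 importances$i < 1L | importances$j < 1L)
  if (length(bad)) {
    abort("edge (%d, %d) references a node absent from the atlas",
          importances$i[bad[1]], importances$j[bad[1]])
  }
  gi <- atlas$gyrus_id[importances$i]
  gj <- atlas$gyrus_id[importances$j]
  g1 <- pmin(gi, gj)
  g2 <- pmax(gi, gj)
  key <- paste(g1, g2, sep = "-")
  agg <- lapply(split(seq_len(nrow(importances)), key), function(rows) {
    imp <- importances$importance[rows]
    top <- rows[which.max(imp)]
    data.frame(gyrus_i = g1[rows[1]], gyrus_j = g2[rows[1]],
               importance = if (stat == "max") max(imp) else mean(imp),
               n_edges = length(rows),
               top_i = importances$i[top], top_j = importances$j[top])
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$importance, out$gyrus_i, out$gyrus_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
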