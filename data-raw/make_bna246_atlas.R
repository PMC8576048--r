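# Builds inst/extdata/bna246_atlas.tsv from the published gyrus/subregion
# structure of the 246-region bilateral parcellation: per hemisphere, 24 gyri
# with the subregion counts below (105 cortical + 18 subcortical nodes);
# bilateral labels interleave left (odd) and right (even), so the homotopic
# partner of node 2k-1 is node 2k. Lobe grouping: gyri 1-6 Frontal, 7-12
# Temporal, 13-16 Parietal, 17 Insular, 18 Limbic, 19-20 Occipital, 21-24
# Subcortical Nuclei. Run from the package root:
#   Rscript data-raw/make_bna246_atlas.R

gyri <- data.frame(
  gyrus_id = 1:24,
  abbrev = c("SFG", "MFG", "IFG", "OrG", "PrG", "PCL",
             "STG", "MTG", "ITG", "FuG", "PhG", "pSTS",
             "SPL", "IPL", "PCun", "PoG",
             "INS", "CG", "MVOcC", "LOcC",
             "Amyg", "Hipp", "BG", "Tha"),
  name = c("Superior frontal gyrus", "Middle frontal gyrus",
           "Inferior frontal gyrus", "Orbital gyrus", "Precentral gyrus",
           "Paracentral lobule", "Superior temporal gyrus",
           "Middle temporal gyrus", "Inferior temporal gyrus",
           "Fusiform gyrus", "Parahippocampal gyrus",
           "Posterior superior temporal sulcus", "Superior parietal lobule",
           "Inferior parietal lobule", "Precuneus", "Postcentral gyrus",
           "Insular gyrus", "Cingulate gyrus",
           "Medioventral occipital cortex", "Lateral occipital cortex",
           "Amygdala", "Hippocampus", "Basal ganglia", "Thalamus"),
  n_subregions = c(7, 7, 6, 6, 6, 2, 6, 4, 7, 3, 6, 2, 5, 6, 4, 4, 6, 7,
                   5, 6, 2, 2, 6, 8),
  stringsAsFactors = FALSE
)
gyri$lobe_id <- c(rep(1, 6), rep(2, 6), rep(3, 4), 4, 5, 6, 6, rep(7, 4))
gyri$is_cortical <- gyri$gyrus_id <= 20

stopifnot(sum(gyri$n_subregions[gyri$is_cortical]) == 105,
          sum(gyri$n_subregions[!gyri$is_cortical]) == 18)

rows <- list()
node <- 0L
for (g in seq_len(nrow(gyri))) {
  for (s in seq_len(gyri$n_subregions[g])) {
    for (hemi in c("L", "R")) {
      node <- node + 1L
      rows[[node]] <- data.frame(
        node_id = node,
        name = sprintf("%s, subregion %d (%s)", gyri$name[g], s, hemi),
        abbrev = sprintf("%s_%s_%d", gyri$abbrev[g], hemi, s),
        hemisphere = hemi,
        partner_id = if (hemi == "L") node + 1L else node - 1L,
        gyrus_id = gyri$gyrus_id[g],
        lobe_id = gyri$lobe_id[g],
        is_cortical = gyri$is_cortical[g],
        stringsAsFactors = FALSE
      )
    }
  }
}
atlas <- do.call(rbind, rows)
stopifnot(nrow(atlas) == 246, sum(atlas$is_cortical) == 210)

write.table(atlas, file.path("inst", "extdata", "bna246_atlas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(atlas), "nodes\n")
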