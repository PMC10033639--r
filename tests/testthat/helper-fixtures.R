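# Shared fixtures: small seeded configurations used across test files.

default_marker_panel <- function() {
  list(tumor = "SOX2", macrophage = c("CD14", "CD68"), tcell = "CD3D",
       bcell = "CD79A", oligodendrocyte = "MBP",
       endothelial = "PECAM1", pericyte = "PDGFRB")
}

# Small fast screen: 30 genes x 4 guides + 10 NTC, 2 mice/arm/stage.
small_screen_cfg <- function(seed, selection = list(), ...) {
  screen_sim_config(seed = seed, n_genes = 30, n_ntc = 10,
                    cells_per_mouse = 5000, mice_per_arm = 2,
                    depth_per_sample = 3e5, selection = selection, ...)
}

# Planted-depletion screen at the recovery-study size:
# 100 genes x 4 guides + 20 NTC, one gene with s_WT = -1, s_CD8KO = 0.
planted_screen_cfg <- function(seed) {
  screen_sim_config(seed = seed, n_genes = 100, n_ntc = 20,
                    selection = list(KIN0001 = c(-1, 0)))
}

# Small single-cell cohort; coupling as given.
small_scrna_cfg <- function(seed, coupling, n_samples = 12,
                            cells_per_sample = 40, n_genes = 300) {
  scrna_sim_config(seed = seed, n_samples = n_samples,
                   cells_per_sample = cells_per_sample,
                   n_genes = n_genes, coupling = coupling)
}

# Full stratification pipeline on one simulated cohort; returns the
# two-sided Mann-Whitney p comparing signature scores of cells in
# focal-low vs focal-high samples.
stratify_pipeline_p <- function(seed, coupling) {
  sim <- simulate_scrna(small_scrna_cfg(seed, coupling))
  lab <- annotate_cells(sim$cpm, default_marker_panel())
  fr <- focal_positive_frequency(sim$cpm, sim$meta$sample_id, lab,
                                 "CHEK2")
  st <- dichotomize_samples(fr)
  sc <- auc_score(sim$cpm, sprintf("IFNSIG%02d", 1:20))
  lo <- sc[sim$meta$sample_id %in% st$sample_id[st$label == "low"]]
  hi <- sc[sim$meta$sample_id %in% st$sample_id[st$label == "high"]]
  compare_groups_mw(lo, hi)$p
}
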