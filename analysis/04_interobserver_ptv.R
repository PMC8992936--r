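#!/usr/bin/env Rscript
# Interobserver evaluation via the PTV-point Euclidean-distance metric:
# apply each observer's paired (CT-based, sCT-based) registration matrices
# to the original PTV contour points, compute per-point distances and Dice
# overlap of the registered structures, and summarize per case.
library(posequiv)

dir.create("results", showWarnings = FALSE)
seed <- 1L

mean_2d <- c(-0.0, -0.2, -0.3, 0.1, -0.1, 0)
sd_2d   <- c(0.7, 0.7, 0.8, 0.6, 0.5, 0)
tab <- sample_paired_registrations(14, 6, mean_2d, sd_2d, seed = seed + 1L,
                                   modality = "2d")

ptv <- make_ptv(center = c(0, -20, 40), semi_axes = c(20, 22, 30),
                n_slices = 12, pts_per_contour = 48)
write_structure(ptv, "results/ptv.json")

dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
rows <- list(); hists <- list()
for (cs in unique(tab$case)) {
  reports <- list(); dscs <- c()
  for (ob in unique(tab$observer[tab$case == cs])) {
    g <- tab[tab$case == cs & tab$observer == ob, ]
    v_ct <- as.numeric(g[g$reference == "ct", dof]); v_ct[6] <- 0
    v_sct <- as.numeric(g[g$reference == "sct", dof]); v_sct[6] <- 0
    m_ct <- build_matrix(do.call(six_dof, as.list(v_ct)))
    m_sct <- build_matrix(do.call(six_dof, as.list(v_sct)))
    rep <- paired_ptv_distances(ptv, m_ct, m_sct)
    reports[[as.character(ob)]] <- rep
    dscs <- c(dscs, registered_ptv_dice(ptv, m_ct, m_sct,
                                        grid_spacing_mm = 2)$dsc)
    hists[[length(hists) + 1L]] <- data.frame(
      case = cs, observer = ob,
      bin_lo = head(rep$histogram$breaks, -1),
      count = rep$histogram$counts)
  }
  s <- observer_summary(reports)
  rows[[length(rows) + 1L]] <- data.frame(
    case = cs, mean_all = s$mean_of_means, sd_all = s$sd_of_means,
    worst_mean = s$worst_mean, worst_sd = s$worst_sd,
    max_mm = s$max_distance, mean_dsc = mean(dscs))
}
cases <- do.call(rbind, rows)
write.csv(cases, "results/interobserver_cases.csv", row.names = FALSE)
write.csv(do.call(rbind, hists), "results/distance_histograms.csv",
          row.names = FALSE)

cat("Per-case interobserver PTV distances (mm) and Dice overlap:\n")
print(cases, row.names = FALSE, digits = 2)
cat(sprintf(paste0(
  "\nAcross %d cases the mean distance is %.1f mm (worst case %.1f mm,\n",
  "max %.1f mm) and the mean Dice of the paired registered PTVs is %.3f:\n",
  "observers disagree by low millimetres while the structures stay\n",
  "highly overlapping.\n"),
  nrow(cases), mean(cases$mean_all), max(cases$worst_mean),
  max(cases$max_mm), mean(cases$mean_dsc)))
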