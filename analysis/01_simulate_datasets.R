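#!/usr/bin/env Rscript
# Generates the synthetic study datasets in the package's plain-text
# interchange formats under results/synthetic/: micropipette-aspiration
# creep records for a control-like and a stiffened (LPS-like) cohort,
# example nanoindentation curves at the four cohort moduli, chemotaxis
# track files at three drift levels, and a wound-area time series.
# Everything is seeded, so re-running reproduces the files byte-for-byte.

suppressPackageStartupMessages(library(cellmech))

seed <- 1L
out_dir <- "results/synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## Aspiration cohorts: control (k1=200, k2=100, mu=300) vs a cohort with
## k1 and mu elevated 1.8x and k2 unchanged, 12 cells each, 20% between-cell
## CV and 2% measurement noise.
creep_groups <- simulate_cohort_mechanics(
  list(control = list(mean = sls_params(200, 100, 300), cv = 0.2, n = 12),
       stiffened = list(mean = sls_params(360, 100, 540), cv = 0.2, n = 12)),
  seed = seed, type = "creep", noise_scale = 0.02, n_points = 120, t_max = 45)
for (g in names(creep_groups)) {
  for (i in seq_along(creep_groups[[g]])) {
    write_creep(creep_groups[[g]][[i]],
                file.path(out_dir, sprintf("creep_%s_%02d.csv", g, i)))
  }
}
truth_tab <- do.call(rbind, lapply(names(creep_groups), function(g) {
  tr <- attr(creep_groups[[g]], "group_truth")
  data.frame(group = g, cell = seq_len(nrow(tr)), tr)
}))
write_results(truth_tab, file.path(out_dir, "creep_ground_truth.csv"),
              config = list(cv = 0.2, noise = "2% additive"), seed = seed)

## One example indentation curve per cohort modulus (3% multiplicative
## load noise, 0.5 um pre-contact travel).
moduli <- c(ctrl_raw264 = 1721, ctrl_peritoneal = 1113,
            lps_raw264 = 4838, lps_peritoneal = 1963)
set.seed(seed + 1)
for (nm in names(moduli)) {
  cur <- simulate_indentation(moduli[[nm]],
                              noise = noise_spec("multiplicative_gaussian", 0.03),
                              baseline_points = 50, contact_offset = 0.5e-6)
  writeLines(c("# tip_radius_um=9", "# spring_constant_n_m=0.048",
               "# max_depth_um=5", "depth_um,load_nn",
               paste(sprintf("%.6f", cur$depth * 1e6),
                     sprintf("%.6f", cur$load * 1e9), sep = ",")),
             file.path(out_dir, sprintf("indent_%s.csv", nm)))
}

## Chemotaxis cohorts: 15 tracks each at three drift levels (3-min frames
## over 6 h), long format, gradient toward +x; coordinates at nm precision.
drifts <- c(responsive = 0.4, impaired = 0.1, unbiased = 0)
for (j in seq_along(drifts)) {
  trs <- simulate_trajectories(15, walk_spec(drift_fraction = drifts[[j]],
                                             speed_scale = 1, seed = seed + 10 + j))
  long <- do.call(rbind, lapply(trs, function(tr) {
    data.frame(cell_id = tr$cell_id, t_min = tr$times,
               x_um = round(tr$xs, 3), y_um = round(tr$ys, 3))
  }))
  con <- file(file.path(out_dir, sprintf("tracks_%s.csv", names(drifts)[j])), "w")
  writeLines("# gradient_axis=x", con)
  write.csv(long, con, row.names = FALSE, quote = FALSE)
  close(con)
}

## Wound-area series: day-0 excision of ~78.5 mm^2 (10 mm circle) healing
## over 12 days.
writeLines(c("day,area_mm2", "0,78.5", "3,58.9", "6,23.6", "9,7.1", "12,1.2"),
           file.path(out_dir, "wound_example.csv"))

message("synthetic datasets written to ", out_dir)
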