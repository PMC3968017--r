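#!/usr/bin/env Rscript
# Generate the canonical synthetic plates used throughout the analysis:
# a 12-sample plate spanning the assay's dynamic range (zero activity,
# sub-floor, the t-test band, the accept region, and a substrate-depleting
# sample), written in both reader-export dialects together with the plate
# layout and the generative ground truth.

library(ntpassay)

seed <- 20260923
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- plate_design(
  data.frame(
    sample_id = sprintf("S%02d", 1:12),
    # per-well true raw activities, pmol 4-NTP degraded/min
    true_raw_pmol_per_min = c(0, 2, 4.84, 6, 10, 25, 50, 100, 200, 500,
                              1000, 3000)),
  template = "12-sample",
  k_bg = 0.001,      # mild shared non-enzymatic decay
  noise_sd = 0.002)  # 2 mOD read noise

sim <- simulate_plate(design, seed = seed)

write_plate_timeseries(sim$series, file.path(out_dir, "plate_wide.tsv"), "wide")
write_plate_timeseries(sim$series, file.path(out_dir, "plate_long.tsv"), "long")

# layout as a YAML config round-trippable through read_layout()
lay <- sim$layout
yaml::write_yaml(list(
  samples = setNames(lapply(lay$samples, function(s)
    list(category = s$category, sample_mass = s$sample_mass,
         buffer_volume = s$buffer_volume, aliquot = s$aliquot,
         dilution_factor = s$dilution_factor)), names(lay$samples)),
  wells = setNames(lapply(seq_len(nrow(lay$assignments)), function(i)
    list(sample = lay$assignments$sample_id[i],
         role = lay$assignments$role[i])), lay$assignments$well)
), file.path(out_dir, "layout.yaml"))

utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "wrote plate (%d wells x %d reads), layout and ground truth to %s",
  length(sim$series$wells), length(sim$series$times), out_dir))
message(sprintf("true raw activities span %g-%g pmol/min",
                min(sim$truth$true_raw_pmol_per_min),
                max(sim$truth$true_raw_pmol_per_min)))
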