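#!/usr/bin/env Rscript
# Stage 1: build the synthetic benchmark inputs.
#
# Generates one multichannel stack per developmental-stage preset (e8, e12,
# d0) plus a migration-assay field, writes the TIFFs and ground-truth CSVs
# under results/synthetic/. Later stages consume these files, so the whole
# study is reproducible from this script's seed.

suppressMessages(library(spherequant))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed0 <- 1L

for (preset in c("e8", "e12", "d0")) {
  # four spheroids per stage so the stage-5 group comparisons have four
  # per-neurosphere data points per group
  params <- synthesis_preset(preset,
                             seed = seed0 + match(preset, c("e8", "e12", "d0")),
                             n_spheroids = 4)
  gen <- generate_stack(params)
  write_stack(gen$stack, file.path(out, paste0(preset, ".tif")))
  write.csv(gen$truth$nuclei, file.path(out, paste0(preset, "_truth.csv")),
            row.names = FALSE)
  co <- gen$truth$nuclei$green & gen$truth$nuclei$red
  cat(sprintf("%s: %d nuclei in %d spheroids; green+/red+ co-expression %.2f\n",
              preset, nrow(gen$truth$nuclei), nrow(gen$truth$spheroids),
              mean(co)))
}

set.seed(seed0)
offsets <- sort(sample(10:150, 12))
fld <- generate_migration_field(60, offsets, seed = seed0)
write_stack(fld$stack, file.path(out, "migration.tif"))
write.csv(data.frame(planted_distance = fld$planted_distances),
          file.path(out, "migration_truth.csv"), row.names = FALSE)
cat(sprintf("migration field: %d planted cells, distal-edge distances %s px\n",
            length(offsets), paste(fld$planted_distances, collapse = ", ")))
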