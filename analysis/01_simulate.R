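#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study scenes with known ground truth.
#
# Three kinds of input are produced: two-channel-plus-accessory SMLM
# localization scenes (PSD disc, elliptical EZ at the measured ~225 x 147 nm
# scale, accessory protein with a Beta(8,2) edge-enrichment law), a line
# movie with stationary/anterograde/retrograde puncta, and a FRAP trace on
# the 19-min acquisition schedule. Everything downstream re-reads these
# files, so the whole workflow is reproducible from this stage alone.

suppressPackageStartupMessages(library(endozone))
dir.create("results/scenes", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

for (i in 1:5) {
  sc <- make_localization_scene(synapse_scene_params(seed = seed + i))
  write_localizations(sc$locs,
                      sprintf("results/scenes/locs_scene%02d.csv", i))
}
cat("wrote 5 localization scenes (",
    nrow(make_localization_scene(synapse_scene_params(seed = seed + 1))$locs),
    "localizations each )\n")

dyn <- make_dynamics_scene(dynamics_scene_params(seed = seed, n_events = 1000))
utils::write.csv(dyn$events, "results/scenes/lifetime_events.csv",
                 row.names = FALSE)
utils::write.csv(as.data.frame(dyn$frap), "results/scenes/frap_trace.csv",
                 row.names = FALSE)
# a sparser event scene for track linking (puncta stay well separated
# relative to the 500 nm linking radius)
sparse <- make_dynamics_scene(dynamics_scene_params(seed = seed + 1,
                                                    n_events = 300))
utils::write.csv(sparse$events, "results/scenes/detection_events.csv",
                 row.names = FALSE)
utils::write.csv(sparse$detections, "results/scenes/detections.csv",
                 row.names = FALSE)
cat("wrote dynamics scene:", dim(dyn$movie)[1], "frames,",
    nrow(dyn$events), "lifetime events,",
    nrow(sparse$detections), "detections for tracking\n")
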