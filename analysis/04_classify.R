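#!/usr/bin/env Rscript
# Step 4 — control-anchored PCA classification of systolic windows.
#
# Cuts a 20-frame window of raw ROI brightness at every systole onset, pools
# these with control windows from a simulated culture-dish recording
# (spontaneous transients, no tissue motion), embeds everything with PCA
# (20 -> 2), and labels a window sync when it falls inside the control
# cluster's 97.5% Mahalanobis gate. Cells are called by window majority.

suppressPackageStartupMessages(library(graftsync))

out <- "results/demo"
video <- read_stack(file.path(out, "stack.tif"))
traces <- read_traces(file.path(out, "traces.csv"), video$frame_rate)
segmentation <- local({
  df <- read.csv(file.path(out, "segmentation.csv"))
  attr(df, "n_frames") <- dim(video)[3]
  class(df) <- c("phase_segmentation", "data.frame")
  df
})

windows <- bind_windows(lapply(traces, function(tr)
  extract_systolic_windows(tr, segmentation, heart_id = 1L)))
control <- make_control_windows(
  scene_config("dish_control", height = 256, width = 256, duration = 10,
               n_cells = 16, seed = 1000))
message(sprintf("%d systolic windows from %d cells; %d control windows",
                nrow(windows$vectors), length(traces),
                nrow(control$vectors)))

emb <- pca_embed(preprocess_windows(control), preprocess_windows(windows))
wl <- classify_windows(emb)
cells <- classify_cells(wl$label, windows$info$cell_id,
                        all_cell_ids = as.integer(names(traces)))

write.csv(data.frame(role = emb$role,
                     pc1 = emb$scores[, 1], pc2 = emb$scores[, 2]),
          file.path(out, "scores.csv"), row.names = FALSE)
write.csv(cells, file.path(out, "cell_labels.csv"), row.names = FALSE)

cells <- cells[order(cells$cell_id), ]
cells$heart_id <- 1L
summ <- summarize_by_heart(cells)
print(summ)
write.csv(data.frame(heart_id = summ$per_heart$heart_id,
                     n_sync = summ$per_heart$n_sync,
                     n_async = summ$per_heart$n_async),
          file.path(out, "summary.csv"), row.names = FALSE)

truth <- read.csv(file.path(out, "truth_cells.csv"))
tru <- truth$label[match(sort(unique(truth$cell_id)), truth$cell_id)]
message(sprintf("balanced accuracy vs ground truth: %.3f",
                balanced_accuracy(tru, cells$label)))
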