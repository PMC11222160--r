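#!/usr/bin/env Rscript
# Stage 2: matched-filter detection of membrane side views in the stage-1
# micrographs, with recall/false-positive accounting against the ground
# truth. Writes per-micrograph pick tables and a summary.

suppressPackageStartupMessages(library(cryomem))

data_dir <- "results/data"
out <- "results/detection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
if (!dir.exists(data_dir)) stop("run analysis/01_simulate_data.R first")

bank <- make_template_bank(n_templates = 5, length = 300, image_size = 96,
                           pixel_size = 4)
micros <- sort(list.files(data_dir, pattern = "^micrograph_\\d+\\.mrc$",
                          full.names = TRUE))
rows <- list()
for (f in micros) {
  img <- read_mrc(f)
  truth <- read_segments_star(sub("\\.mrc$", "_truth.star", f))
  field <- match_templates(img, bank, angle_step = 5)
  picks <- pick_segments(field, threshold = 0.4, nms_radius = 150)
  picks$micrograph <- basename(f)
  write_star(picks, file.path(out, sub("\\.mrc$", "_picks.star",
                                       basename(f))))
  hit <- rep(FALSE, length(truth))
  fp <- 0
  for (p in seq_len(nrow(picks))) {
    d <- vapply(truth, function(s)
      sqrt(sum((c(picks$centre_x_A[p], picks$centre_y_A[p]) - s$centre)^2)),
      0) / img$pixel_size
    j <- which.min(d)
    if (d[j] <= 4 && !hit[j]) hit[j] <- TRUE else fp <- fp + 1
  }
  rows[[f]] <- data.frame(micrograph = basename(f), n_true = length(truth),
                          n_hit = sum(hit), n_false = fp)
  log_msg("detect", sprintf("%s: %d/%d segments, %d false",
                            basename(f), sum(hit), length(truth), fp))
}
summary <- do.call(rbind, rows)
utils::write.table(summary, file.path(out, "detection_summary.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
log_msg("detect", sprintf("overall recall %.1f%%, %.2f false positives/image",
                          100 * sum(summary$n_hit) / sum(summary$n_true),
                          mean(summary$n_false)))
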