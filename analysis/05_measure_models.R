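#!/usr/bin/env Rscript
# Stage 5: coordinate-model geometry. Measures membrane-surface height and
# ligand height above the membrane (M-distance) on the stage-1 fixtures,
# plus entrance distances against a user-style landmark, and appends all
# results to a TSV report. If deposited coordinate models are available
# locally (see README), the Rieske-quinone minimum distance is measured
# too.

suppressPackageStartupMessages(library(cryomem))

data_dir <- "results/data"
out <- "results/measurements"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
report <- file.path(out, "measurements.tsv")
if (file.exists(report)) file.remove(report)

for (h in c(0, 16, 20)) {
  f <- file.path(data_dir, sprintf("fixture_ligand_%02dA.pdb", h))
  if (!file.exists(f)) stop("run analysis/01_simulate_data.R first")
  m <- load_model(f)
  height <- membrane_height(m)
  lig <- select_atoms(m, resid = "Q1C")
  md <- m_distance(m, lig, height)
  ed <- e_distance(m, lig, entrance_point = c(0, 60, 35))
  write_measurements_tsv(list(height, md, ed), report,
                         model_name = basename(f))
  log_msg("measure", sprintf(
    "%s: membrane height %+.2f Å, M-distance %+.2f Å (truth %d), E-distance %.1f Å",
    basename(f), height$value, md$value, h, ed$value))
}

dep_dir <- Sys.getenv("CRYOMEM_MODEL_DIR",
                      system.file("extdata", "deposited",
                                  package = "cryomem"))
if (nzchar(dep_dir) && dir.exists(dep_dir)) {
  for (f in list.files(dep_dir, pattern = "\\.(pdb|cif)$",
                       full.names = TRUE)) {
    m <- load_model(f)
    fes <- select_atoms(m, elem = "FE", resid = c("FES", "2FE"))
    if (nrow(fes) == 0) fes <- select_atoms(m, elem = "FE")
    q10 <- select_atoms(m, resid = c("UQ", "U10", "UQ1"))
    if (nrow(fes) == 0 || nrow(q10) == 0) next
    gd <- group_distance(m, fes, q10, mode = "min")
    write_measurements_tsv(list(gd), report, model_name = basename(f))
    log_msg("measure", sprintf("%s: [2Fe-2S]-Q10 min distance %.1f Å",
                               basename(f), gd$value))
  }
} else {
  log_msg("measure", "no deposited models found; fixture measurements only")
}
log_msg("measure", "report written to ", report)
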