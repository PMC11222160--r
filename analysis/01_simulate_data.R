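#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data used by the downstream
# analyses — a curvature-indexed bilayer template bank, seeded micrographs
# with membrane segments and protein blobs, and 3D membrane volumes — and
# write them in standard formats under results/.

suppressPackageStartupMessages(library(cryomem))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(paths = list(out = out), seed = 1)
write_pipeline_config(cfg, file.path(out, "config.yaml"))

log_msg("simulate", "building 21-template bank, kappa 0..0.02 nm^-1")
bank <- make_template_bank(n_templates = 21, length = 400,
                           image_size = 128, pixel_size = 4)
write_mrc_stack(bank$images, file.path(out, "template_bank.mrcs"))
write_star(data.frame(template_id = seq_along(bank$kappas),
                      kappa_per_nm = bank$kappas),
           file.path(out, "template_bank.star"))

log_msg("simulate", "rendering 10 seeded micrographs (3 segments each, snr 0.5)")
for (i in 1:10) {
  img_seed <- cfg$seed * 100 + i
  segs <- cryomem:::with_seed(img_seed * 7, lapply(1:3, function(j)
    ground_truth_segment(
      centre = c(stats::runif(1, -250, 250),
                 (j - 2) * 320 + stats::runif(1, -60, 60)),
      theta = stats::runif(1, 0, 180),
      kappa = sample(seq(0, 0.02, by = 0.005), 1),
      length = 300)))
  spec <- sim_spec_2d(image_size = 256, pixel_size = 4, segments = segs,
                      n_blobs = 2, snr = 0.5, seed = img_seed)
  sim <- suppressWarnings(simulate_micrograph(spec))
  write_mrc(sim$image, file.path(out, sprintf("micrograph_%02d.mrc", i)))
  write_segments_star(sim$segments,
                      file.path(out, sprintf("micrograph_%02d_truth.star", i)))
}

log_msg("simulate", "rendering 3D membrane volumes (plane, sphere caps, sinusoid)")
vols <- list(
  plane = sim_spec_3d(grid_size = 64, voxel_size = 4, surface_kind = "plane"),
  sphere_R500 = sim_spec_3d(grid_size = 64, voxel_size = 4,
                            surface_kind = "sphere_cap",
                            surface_params = list(R = 500)),
  sinusoid = sim_spec_3d(grid_size = 64, voxel_size = 4,
                         surface_kind = "sinusoid",
                         surface_params = list(amplitude = 15,
                                               wavelength = 250)))
for (nm in names(vols)) {
  sim <- simulate_membrane_volume(vols[[nm]])
  write_mrc(sim$volume, file.path(out, sprintf("volume_%s.mrc", nm)))
}

log_msg("simulate", "writing coordinate fixtures (headgroup lattice + ligand)")
for (h in c(0, 16, 20)) {
  m <- make_fixture_model(model_fixture_spec(jitter_sigma = 2,
                                             ligand_height = h,
                                             seed = cfg$seed))
  write_model_pdb(m, file.path(out, sprintf("fixture_ligand_%02dA.pdb", h)))
}
log_msg("simulate", "done; outputs under ", out)
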