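#!/usr/bin/env Rscript
# Segment vessel models from the rendered modality images (vesselness
# detection + half-maximum surface extraction + component cleanup), estimate
# per-vertex radii on the gold model from its centerline, and build the
# sulcal model. Requires 01_simulate_phantoms.R output.

suppressPackageStartupMessages(library(seegplan))

pdir <- "results/phantom"
out <- "results/models"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

icv <- read_volume(file.path(pdir, "intracranial.nii.gz"))
gm <- read_volume(file.path(pdir, "gray_matter.nii.gz"))

meshes <- list()
for (nm in c("gold", "mid", "low")) {
  img <- read_volume(file.path(pdir, paste0("image_", nm, ".nii.gz")))
  m <- segment_vessel_model(img, icv)
  cat(sprintf("%s: %d vertices, %d faces (vesselness threshold %.3g, iso %.3g)\n",
              nm, nrow(m$vertices), nrow(m$faces),
              attr(m, "threshold"), attr(m, "surface_iso")))
  meshes[[nm]] <- m
}

gold <- extract_centerline_radii(meshes$gold, vol_grid(icv))
gold <- deblur_radii(gold, blur_sigma = 0.5)
cat(sprintf("gold radii: median %.2f mm, range %.2f-%.2f mm\n",
            median(gold$vertex_radius), min(gold$vertex_radius),
            max(gold$vertex_radius)))
write_mesh(gold, file.path(out, "vessels_gold.ply"))
write_mesh(meshes$mid, file.path(out, "vessels_mid.ply"))
write_mesh(meshes$low, file.path(out, "vessels_low.ply"))

for (th in c(1, 2, 3, 4)) {
  pr <- remove_small_components(prune_by_diameter(gold, th), 30)
  cat(sprintf("gold pruned at %d mm: %d vertices remain\n", th,
              nrow(pr$vertices)))
  write_mesh(pr, file.path(out, sprintf("vessels_gold_pruned_%dmm.ply", th)))
}

sulci <- extract_sulcal_model(gm, icv, erosion_mm = 5)
cat(sprintf("sulcal model: %d vertices\n", nrow(sulci$vertices)))
write_mesh(sulci, file.path(out, "sulci.ply"))
cat("wrote", out, "\n")
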