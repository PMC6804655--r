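#!/usr/bin/env Rscript
# Build one seeded head phantom and write its pieces to disk: the three
# modality images (shared ground-truth vascular tree rendered at visibility
# cutoffs 0 / 2 / 4 mm), anatomical masks, skull mesh, target ROIs and the
# ground-truth tree.

suppressPackageStartupMessages(library(seegplan))

seed <- 7L
out <- "results/phantom"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

phantom <- make_phantom(seed)
print(phantom)

for (nm in names(phantom$modality_images))
  write_volume(phantom$modality_images[[nm]],
               file.path(out, paste0("image_", nm, ".nii.gz")))
write_volume(phantom$intracranial_mask, file.path(out, "intracranial.nii.gz"))
write_volume(phantom$gm_mask, file.path(out, "gray_matter.nii.gz"))
write_volume(phantom$target_rois, file.path(out, "target_rois.nii.gz"))
write_mesh(phantom$skull_mesh, file.path(out, "skull.ply"))
write_tree_json(phantom$tree, file.path(out, "tree_truth.json"))

segs <- phantom$tree$segments
cat(sprintf("tree: %d segments, diameters %.2f-%.2f mm\n",
            nrow(segs), 2 * min(segs$radius), 2 * max(segs$radius)))
cat(sprintf("segments visible at 2 mm cutoff: %d; at 4 mm: %d\n",
            sum(2 * segs$radius >= 2), sum(2 * segs$radius >= 4)))
cat("wrote", out, "\n")
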