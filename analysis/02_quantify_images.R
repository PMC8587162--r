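#!/usr/bin/env Rscript
# Quantify the generated images: %LT/%BCD per berry and the six canopy
# parameters per scene; report recovery against the stored ground truth.
# Run 01_simulate_data.R first.
suppressMessages(library(grapevit))

syn <- "results/synthetic"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat("== berry vitality ==\n")
bm <- utils::read.csv(file.path(syn, "berry_manifest.csv"))
vit <- analyze_berry_manifest(bm)
vit$lt_truth <- bm$lt_truth
vit$error <- vit$lt_percent - vit$lt_truth
utils::write.csv(vit, file.path(out, "berry_vitality.csv"), row.names = FALSE)
print(as.data.frame(vit[, c("berry_id", "lt_percent", "bcd_percent",
                            "lt_truth", "error")]))
cat(sprintf("max |LT error|: %.2f points (budget: 2)\n", max(abs(vit$error))))

cat("\n== canopy architecture ==\n")
cm <- utils::read.csv(file.path(syn, "canopy_manifest.csv"))
can <- analyze_canopy_manifest(cm)
per_img <- can$per_image
per_img$ff_truth <- cm$ff_truth
per_img$phi_truth <- cm$phi_truth
utils::write.csv(per_img[, c("source_id", "plant_id", "fc", "ff", "phi", "lai",
                             "omega", "lai_e", "ff_truth", "phi_truth")],
                 file.path(out, "canopy_per_image.csv"), row.names = FALSE)
utils::write.csv(can$per_plant, file.path(out, "canopy_per_plant.csv"),
                 row.names = FALSE)
print(as.data.frame(per_img[, c("source_id", "ff", "ff_truth", "phi",
                                "phi_truth", "lai", "omega")]))
cat(sprintf("max |ff error|: %.4f (budget 0.02); max |phi error|: %.4f (budget 0.03)\n",
            max(abs(per_img$ff - per_img$ff_truth)),
            max(abs(per_img$phi - per_img$phi_truth))))
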