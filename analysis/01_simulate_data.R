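#!/usr/bin/env Rscript
# Generate every synthetic input kind with ground truth:
# berry fluorescence images, canopy scenes, NIR spectra, vineyard table.
suppressMessages(library(grapevit))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L

cat("== 1. berry images (known living-tissue fractions) ==\n")
berry_manifest <- do.call(rbind, lapply(seq_along(c(0.3, 0.55, 0.8)), function(i) {
  lt <- c(0.3, 0.55, 0.8)[i]
  b <- make_berry_image(lt, with_seed = (i == 2), rng_seed = seed + i)
  id <- sprintf("berry_%02d", i)
  img_path <- file.path(out, paste0(id, ".png"))
  write_rgb_image(b$image, img_path)
  write_ground_truth(b$truth, file.path(out, paste0(id, "_truth.json")))
  seed_path <- ""
  if (!is.null(b$truth$seed_polygon)) {
    seed_path <- file.path(out, paste0(id, "_seed.csv"))
    utils::write.csv(data.frame(row = b$truth$seed_polygon[, 1],
                                col = b$truth$seed_polygon[, 2]),
                     seed_path, row.names = FALSE)
  }
  cat(sprintf("  %s: target LT %.0f%%, interior %d px\n", id, 100 * lt,
              b$truth$interior_px))
  data.frame(berry_id = id, path = img_path, seed_path = seed_path,
             lt_truth = 100 * b$truth$lt_fraction_effective)
}))
utils::write.csv(berry_manifest, file.path(out, "berry_manifest.csv"),
                 row.names = FALSE)

cat("== 2. canopy scenes (known crown cover / porosity) ==\n")
scene_grid <- expand.grid(ff = c(0.67, 0.84), phi = c(0.19, 0.28))
canopy_manifest <- do.call(rbind, lapply(seq_len(nrow(scene_grid)), function(i) {
  sc <- make_canopy_scene(scene_grid$ff[i], scene_grid$phi[i],
                          rng_seed = seed + i)
  id <- sprintf("scene_%02d", i)
  img_path <- file.path(out, paste0(id, ".png"))
  write_rgb_image(sc$image, img_path)
  write_ground_truth(sc$truth, file.path(out, paste0(id, "_truth.json")))
  cat(sprintf("  %s: ff %.2f phi %.2f -> fc %.3f\n", id,
              sc$truth$ff, sc$truth$phi, sc$truth$fc))
  data.frame(source_id = id, path = img_path,
             plant_id = sprintf("plant_%02d", (i + 1) %/% 2),
             side = c("east", "west")[1 + (i %% 2)],
             ff_truth = sc$truth$ff, phi_truth = sc$truth$phi)
}))
utils::write.csv(canopy_manifest, file.path(out, "canopy_manifest.csv"),
                 row.names = FALSE)

cat("== 3. NIR spectra: 432 berries x 3 replicates ==\n")
nir <- make_nir_dataset(n_berries = 432, rng_seed = seed)
write_spectra_csv(nir$spectra, file.path(out, "nir_spectra.csv"))
write_ground_truth(nir$truth[c("death_band", "noise_sigma", "rng_seed")],
                   file.path(out, "nir_truth.json"))
utils::write.csv(data.frame(berry_id = sprintf("b%03d", seq_along(nir$truth$bcd)),
                            LT = nir$truth$lt, DT = nir$truth$bcd),
                 file.path(out, "nir_targets.csv"), row.names = FALSE)
cat(sprintf("  BCD truth range: %.1f-%.1f%%\n", min(nir$truth$bcd),
            max(nir$truth$bcd)))

cat("== 4. vineyard tables: canopy features -> vitality + sensory ==\n")
for (cult in c("shiraz", "chardonnay")) {
  n <- if (cult == "shiraz") 432L else 216L
  vd <- make_vineyard_dataset(n, cultivar = cult, rng_seed = seed)
  utils::write.csv(vd$data, file.path(out, paste0("vineyard_", cult, ".csv")),
                   row.names = FALSE)
  write_ground_truth(vd$truth[c("teacher", "noise_sigma_vitality",
                                "noise_sigma_sensory", "cultivar", "rng_seed")],
                     file.path(out, paste0("vineyard_", cult, "_truth.json")))
  cat(sprintf("  %s: %d samples, LT %.0f-%.0f%%\n", cult, n,
              min(vd$data$LT), max(vd$data$LT)))
}
cat("done; artifacts under", out, "\n")
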