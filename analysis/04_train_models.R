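#!/usr/bin/env Rscript
# Train the four regression workflows on the synthetic datasets and write
# the per-stage accuracy tables, outlier reports and a group comparison.
# Run 01_simulate_data.R first.
suppressMessages(library(grapevit))

syn <- "results/synthetic"
out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L

canopy_cols <- c("lai", "lai_e", "fc", "ff", "phi", "omega")

cat("== Model 1: NIR derivative features -> LT/DT (Bayesian regularization) ==\n")
spectra <- read_spectra_csv(file.path(syn, "nir_spectra.csv"))
X1 <- nir_features(spectra)                       # SG derivative, 1596-1919 nm
tg <- utils::read.csv(file.path(syn, "nir_targets.csv"))
stopifnot(identical(rownames(X1), tg$berry_id))
rep1 <- run_model(1, X1, as.matrix(tg[, c("LT", "DT")]), seed = seed)
print(rep1)
write_model_report(rep1, out)

cat("\n== Model 2: canopy features -> LT/DT (Levenberg-Marquardt) ==\n")
shz <- utils::read.csv(file.path(syn, "vineyard_shiraz.csv"), check.names = FALSE)
rep2 <- run_model(2, as.matrix(shz[, canopy_cols]),
                  as.matrix(shz[, c("LT", "DT")]), seed = seed)
print(rep2)
write_model_report(rep2, out)

cat("\n== Models 3-4: canopy features -> ten sensory descriptors ==\n")
for (spec in list(list(id = 3, cultivar = "chardonnay"),
                  list(id = 4, cultivar = "shiraz"))) {
  vd <- utils::read.csv(file.path(syn, sprintf("vineyard_%s.csv", spec$cultivar)),
                        check.names = FALSE)
  vd <- vd[seq_len(min(nrow(vd), 216L)), ]        # 216 samples per cultivar
  sens_cols <- setdiff(names(vd), c("sample_id", "cultivar", canopy_cols,
                                    "LT", "DT"))
  rep_s <- run_model(spec$id, as.matrix(vd[, canopy_cols]),
                     as.matrix(vd[, sens_cols]), seed = seed)
  print(rep_s)
  write_model_report(rep_s, out)
}

cat("\n== neuron trimming demonstration (Model 2 inputs) ==\n")
sp <- split_dataset(nrow(shz), c(0.6, 0.2, 0.2), seed)
trim <- neuron_trimming(
  as.matrix(shz[, canopy_cols]), as.matrix(shz[, c("LT", "DT")]), sp,
  network_config(6, 3, 2, max_epochs = 200, seed = seed)
)
print(as.data.frame(trim$candidates))
cat("selected hidden-layer size:", trim$selected, "\n")
utils::write.csv(trim$candidates, file.path(out, "model2_trimming.csv"),
                 row.names = FALSE)

cat("\n== vigor-group comparison of LT (ANOVA + Tukey letters) ==\n")
vigor <- cut(shz$lai, quantile(shz$lai, c(0, 1/3, 2/3, 1)),
             labels = c("low", "medium", "high"), include.lowest = TRUE)
cmp <- anova_tukey(shz$LT, vigor)
print(as.data.frame(cmp$table))
cat(sprintf("F = %.1f, p = %.3g\n", cmp$f_statistic, cmp$p_value))
utils::write.csv(cmp$table, file.path(out, "lt_by_vigor_group.csv"),
                 row.names = FALSE)
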