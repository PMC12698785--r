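#!/usr/bin/env Rscript

# Step 3 — interrogate the published cost surface.
#
# Evaluates the published quadratic cost-of-transport surface against the
# published condition means, locates its extrema over the tested box,
# classifies the per-depth cost-speed curves, and predicts cost and
# metabolic power at the self-selected speeds.

suppressPackageStartupMessages(library(aquacot))

surf <- study_surface()
cond <- study_condition_means()

pred <- evaluate_surface(surf, cond$speed, cond$depth)
r2 <- prediction_agreement(pred, cond$cot)$r_squared
cat(sprintf("published surface vs condition means: R^2 = %.4f\n", r2))

ext <- surface_extrema(surf)
cat(sprintf("minimum %.2f J/kg/m at %.2f m/s, %.2f m (%s)\n",
            ext$minimum$cot, ext$minimum$speed, ext$minimum$depth,
            ext$minimum$location))
cat(sprintf("maximum %.2f J/kg/m at %.2f m/s, %.2f m (%s)\n",
            ext$maximum$cot, ext$maximum$speed, ext$maximum$depth,
            ext$maximum$location))

cat("\nper-depth cost-speed curve shapes:\n")
curves <- lapply(split(cond, cond$depth_label), function(d) {
  per_depth_curve(d$speed, d$cot, name = d$depth_label[1])
})
for (cv in curves) {
  cat(sprintf("  %-10s curvature %+.2f  shape: %s\n",
              cv$name, cv$coefficients[1], cv$shape))
}

ss <- self_selected_summary(surf, study_self_selected_speeds(),
                            c(knee = 0.5, hip = 0.85,
                              umbilicus = 1.12, xiphoid = 1.3))
cat("\nself-selected speed predictions:\n")
print(ss, row.names = FALSE, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(ss, "results/self_selected.csv", row.names = FALSE)
jsonlite::write_json(
  list(r_squared_vs_means = r2, extrema = ext,
       coefficients = as.list(surf$coefficients)),
  "results/surface_interrogation.json", auto_unbox = TRUE, digits = NA
)
cat("\nwritten: results/self_selected.csv, results/surface_interrogation.json\n")
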