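#!/usr/bin/env Rscript

# Step 4 — iso-cost speeds against reference locomotion modes.
#
# Fits per-depth quadratic cost-speed curves to the published condition
# means and intersects them with user-supplied reference curves (front-crawl
# swimming, dry-land walking). Reference coefficients are configuration:
# copy inst/extdata/reference_curves_template.json, fill in the quadratic
# coefficients from the source equations, and pass the path as the first
# argument. With the unfilled template, the stage reports itself skipped.

suppressPackageStartupMessages(library(aquacot))

args <- commandArgs(trailingOnly = TRUE)
ref_path <- if (length(args) >= 1) args[1] else {
  system.file("extdata", "reference_curves_template.json",
              package = "aquacot")
}

cond <- study_condition_means()
curves <- lapply(split(cond, cond$depth_label), function(d) {
  per_depth_curve(d$speed, d$cot, name = d$depth_label[1])
})

raw <- jsonlite::read_json(ref_path, simplifyVector = FALSE)
filled <- Filter(function(r) !any(vapply(r$coefficients, is.null,
                                         logical(1))), raw)
if (length(filled) == 0) {
  cat(sprintf("no filled reference curves in %s — iso-cost stage skipped\n",
              ref_path))
  quit(status = 0)
}
refs <- lapply(filled, function(r) {
  cot_curve(unlist(r$coefficients), unlist(r$speed_range), r$name)
})

rows <- list()
for (cv in curves) {
  for (rf in refs) {
    pts <- iso_cost_speed(cv, rf, cv$speed_range)
    if (nrow(pts) > 0) {
      rows[[length(rows) + 1L]] <-
        cbind(depth_label = cv$name, reference = rf$name, pts)
    } else {
      cat(sprintf("  %s vs %s: no intersection in [%.1f, %.1f] m/s\n",
                  cv$name, rf$name, cv$speed_range[1], cv$speed_range[2]))
    }
  }
}
if (length(rows) > 0) {
  iso <- do.call(rbind, rows)
  print(iso, row.names = FALSE, digits = 3)
  dir.create("results", showWarnings = FALSE)
  write.csv(iso, "results/isocost.csv", row.names = FALSE)
  cat("written: results/isocost.csv\n")
}
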