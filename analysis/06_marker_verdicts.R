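#!/usr/bin/env Rscript
# Per-marker sexing verdicts and the recommended marker panel for each
# species-style bundle, plus the human-readable report.

suppressPackageStartupMessages(library(zwmarkers))
out <- "results/verdicts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- turaco_reference_fixture()
verdicts <- do.call(rbind, lapply(names(fx$species), function(sp)
  run_marker_pipeline(fx$species[[sp]], fx$primers,
                      species_id = sp)$verdicts))
print(verdicts[, c("species_id", "marker_id", "verdict",
                   "gel_pct_required", "delta_L")])
utils::write.table(verdicts, file.path(out, "verdicts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(verdicts, file.path(out, "verdicts.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
panel <- recommend_panel(verdicts)
utils::write.table(panel, file.path(out, "panel.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(species_report(verdicts, panel),
           file.path(out, "report.md"))
top <- panel[panel$rank %in% 1L, c("species_id", "marker_id")]
message("top marker per bundle: ",
        paste(sprintf("%s->%s", top$species_id, top$marker_id),
              collapse = ", "))
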