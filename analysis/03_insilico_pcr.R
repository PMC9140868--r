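#!/usr/bin/env Rscript
# Predict Z-specific amplicons for the seven markers: degenerate-primer
# scan, product enumeration, and exon/intron composition per product.
# Writes a marker table (TSV) and BED of amplicon coordinates. The
# SPIN-derived marker (M6) finds no binding sites, reproducing its
# "unknown" status in the reference assemblies.

suppressPackageStartupMessages(library(zwmarkers))
out <- "results/insilico_pcr"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- turaco_reference_fixture()
run <- run_marker_pipeline(fx$species$erythrolophus, fx$primers,
                           species_id = "reference")
z <- run$z_amplicons
print(z[, c("marker_id", "seq_id", "fwd_pos5", "rev_pos5", "length",
            "composition")])
amplicons_to_tsv(z, file.path(out, "z_amplicons.tsv"))
amplicons_to_bed(z, file.path(out, "z_amplicons.bed"))
amplicons_to_tsv(run$amplicons, file.path(out, "all_products.tsv"))
missing <- setdiff(fx$primers$marker, z$marker_id)
message("markers with no predicted Z product: ",
        paste(missing, collapse = ", "))
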