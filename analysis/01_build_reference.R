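#!/usr/bin/env Rscript
# Build the synthetic reference landscape (three species-style bundles
# engineered to the published turaco marker geometry) and write its
# sequences, role maps and transcripts under results/reference/.

suppressPackageStartupMessages(library(zwmarkers))
out <- "results/reference"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- turaco_reference_fixture()
for (sp in names(fx$species)) {
  b <- fx$species[[sp]]
  write_genome_fasta(b$sequences, file.path(out, paste0(sp, ".fasta")))
  write_role_map(b$roles, file.path(out, paste0(sp, "_roles.yaml")))
  if (!is.null(b$mrnas))
    write_genome_fasta(b$mrnas, file.path(out, paste0(sp, "_mrna.fasta")))
  message(sp, ": ", length(b$sequences), " sequences, ",
          sum(Biostrings::width(b$sequences)), " bp total")
}
utils::write.table(fx$primers, file.path(out, "primers.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("reference landscape written to ", out)
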