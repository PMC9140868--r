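#!/usr/bin/env Rscript
# Infer exon/intron structure of the CHD1- and NIPBL-like genes by
# spliced mapping of their transcripts, and export the models (GFF3) and
# intron tables (TSV). The intron tables carry the marker-relevant
# lengths: intron 9 (2852 bp), 16 (335 bp) and 22 (185 bp) of CHD1, and
# intron 17 (801 bp) of NIPBL -- including the fact that the NIPBL
# primer pair named for intron 16 actually brackets intron 17 here.

suppressPackageStartupMessages(library(zwmarkers))
out <- "results/gene_structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- turaco_reference_fixture()
ery <- fx$species$erythrolophus
for (i in seq_len(nrow(ery$mrna_targets))) {
  tg <- ery$mrna_targets[i, ]
  m <- map_exons(as.character(ery$mrnas[[tg$mrna_id]]),
                 as.character(ery$sequences[[tg$seq_id]]),
                 gene_id = tg$gene_id, seq_id = tg$seq_id)
  print(m)
  export_gff3(m, file.path(out, paste0(tg$mrna_id, ".gff3")))
  it <- intron_table(m)
  utils::write.table(it, file.path(out, paste0(tg$mrna_id, "_introns.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  key <- it[it$intron %in% c(9L, 16L, 17L, 22L), ]
  message(tg$gene_id, " on ", tg$seq_id, ": ",
          paste(sprintf("I%d=%d bp", key$intron, key$length),
                collapse = ", "))
}
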