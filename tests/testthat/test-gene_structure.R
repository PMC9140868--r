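# Spliced mapping and gene-model bookkeeping.

make_planted_gene <- function(exon_lengths, intron_lengths, pad = 120L) {
  built <- zwmarkers:::.gene_build(exon_lengths, intron_lengths)
  n <- length(built$exons)
  pieces <- character(2L * n - 1L)
  pieces[seq(1, 2 * n - 1, 2)] <- built$exons
  if (n > 1L) pieces[seq(2, 2 * n - 2, 2)] <- built$introns
  gene <- paste(pieces, collapse = "")
  genome <- paste0(random_dna(pad), gene, random_dna(pad))
  starts <- pad + 1L +
    cumsum(c(0L, head(nchar(built$exons), -1L) + nchar(built$introns)))
  list(genome = genome,
       mrna = paste(built$exons, collapse = ""),
       exons = data.frame(start = starts,
                          end = starts + nchar(built$exons) - 1L))
}

test_that("gene_model derives introns and enforces exon ordering", {
  m <- gene_model("g", "s", data.frame(start = c(1, 21), end = c(10, 30)))
  expect_equal(m$introns$start, 11L)
  expect_equal(m$introns$end, 20L)
  expect_equal(m$introns$length, 10L)
  expect_equal(intron_table(m),
               data.frame(intron = 1L, start = 11L, end = 20L,
                          length = 10L))
  single <- gene_model("g", "s", data.frame(start = 5, end = 50))
  expect_equal(nrow(intron_table(single)), 0L)
  expect_error(gene_model("g", "s",
                          data.frame(start = c(1, 5), end = c(10, 30))),
               "separated|increasing")
})

test_that("map_exons recovers a planted two-exon structure exactly", {
  set.seed(201)
  g <- make_planted_gene(c(100L, 200L), 50L, pad = 0L)
  m <- map_exons(g$mrna, g$genome, gene_id = "toy")
  expect_equal(m$exons, data.frame(start = c(1L, 151L), end = c(100L, 350L)))
  expect_equal(intron_table(m)$length, 50L)
})

test_that("an mRNA equal to the genome maps as one intronless exon", {
  set.seed(202)
  s <- random_dna(400)
  m <- map_exons(s, s)
  expect_equal(nrow(m$exons), 1L)
  expect_equal(m$exons$start, 1L)
  expect_equal(m$exons$end, 400L)
  expect_equal(nrow(m$introns), 0L)
})

test_that("an unrelated mRNA is reported unmappable", {
  set.seed(203)
  expect_error(map_exons(random_dna(300), random_dna(2000)),
               "unmappable")
})

test_that("minus-strand genes map via reverse-complement normalization", {
  set.seed(204)
  g <- make_planted_gene(c(120L, 150L, 90L), c(200L, 80L))
  m_plus <- map_exons(g$mrna, g$genome, gene_id = "toy")
  m_minus <- map_exons(g$mrna, revcomp(g$genome), gene_id = "toy")
  expect_equal(m_minus$strand, "-")
  gl <- nchar(g$genome)
  expect_equal(m_minus$exons$start, rev(gl - m_plus$exons$end + 1L))
  expect_equal(m_minus$exons$end, rev(gl - m_plus$exons$start + 1L))
  # feature numbering follows transcription order on the minus strand
  f <- gene_features(m_minus)
  expect_equal(f$tag[1L], paste0("E", nrow(m_minus$exons)))
})

test_that("planted structures are recovered exactly across random configurations", {
  n_cfg <- 60L
  fail <- 0L
  for (seed in seq_len(n_cfg)) {
    set.seed(300 + seed)
    n_ex <- sample(2:5, 1)
    exl <- sample(60:250, n_ex, replace = TRUE)
    inl <- sample(30:400, n_ex - 1, replace = TRUE)
    g <- make_planted_gene(exl, inl)
    mrna <- g$mrna
    # sprinkle sub-2% divergence away from junctions (20 bp margins)
    n_mut <- floor(0.01 * nchar(mrna))
    if (n_mut > 0) {
      margins <- unlist(lapply(seq_len(n_ex), function(i) {
        qs <- sum(exl[seq_len(i - 1)]) + 1L
        qe <- qs + exl[i] - 1L
        if (qe - 20L >= qs + 20L) (qs + 20L):(qe - 20L) else integer()
      }))
      pos <- sample(margins, min(n_mut, length(margins)))
      ch <- strsplit(mrna, "")[[1]]
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      mrna <- paste(ch, collapse = "")
    }
    m <- try(map_exons(mrna, g$genome), silent = TRUE)
    if (inherits(m, "try-error") || !identical(m$exons, g$exons))
      fail <- fail + 1L
  }
  expect_equal(fail, 0L)
})

test_that("exon+intron lengths conserve the gene span", {
  for (seed in 1:10) {
    set.seed(400 + seed)
    n_ex <- sample(2:4, 1)
    g <- make_planted_gene(sample(60:200, n_ex, TRUE),
                           sample(40:300, n_ex - 1, TRUE))
    m <- map_exons(g$mrna, g$genome)
    span <- m$exons$end[nrow(m$exons)] - m$exons$start[1] + 1L
    expect_equal(sum(m$exons$end - m$exons$start + 1L) +
                   sum(m$introns$length), span)
  }
})

test_that("a primer pair named for one intron can be reported as amplifying another", {
  # a marker whose name says intron 16 but whose product, per the model,
  # spans intron 17: the composition annotation is what settles it
  set.seed(205)
  g <- make_planted_gene(rep(80L, 18L), sample(60:120, 17L, TRUE))
  m <- map_exons(g$mrna, g$genome, gene_id = "NIPBLlike")
  amp <- list(start = m$exons$end[17] - 10L, end = m$exons$start[18] + 10L)
  comp <- annotate_composition(amp, m)
  expect_true("I17" %in% comp$segments$tag)
  expect_false("I16" %in% comp$segments$tag)
})

test_that("GFF3 export writes 1-based inclusive gene and exon features", {
  m <- gene_model("g1", "chrZ",
                  data.frame(start = c(11, 101), end = c(50, 160)))
  f <- withr::local_tempfile(fileext = ".gff3")
  export_gff3(m, f)
  back <- rtracklayer::import(f)
  ex <- back[back$type == "exon"]
  expect_equal(GenomicRanges::start(ex), c(11L, 101L))
  expect_equal(GenomicRanges::end(ex), c(50L, 160L))
})
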