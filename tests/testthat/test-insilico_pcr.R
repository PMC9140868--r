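test_that("iupac_match expands degenerate codes, N in target never matches", {
  expect_true(iupac_match("R", "A"))
  expect_true(iupac_match("R", "G"))
  expect_false(iupac_match("R", "C"))
  expect_false(iupac_match("W", "N"))
  expect_false(iupac_match("N", "N"))
  expect_true(all(iupac_match(c("Y", "Y"), c("C", "T"))))
  expect_error(iupac_match("X", "A"), "illegal")
  expect_setequal(iupac_expand("B"), c("C", "G", "T"))
})

test_that("scan_primer finds planted exact and degenerate sites", {
  set.seed(101)
  s <- random_dna(2000)
  p <- "TCTGCATCGCTAAATCCTTT"
  s <- plant_at(s, 101, p)
  st <- scan_primer(s, p)
  expect_true(any(st$strand == "+" & st$pos5 == 101 & st$mismatches == 0))

  # degenerate primer matches a concrete realization with 0 mismatches
  st2 <- scan_primer("CTCCCAAGGATGAGAAACTG", "CTCCCAAGGATGAGRAAYTG",
                     max_mismatch = 0)
  expect_equal(st2$pos5, 1L)
  expect_equal(st2$mismatches, 0L)

  # minus-strand site: pos5 is the 5'-most base, i.e. the right footprint end
  s3 <- plant_at(random_dna(600), 301, revcomp(p))
  st3 <- scan_primer(s3, p)
  expect_true(any(st3$strand == "-" & st3$pos5 == 320))
})

test_that("three_prime_exact rejects 3'-terminal mismatches only", {
  set.seed(7)
  s <- random_dna(500)
  p <- "ACGTACGTACGTACGTACGT"
  mut5 <- p; substr(mut5, 2, 2) <- "T"   # 5' mismatch: tolerated
  mut3 <- p; substr(mut3, 20, 20) <- "C" # 3' terminal mismatch: fatal
  s1 <- plant_at(s, 101, mut5)
  s2 <- plant_at(s, 101, mut3)
  expect_true(any(scan_primer(s1, p)$pos5 == 101))
  expect_false(any(scan_primer(s2, p)$pos5 == 101))
})

test_that("scan_primer equals the brute-force oracle on random sequences", {
  primers <- c("TCTGCATCGCTAAATCCTTT", "CTCCCAAGGATGAGRAAYTG",
               "AGAAGATGSWCTGAARTCCAGCT")
  for (seed in 1:6) {
    set.seed(seed)
    s <- random_dna(2000)
    p <- primers[(seed %% length(primers)) + 1L]
    # plant a handful of mutated copies so hits exist
    for (at in c(101, 601, 1201)) {
      v <- p
      pos <- sample(nchar(p) - 3L, 1L)
      substr(v, pos, pos) <- sample(c("A", "C", "G", "T"), 1L)
      s <- plant_at(s, at, chartr("RYSWKMBDHVN", "ACGAGACAAAA", v))
    }
    got <- scan_primer(s, p, max_mismatch = 3L)
    want <- brute_scan(s, p, max_mismatch = 3L)
    expect_equal(got$pos5, want$pos5)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("scan_primer treats N in the target as unmatched", {
  s <- paste0("AAAA", "TCTGCATCGCTAAATCCTTT", "AAAA")
  substr(s, 10, 10) <- "N"
  st <- scan_primer(s, "TCTGCATCGCTAAATCCTTT", max_mismatch = 0)
  expect_equal(nrow(st), 0L)
  st1 <- scan_primer(s, "TCTGCATCGCTAAATCCTTT", max_mismatch = 1)
  expect_equal(st1$mismatches, 1L)
})

test_that("enumerate_amplicons applies the pos5 length convention", {
  f <- data.frame(seq_id = "s", strand = "+", pos5 = 1L, start = 1L,
                  end = 20L, mismatches = 0L)
  r <- data.frame(seq_id = "s", strand = "-", pos5 = 50L, start = 31L,
                  end = 50L, mismatches = 0L)
  a <- enumerate_amplicons(f, r, marker_id = "MX")
  expect_equal(a$length, 50L)
  expect_equal(a$start, 1L)
  expect_equal(a$end, 50L)

  # combinatorics: all convergent in-range pairs reported, sorted
  f2 <- rbind(f, transform(f, pos5 = 201L, start = 201L, end = 220L))
  r2 <- rbind(r, transform(r, pos5 = 400L, start = 381L, end = 400L))
  a2 <- enumerate_amplicons(f2, r2, marker_id = "MX")
  expect_equal(nrow(a2), 3L)  # (1,50) (1,400) (201,400)
  expect_equal(a2$length, c(50L, 400L, 200L))
  # max_product filters
  a3 <- enumerate_amplicons(f2, r2, max_product = 100L)
  expect_equal(nrow(a3), 1L)
})

test_that("published marker positions reproduce printed lengths under the convention", {
  ref <- read_marker_reference()
  ref <- ref[!is.na(ref$length), ]
  expect_equal(nrow(ref), 6L)
  expect_equal(abs(ref$rev_pos - ref$fwd_pos) + 1L, ref$length)
})

test_that("composition annotation intersects amplicons with gene features", {
  m <- gene_model("g", "s", data.frame(start = c(1, 151), end = c(100, 350)))
  amp <- list(start = 71, end = 250)
  comp <- annotate_composition(amp, m)
  expect_equal(comp$segments$tag, c("E1", "I1", "E2"))
  expect_equal(comp$segments$overlap, c(30L, 50L, 100L))
  expect_equal(comp$total, 180L)
  expect_equal(comp$composition, "E1(30)/I1(50)/E2(100)")

  inside <- annotate_composition(list(start = 10, end = 60), m)
  expect_equal(inside$segments$tag, "E1")
  expect_equal(inside$total, 51L)

  expect_warning(out <- annotate_composition(list(start = 400, end = 450), m),
                 "outside")
  expect_true(out$outside_gene)
  expect_equal(nrow(out$segments), 0L)
})

test_that("amplicon BED export converts 1-based inclusive to 0-based half-open", {
  amps <- data.frame(marker_id = "M1", seq_id = "s", start = 101L,
                     end = 200L, length = 100L)
  f <- withr::local_tempfile(fileext = ".bed")
  amplicons_to_bed(amps, f)
  fields <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(100L, 200L))
})

test_that("an inner-variant primer pair nests strictly inside the outer pair's product", {
  # the intron-16 pairs bind the same template: the inner product must lie
  # strictly inside the outer one and span the same intron
  fx <- turaco_reference_fixture()
  ery <- fx$species$erythrolophus
  amps <- predict_amplicons(ery$sequences["chd1_Za"], fx$primers)
  outer <- amps[amps$marker_id == "M4", ]
  inner <- amps[amps$marker_id == "M5", ]
  expect_equal(nrow(outer), 1L)
  expect_equal(nrow(inner), 1L)
  expect_gt(inner$start, outer$start)
  expect_lt(inner$end, outer$end)
  model <- ery$truth$models$CHD1a
  for (a in list(outer, inner)) {
    comp <- annotate_composition(a, model)
    expect_true("I16" %in% comp$segments$tag)
  }
})
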