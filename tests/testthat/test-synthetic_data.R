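# Generator determinism, planted truth, and end-to-end recovery.

test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(seed = 77L)
  s1 <- simulate_zw(cfg)
  s2 <- simulate_zw(cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_zw(sim_config(seed = 78L))
  expect_false(identical(as.character(s1$sequences),
                         as.character(s3$sequences)))
})

test_that("planted truth is self-consistent", {
  sim <- simulate_zw(sim_config(seed = 5L))
  amp <- sim$truth$amplicons
  expect_equal(amp$length, amp$end - amp$start + 1L)
  # composition segments sum to the amplicon length
  segs <- as.integer(unlist(regmatches(amp$composition,
                                       gregexpr("[0-9]+(?=\\))",
                                                amp$composition,
                                                perl = TRUE))))
  expect_equal(sum(segs), amp$length)
  # the truth gene model obeys the package's own invariants
  m <- sim$truth$models[[1]]
  expect_s3_class(m, "gene_model")
  expect_true(all(m$introns$length >= 1L))
  # mRNA is the exon concatenation
  z <- as.character(sim$sequences[["Zsim"]])
  expect_equal(as.character(sim$mrnas[[1]]),
               paste(substring(z, m$exons$start, m$exons$end),
                     collapse = ""))
})

test_that("planted primer sites are the only sites found", {
  sim <- simulate_zw(sim_config(seed = 13L))
  p <- sim$primers
  st <- scan_primer(as.character(sim$sequences[["Zsim"]]), p$fwd_seq[1],
                    seq_id = "Zsim")
  expect_equal(nrow(st[st$strand == "+", ]), 1L)
  expect_equal(st$pos5[st$strand == "+"], sim$truth$sites$fwd_pos5)
})

test_that("a truncated second copy is marked partial in truth and recovered", {
  cfg <- sim_config(seed = 31L)
  cfg$markers[[1]]$truncate_to <- c(200L, 520L)
  sim <- simulate_zw(cfg)
  expect_true(sim$truth$markers$partial)
  expect_true(is.na(sim$truth$markers$delta_L))
  run <- run_marker_pipeline(sim, sim$primers)
  expect_true(run$reports$partial)
  expect_true(is.na(run$reports$delta_L))
  expect_equal(run$verdicts$verdict[run$verdicts$marker_id == "MZ1"],
               "partial_copy_only")
})

test_that("degenerate primer positions realized differently on Z and W still amplify", {
  cfg <- sim_config(seed = 41L, degenerate_divergent = TRUE)
  sim <- simulate_zw(cfg)
  run <- run_marker_pipeline(sim, sim$primers)
  # W copy found despite the R-position differing between gametologs
  expect_equal(run$reports$second_location, "W")
  expect_equal(run$reports$delta_L, 43L)
  # and the W copy itself yields a W-side amplicon with the same primers
  amps_w <- run$amplicons[run$amplicons$seq_id == "Wsim", ]
  expect_equal(nrow(amps_w), 1L)
  expect_equal(amps_w$length, run$reports$second_length)
})

test_that("nonspecific plants yield extra products and a confounded verdict when close", {
  cfg <- sim_config(seed = 51L,
                    nonspecific = list(list(marker_id = "MZ1",
                                            length = 515L)))
  sim <- simulate_zw(cfg)
  run <- run_marker_pipeline(sim, sim$primers,
                             nonspecific = list(MZ1 = 515))
  amps_z <- run$amplicons[run$amplicons$seq_id == "Zsim", ]
  expect_gte(nrow(amps_z), 2L)  # true product + planted nonspecific
  v <- run$verdicts[run$verdicts$marker_id == "MZ1", ]
  # 515 bp sits in the diagnostic window of a 520/477 pair
  expect_equal(v$verdict, "confounded")
})

test_that("simulation bundles round-trip through disk", {
  sim <- simulate_zw(sim_config(seed = 61L))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  back <- read_genome_fasta(file.path(d, "genome.fasta"))
  expect_identical(as.character(back), as.character(sim$sequences))
  roles <- read_role_map(file.path(d, "roles.yaml"))
  expect_identical(roles, sim$roles)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$markers[[1]]$delta_L, 43L)
})

test_that("recovery_report flags deliberate perturbations", {
  sim <- simulate_zw(sim_config(seed = 71L))
  run <- run_marker_pipeline(sim, sim$primers)
  rec <- recovery_report(run, sim$truth)
  expect_true(rec$exact)
  expect_equal(sum(rec$stages$n_exact), sum(rec$stages$n_expected))
  broken <- run
  broken$reports$delta_L <- broken$reports$delta_L + 1L
  rec2 <- recovery_report(broken, sim$truth)
  expect_false(rec2$exact)
  expect_true(any(grepl("delta", rec2$mismatches)))
  empty <- run
  empty$z_amplicons <- run$z_amplicons[0, ]
  empty$reports <- run$reports[0, ]
  rec3 <- recovery_report(empty, sim$truth)
  expect_equal(rec3$stages$n_exact[rec3$stages$stage == "amplicons"], 0L)
})

test_that("reference fixture reproduces the published marker landscape", {
  fx <- turaco_reference_fixture()
  ery <- fx$species$erythrolophus
  # gene models planted at the published-geometry coordinates
  chd <- ery$truth$models$CHD1a
  it <- intron_table(chd)
  expect_equal(it$length[it$intron == 9], 2852L)
  expect_equal(it$length[it$intron == 16], 335L)
  expect_equal(it$length[it$intron == 22], 185L)
  nip <- ery$truth$models$NIPBL
  expect_equal(intron_table(nip)$length[17], 801L)
  # spliced mapping recovers those models from the bundled transcripts
  m <- map_exons(as.character(ery$mrnas[["NIPBL_mrna"]]),
                 as.character(ery$sequences[["nipbl_Z"]]),
                 gene_id = "NIPBL", seq_id = "nipbl_Z")
  expect_equal(m$exons, nip$exons)
})
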