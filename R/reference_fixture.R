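# Synthetic reference fixture.
#
# Deterministic synthetic sequences engineered so that the full pipeline
# reproduces the marker geometry reported for the published turaco genome
# assemblies: the six locatable markers' amplicon lengths and exon/intron
# compositions (M1 367 = E22 30/I22 185/E23 152; M2 258; M3 2997; M4 504;
# M5 464; M7 923 = E17 54/I17 801/E18 68), the per-primer positions whose
# arithmetic gives those lengths, and the female second-copy lengths
# (378, 269, 623, 461, 421, 510) with their Z/W length polymorphisms
# (11, 11, 2374, 43, 43, 413). These are synthetic stand-ins, not the
# GenBank sequences: background is random, only the marker geometry is
# engineered.
#
# One structural point: the published positions put the M1 and M2
# upstream primers on overlapping, sequence-incompatible footprints
# (their printed exon-22 fragments force the overlap), so no single
# sequence can carry exact binding sites for both pairs. The fixture
# therefore ships two copies of the CHD1-like Z region ("chd1_Za" exact
# for M1/M3/M4/M5, "chd1_Zb" exact for M2), each with a matching
# transcript, plus matched second-copy regions on a decoy scaffold.

.FIXTURE_SEED <- 932L

# CHD1-like exon/intron length plan (1-based; anchors chosen so that the
# published primer positions fall out exactly)
.chd1_plan <- function() {
  exon_lengths <- c(rep(180L, 8L), 120L, 150L, rep(200L, 5L), 250L, 120L,
                    rep(200L, 4L), 146L, 200L, 150L, 400L)
  intron_lengths <- c(rep(300L, 8L), 2852L, rep(800L, 5L), 791L, 335L,
                      rep(672L, 5L), 185L, 400L, 350L)
  list(exon_lengths = exon_lengths, intron_lengths = intron_lengths,
       gene_start = 25433L, seq_len = 46500L)
}

.nipbl_plan <- function() {
  exon_lengths <- c(rep(180L, 16L), 140L, 160L, 200L)
  intron_lengths <- c(rep(4060L, 15L), 4054L, 801L, 500L)
  list(exon_lengths = exon_lengths, intron_lengths = intron_lengths,
       gene_start = 1000L, seq_len = 71500L)
}

# exon coordinate table from a plan
.plan_exons <- function(plan) {
  starts <- plan$gene_start +
    cumsum(c(0L, utils::head(plan$exon_lengths, -1L) + plan$intron_lengths))
  data.frame(start = starts, end = starts + plan$exon_lengths - 1L)
}

# overwrite bases of a sequence string (1-based inclusive)
.plant <- function(seq, at, what) {
  substr(seq, at, at + nchar(what) - 1L) <- what
  seq
}

# copy a region [from, to] of `src`, apply substitutions at `rate`
# (protecting the given absolute intervals), then apply one intron indel:
# delete `delta` bases starting at `del_at` (absolute) when delta > 0, or
# insert `-delta` random bases before `del_at` when delta < 0.
.copy_with_indel <- function(src, from, to, delta, del_at, rate,
                             protect_abs) {
  region <- substring(src, from, to)
  loc <- function(p) p - from + 1L
  protect <- lapply(protect_abs, function(iv) c(loc(iv[1L]), loc(iv[2L])))
  protect <- c(protect, list(c(1L, 5L), c(nchar(region) - 4L, nchar(region)),
                             c(loc(del_at) - 4L,
                               loc(del_at) + abs(delta) + 4L)))
  region <- .apply_divergence(region, rate, protect)
  d <- loc(del_at)
  if (delta > 0L)
    paste0(substring(region, 1L, d - 1L), substring(region, d + delta))
  else
    paste0(substring(region, 1L, d - 1L), .rand_dna(-delta),
           substring(region, d))
}

.fixture_env <- new.env(parent = emptyenv())

#' Synthetic reference fixture of the turaco marker landscape
#'
#' Builds, deterministically, three species-style sequence bundles:
#'
#' * `erythrolophus`: two CHD1-like Z records and one NIPBL-like Z record
#'   carrying exact binding sites for the packaged primers at the
#'   published per-primer positions, a W record carrying the NIPBL
#'   intron-17 second copy (413 bp shorter), and a decoy scaffold
#'   carrying the CHD1-derived second copies (intron 22 11 bp longer,
#'   intron 9 2374 bp shorter, intron 16 43 bp shorter), all at ~3%
#'   substitution divergence outside primer footprints.
#' * `concolor`: a Z-style record and a scaffold record with two
#'   equal-length copies of the intron-22 amplicon (delta-L 0).
#' * `cristata`: a Z-style record with the NIPBL amplicon and a 1255 bp
#'   scaffold whose first 526 bp are query positions 398--923 of that
#'   amplicon -- an end-truncated (partial) copy.
#'
#' The SPIN-derived marker (M6) is deliberately absent from all records:
#' its binding sites could not be located in the published assemblies and
#' the fixture reproduces that absence.
#'
#' @return list with `primers` (the packaged primer table), `reference`
#'   (the packaged published-value table), and `species`, a named list of
#'   bundles (`sequences`, `roles`, `mrnas`, `mrna_targets`, `truth`).
#' @export
turaco_reference_fixture <- function() {
  if (!is.null(.fixture_env$fixture)) return(.fixture_env$fixture)
  primers <- read_primer_table()
  reference <- read_marker_reference()
  P <- function(mk, col) {
    v <- reference[[col]][reference$marker == mk]
    if (is.character(v)) v else as.integer(v)
  }
  pseq <- function(mk, which) {
    r <- primers[primers$marker == mk, ]
    if (which == "fwd") r$fwd_seq else r$rev_seq
  }

  # ---- erythrolophus-style bundle ---------------------------------
  set.seed(.subseed(.FIXTURE_SEED, 11L))
  chd <- .chd1_plan()
  chd_ex <- .plan_exons(chd)
  built <- .gene_build(chd$exon_lengths, chd$intron_lengths)
  pad5 <- .rand_dna(chd$gene_start - 1L)
  n <- length(built$exons)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, 2L)] <- built$exons
  pieces[seq(2L, 2L * n - 2L, 2L)] <- built$introns
  gseq <- paste(pieces, collapse = "")
  recA <- paste0(pad5, gseq,
                 .rand_dna(chd$seq_len - nchar(pad5) - nchar(gseq)))
  stopifnot(chd_ex$end[9L] == 29392L, chd_ex$start[10L] == 32245L,
            chd_ex$end[16L] == 38435L, chd_ex$start[17L] == 38771L,
            chd_ex$end[22L] == 43196L, chd_ex$start[23L] == 43382L)

  # exact plants on record A (published positions; left primer verbatim,
  # right primer reverse-complemented, degenerate codes realized to their
  # first expansion letter)
  rl <- function(s) .realize_primer(s, 1L)
  # M1: P8 left at 43,167; P2 right ending 43,533
  recA <- .plant(recA, 43167L, rl(pseq("M1", "rev")))
  recA <- .plant(recA, 43533L - nchar(pseq("M1", "fwd")) + 1L,
                 revcomp(rl(pseq("M1", "fwd"))))
  # M3: CHD1i9-F left 29,350; CHD1i9-R right ending 32,346
  recA <- .plant(recA, 29350L, rl(pseq("M3", "fwd")))
  recA <- .plant(recA, 32346L - nchar(pseq("M3", "rev")) + 1L,
                 revcomp(rl(pseq("M3", "rev"))))
  # M4: 2550F left 38,324; 2718R right ending 38,827
  recA <- .plant(recA, 38324L, rl(pseq("M4", "fwd")))
  recA <- .plant(recA, 38827L - nchar(pseq("M4", "rev")) + 1L,
                 revcomp(rl(pseq("M4", "rev"))))
  # M5: CHD1i16-F left 38,358; CHD1i16-R right ending 38,821.
  # Its reverse footprint overlaps M4's compatibly (shared motif).
  ov_m4 <- substring(revcomp(rl(pseq("M4", "rev"))), 1L, 15L)
  ov_m5 <- substring(revcomp(rl(pseq("M5", "rev"))), 6L, 20L)
  stopifnot(identical(ov_m4, ov_m5))
  recA <- .plant(recA, 38358L, rl(pseq("M5", "fwd")))
  recA <- .plant(recA, 38821L - nchar(pseq("M5", "rev")) + 1L,
                 revcomp(rl(pseq("M5", "rev"))))
  # junction hygiene around plants: E23 first base must differ from the
  # first intron-22 base on both records; fix deterministically
  substr(recA, 43382L, 43382L) <- "A"   # E23 first base
  substr(recA, 43196L, 43196L) <- "T"   # E22 last base (intron ends ..AG)

  # record B: M2-exact variant (1272H overwrites the P8 overlap; 1237L
  # planted on the right). Identical to A elsewhere.
  recB <- recA
  recB <- .plant(recB, 43178L, rl(pseq("M2", "fwd")))
  recB <- .plant(recB, 43435L - nchar(pseq("M2", "rev")) + 1L,
                 revcomp(rl(pseq("M2", "rev"))))

  # NIPBL-like record
  set.seed(.subseed(.FIXTURE_SEED, 12L))
  nip <- .nipbl_plan()
  nip_ex <- .plan_exons(nip)
  nbuilt <- .gene_build(nip$exon_lengths, nip$intron_lengths)
  npieces <- character(2L * length(nbuilt$exons) - 1L)
  npieces[seq(1L, length(npieces), 2L)] <- nbuilt$exons
  npieces[seq(2L, length(npieces) - 1L, 2L)] <- nbuilt$introns
  ngseq <- paste(npieces, collapse = "")
  npad5 <- .rand_dna(nip$gene_start - 1L)
  recN <- paste0(npad5, ngseq,
                 .rand_dna(nip$seq_len - nchar(npad5) - nchar(ngseq)))
  stopifnot(nip_ex$end[17L] == 68973L, nip_ex$start[18L] == 69775L)
  recN <- .plant(recN, 68920L, rl(pseq("M7", "fwd")))
  recN <- .plant(recN, 69842L - nchar(pseq("M7", "rev")) + 1L,
                 revcomp(rl(pseq("M7", "rev"))))

  # second-copy regions (3% divergence outside footprints)
  div <- 0.03
  set.seed(.subseed(.FIXTURE_SEED, 13L))
  fp <- function(mk, left_is_fwd) {
    lmk <- if (left_is_fwd) "fwd" else "rev"
    rmk <- if (left_is_fwd) "rev" else "fwd"
    lpos <- min(P(mk, "fwd_pos"), P(mk, "rev_pos"))
    rpos <- max(P(mk, "fwd_pos"), P(mk, "rev_pos"))
    list(left = c(lpos, lpos + nchar(pseq(mk, lmk)) - 1L),
         right = c(rpos - nchar(pseq(mk, rmk)) + 1L, rpos))
  }
  # intron 22 copy, +11 bp (regions from A for M1, from B for M2)
  f1 <- fp("M1", FALSE)
  regA <- .copy_with_indel(recA, 43137L, 43563L, -11L, 43289L, div,
                           list(f1$left, f1$right))
  f2 <- fp("M2", TRUE)
  regB <- .copy_with_indel(recB, 43148L, 43465L, -11L, 43289L, div,
                           list(f2$left, f2$right))
  # intron 9 copy, -2374 bp
  f3 <- fp("M3", TRUE)
  regC <- .copy_with_indel(recA, 29320L, 32376L, 2374L, 29632L, div,
                           list(f3$left, f3$right))
  # intron 16 copy, -43 bp (covers both M4 and M5)
  f4 <- fp("M4", TRUE); f5 <- fp("M5", TRUE)
  regD <- .copy_with_indel(recA, 38294L, 38857L, 43L, 38582L, div,
                           list(f4$left, f4$right, f5$left, f5$right))
  scaffold <- paste0(.rand_dna(400L), regC, .rand_dna(300L), regD,
                     .rand_dna(300L), regA, .rand_dna(300L), regB,
                     .rand_dna(400L))
  # intron 17 copy, -413 bp, on the W record
  set.seed(.subseed(.FIXTURE_SEED, 14L))
  f7 <- fp("M7", TRUE)
  regE <- .copy_with_indel(recN, 68890L, 69872L, 413L, 69168L, div,
                           list(f7$left, f7$right))
  wrec <- paste0(.rand_dna(500L), regE, .rand_dna(500L))

  ery_seqs <- Biostrings::DNAStringSet(c(
    chd1_Za = recA, chd1_Zb = recB, nipbl_Z = recN,
    W_chr = wrec, scaffold37 = scaffold))
  ery_roles <- role_map(c(chd1_Za = "Z", chd1_Zb = "Z", nipbl_Z = "Z",
                          W_chr = "W", scaffold37 = "scaffold"))
  mrna <- function(rec, ex) paste(substring(rec, ex$start, ex$end),
                                  collapse = "")
  ery_mrnas <- Biostrings::DNAStringSet(c(
    CHD1a_mrna = mrna(recA, chd_ex),
    CHD1b_mrna = mrna(recB, chd_ex),
    NIPBL_mrna = mrna(recN, nip_ex)))
  ery_targets <- data.frame(
    mrna_id = c("CHD1a_mrna", "CHD1b_mrna", "NIPBL_mrna"),
    seq_id = c("chd1_Za", "chd1_Zb", "nipbl_Z"),
    gene_id = c("CHD1", "CHD1", "NIPBL"), stringsAsFactors = FALSE)
  ery_truth <- list(
    models = list(CHD1a = gene_model("CHD1", "chd1_Za", chd_ex),
                  CHD1b = gene_model("CHD1", "chd1_Zb", chd_ex),
                  NIPBL = gene_model("NIPBL", "nipbl_Z", nip_ex)),
    marker_seq = c(M1 = "chd1_Za", M2 = "chd1_Zb", M3 = "chd1_Za",
                   M4 = "chd1_Za", M5 = "chd1_Za", M7 = "nipbl_Z"))

  # ---- concolor-style bundle: equal-length copies ------------------
  set.seed(.subseed(.FIXTURE_SEED, 15L))
  ccz <- .rand_dna(1200L)
  ccz <- .plant(ccz, 401L, rl(pseq("M1", "fwd")))
  ccz <- .plant(ccz, 764L - nchar(pseq("M1", "rev")) + 1L,
                revcomp(rl(pseq("M1", "rev"))))
  cc_region <- .apply_divergence(
    substring(ccz, 371L, 794L), 0.01,
    protect = list(c(31L, 50L), c(355L, 394L)))
  ccs <- paste0(.rand_dna(200L), cc_region, .rand_dna(200L))
  cc_seqs <- Biostrings::DNAStringSet(c(cc_Z = ccz, cc_scaffold = ccs))
  cc_roles <- role_map(c(cc_Z = "Z", cc_scaffold = "scaffold"))

  # ---- cristata-style bundle: truncated partial copy ---------------
  set.seed(.subseed(.FIXTURE_SEED, 16L))
  crz <- paste0(.rand_dna(300L), substring(recN, 68890L, 69872L),
                .rand_dna(300L))
  m7amp <- substring(recN, 68920L, 69842L)           # 923 bp
  frag <- substring(m7amp, 398L, 923L)               # query 398..923
  frag <- .apply_divergence(frag, 0.02,
                            protect = list(c(1L, 10L), c(517L, 526L)))
  crs <- paste0(frag, .rand_dna(1255L - nchar(frag)))
  cr_seqs <- Biostrings::DNAStringSet(c(cr_Z = crz, cr_scaffold = crs))
  cr_roles <- role_map(c(cr_Z = "Z", cr_scaffold = "scaffold"))

  fixture <- list(
    primers = primers,
    reference = reference,
    species = list(
      erythrolophus = list(sequences = ery_seqs, roles = ery_roles,
                           mrnas = ery_mrnas, mrna_targets = ery_targets,
                           truth = ery_truth),
      concolor = list(sequences = cc_seqs, roles = cc_roles,
                      mrnas = NULL, mrna_targets = NULL,
                      truth = list(delta_L = c(M1 = 0L))),
      cristata = list(sequences = cr_seqs, roles = cr_roles,
                      mrnas = NULL, mrna_targets = NULL,
                      truth = list(partial = c(M7 = TRUE)))))
  .fixture_env$fixture <- fixture
  fixture
}

#' Packaged table of published marker geometry
#'
#' Per-marker published primer positions, amplicon lengths, exon/intron
#' compositions and second-copy lengths for the reference species, as
#' shipped in `inst/extdata/marker_reference.tsv`. The SPIN marker's
#' sites were never located, so its row carries NAs.
#'
#' @return data.frame, one row per marker M1--M7.
#' @export
read_marker_reference <- function() {
  path <- system.file("extdata", "marker_reference.tsv",
                      package = "zwmarkers", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
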