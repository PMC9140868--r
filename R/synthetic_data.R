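# Synthetic ZW genome generator with full ground truth.
#
# Generates paired Z/W sequences carrying multi-exon genes with planted
# primer binding sites, gametolog divergence (substitutions), intron
# indels producing a target length polymorphism, optional translocated
# decoy copies and truncated partial copies. Background sequence is
# i.i.d. uniform ACGT, rejection-checked so that no unplanned primer
# binding site (at the scanning mismatch tolerance) exists anywhere:
# planted truth is unique by construction. The random stream is
# partitioned per sequence so adding a scaffold does not perturb Z/W
# content at a fixed master seed.

# Internal: derive a 31-bit sub-seed for stream `i` at `attempt`.
.subseed <- function(seed, i, attempt = 0L) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 +
                attempt * 15485863) %% 2147483629) + 1L
}

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Internal: deterministic realization of an IUPAC primer.
# variant 1 picks the first expansion letter at degenerate positions,
# variant 2 the last -- so Z and W plants exercise different realizations.
.realize_primer <- function(iupac, variant = 1L) {
  ch <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  paste(vapply(ch, function(b) {
    e <- iupac_expand(b)
    if (variant == 1L) e[1L] else e[length(e)]
  }, character(1L)), collapse = "")
}

# Internal: build exon/intron sequences for one gene.
# Introns of length >= 4 get GT..AG termini. Junction uniqueness is
# enforced (first intron base differs from the next exon's first base,
# last intron base from the previous exon's last base) so spliced mapping
# recovers the planted boundaries exactly.
.gene_build <- function(exon_lengths, intron_lengths) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            all(exon_lengths >= 2L), all(intron_lengths >= 1L))
  exons <- vapply(exon_lengths, .rand_dna, character(1L))
  introns <- vapply(intron_lengths, function(n) {
    if (n >= 4L) paste0("GT", .rand_dna(n - 4L), "AG") else .rand_dna(n)
  }, character(1L))
  pick_not <- function(bad) sample(setdiff(c("A", "C", "G", "T"), bad), 1L)
  for (i in seq_along(introns)) {
    ifirst <- substring(introns[i], 1L, 1L)
    ilast <- substring(introns[i], nchar(introns[i]), nchar(introns[i]))
    if (substring(exons[i], nchar(exons[i]), nchar(exons[i])) == ilast)
      substr(exons[i], nchar(exons[i]), nchar(exons[i])) <- pick_not(ilast)
    if (substring(exons[i + 1L], 1L, 1L) == ifirst)
      substr(exons[i + 1L], 1L, 1L) <- pick_not(ifirst)
  }
  list(exons = exons, introns = introns)
}

# Internal: substitute bases at `rate` over positions outside `protect`
# (list of c(start, end) intervals). Substitutions go to a different base.
.apply_divergence <- function(seq, rate, protect = list()) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  mask <- rep(TRUE, n)
  for (iv in protect) {
    lo <- max(1L, iv[1L]); hi <- min(n, iv[2L])
    if (lo <= hi) mask[lo:hi] <- FALSE
  }
  pos <- which(mask)
  pos <- pos[stats::runif(length(pos)) < rate]
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch[pos] <- vapply(ch[pos],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1L), USE.NAMES = FALSE)
  paste(ch, collapse = "")
}

# Internal: scan every primer over every sequence and report sites not
# attributable to a planted footprint. A site counts as planned when its
# footprint overlaps an allowed interval by at least half its length:
# near-palindromic primers cast a minus-strand shadow a base or two off
# their own plant, which is a property of the primer, not a background
# accident, and cannot pair into a spurious product.
.spurious_sites <- function(seqs, primers, allowed,
                            max_mismatch = 2L, three_prime_exact = 3L) {
  bad <- 0L
  for (sid in names(seqs)) {
    ivs <- allowed[[sid]]
    contained <- function(a, b) {
      if (is.null(ivs)) return(FALSE)
      need <- (b - a + 1L) %/% 2L
      any(vapply(ivs, function(iv)
        min(b, iv[2L]) - max(a, iv[1L]) + 1L >= need, logical(1L)))
    }
    for (p in c(primers$fwd_seq, primers$rev_seq)) {
      st <- scan_primer(seqs[[sid]], p, max_mismatch, three_prime_exact,
                        seq_id = sid)
      if (!nrow(st)) next
      for (r in seq_len(nrow(st)))
        if (!contained(st$start[r], st$end[r])) bad <- bad + 1L
    }
  }
  bad
}

#' Synthetic ZW genome configuration
#'
#' Defaults describe the study conditions the package targets: a
#' multi-exon gene whose marker intron differs in length between the Z
#' and W gametologs, ~5% substitution divergence between gametologs
#' (published gametolog identities for these markers run roughly
#' 75--99%), primers planted exactly with one degenerate position
#' realized differently on Z and W.
#'
#' @param seed master seed; all streams derive from it.
#' @param genes list of gene specs `list(gene_id, exon_lengths,
#'   intron_lengths)`.
#' @param markers list of marker specs `list(marker_id, gene_id,
#'   intron_index, flank_up, flank_down, fwd_seq, rev_seq, delta,
#'   second_location, plant_mismatches, truncate_to)`; `delta` is signed
#'   (positive = Z copy longer), `second_location` one of "W", "scaffold",
#'   "absent"; `truncate_to = c(qfrom, qto)` keeps only that query window
#'   of the second copy (a partial copy); `plant_mismatches` introduces
#'   that many mismatches into the planted Z forward-primer footprint
#'   (outside the 3'-exact zone).
#' @param divergence per-site substitution probability between gametolog
#'   copies (0--0.2).
#' @param copy_flank extra flank copied around the amplicon into the
#'   second-copy region (default 30 bp).
#' @param degenerate_divergent realize degenerate primer positions
#'   differently on Z and W (default TRUE).
#' @param decoy_scaffold also place a third, more diverged copy of each
#'   "scaffold" marker on a decoy scaffold? (default FALSE; the
#'   second_location = "scaffold" route already emulates a translocated
#'   copy.)
#' @param nonspecific optional list of `list(marker_id, length)`: plants
#'   an extra convergent primer-site pair in Z background producing a
#'   nonspecific product of that length.
#' @param pad background padding around the gene on Z (default 300).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genes = list(list(gene_id = "CHD1like",
                                         exon_lengths = c(220L, 180L, 200L),
                                         intron_lengths = c(400L, 350L))),
                       markers = list(list(marker_id = "MZ1",
                                           gene_id = "CHD1like",
                                           intron_index = 1L,
                                           flank_up = 60L, flank_down = 60L,
                                           fwd_seq = "TCTGCATCGCTARATCCTTT",
                                           rev_seq = "CTCCCAAGGATGAGRAAYTG",
                                           delta = 43L,
                                           second_location = "W")),
                       divergence = 0.05, copy_flank = 30L,
                       degenerate_divergent = TRUE,
                       decoy_scaffold = FALSE,
                       nonspecific = NULL, pad = 300L) {
  stopifnot(divergence >= 0, divergence <= 0.2)
  for (m in markers) {
    g <- genes[[which(vapply(genes, `[[`, "", "gene_id") == m$gene_id)]]
    iz <- g$intron_lengths[m$intron_index]
    if (iz - max(m$delta, 0L) < 1L)
      stop("planted delta leaves intron ", m$intron_index, " below 1 bp")
    if (m$flank_up < nchar(m$fwd_seq) + 1L ||
        m$flank_down < nchar(m$rev_seq) + 1L)
      stop("flanks must exceed primer lengths (marker ", m$marker_id, ")")
  }
  structure(list(seed = seed, genes = genes, markers = markers,
                 divergence = divergence, copy_flank = copy_flank,
                 degenerate_divergent = degenerate_divergent,
                 decoy_scaffold = decoy_scaffold,
                 nonspecific = nonspecific, pad = pad),
            class = "sim_config")
}

#' Random study-condition configuration
#'
#' Samples one gene (2--4 exons, exon lengths 120--300 bp, intron lengths
#' 150--500 bp), one marker with a signed length polymorphism of
#' magnitude `delta_range`, random 20-mer primers with one degenerate
#' position, divergence up to `max_divergence`, and a random second-copy
#' compartment -- one random instance of the conditions the generator
#' emulates.
#'
#' @param seed integer seed.
#' @param delta_range magnitude range of the planted polymorphism
#'   (default 1--3000).
#' @param max_divergence upper bound on gametolog divergence
#'   (default 0.05).
#' @return a [sim_config()].
#' @export
random_sim_config <- function(seed, delta_range = c(1L, 3000L),
                              max_divergence = 0.05) {
  set.seed(.subseed(seed, 97L))
  n_exons <- sample(2:4, 1L)
  exon_lengths <- sample(120:300, n_exons, replace = TRUE)
  intron_lengths <- sample(150:500, n_exons - 1L, replace = TRUE)
  idx <- sample(n_exons - 1L, 1L)
  delta <- sample(delta_range[1L]:delta_range[2L], 1L) *
    sample(c(-1L, 1L), 1L)
  # the marker intron must stay >= ~100 bp on both gametologs so the
  # polymorphism, not intron exhaustion, is what the run measures
  intron_lengths[idx] <- max(delta, 0L) + sample(100:400, 1L)
  rand_primer <- function() {
    p <- .rand_dna(20L)
    pos <- sample(5:14, 1L)
    base <- substring(p, pos, pos)
    code <- switch(base, A = "R", G = "R", C = "Y", T = "Y")
    substr(p, pos, pos) <- code
    p
  }
  sim_config(
    seed = seed,
    genes = list(list(gene_id = "geneA", exon_lengths = exon_lengths,
                      intron_lengths = intron_lengths)),
    markers = list(list(marker_id = "MZ1", gene_id = "geneA",
                        intron_index = idx,
                        flank_up = sample(40:80, 1L),
                        flank_down = sample(40:80, 1L),
                        fwd_seq = rand_primer(), rev_seq = rand_primer(),
                        delta = delta,
                        second_location = sample(c("W", "scaffold"), 1L))),
    divergence = stats::runif(1L, 0, max_divergence))
}

# Internal: one full build attempt; returns NULL when the rejection pass
# finds an unplanned primer site.
.simulate_attempt <- function(cfg, attempt) {
  seqs <- list(); allowed <- list(); roles <- character()
  truth_models <- list(); truth_amps <- list(); truth_sites <- list()
  truth_markers <- list(); mrnas <- list(); mrna_targets <- list()

  gene_ids <- vapply(cfg$genes, `[[`, "", "gene_id")

  # ---- Z chromosome -------------------------------------------------
  set.seed(.subseed(cfg$seed, 1L, attempt))
  z_parts <- character(); z_allowed <- list()
  offset <- 0L
  z_pad <- .rand_dna(cfg$pad)
  z_parts <- c(z_parts, z_pad); offset <- offset + cfg$pad
  gene_info <- list()
  for (g in cfg$genes) {
    built <- .gene_build(g$exon_lengths, g$intron_lengths)
    gmarkers <- Filter(function(m) m$gene_id == g$gene_id, cfg$markers)
    # plant primers inside exons (gene-local overwrite)
    for (m in gmarkers) {
      i <- m$intron_index
      fwd <- .realize_primer(m$fwd_seq, 1L)
      rev_ <- .realize_primer(m$rev_seq, 1L)
      if (!is.null(m$plant_mismatches) && m$plant_mismatches > 0L) {
        ch <- strsplit(fwd, "", fixed = TRUE)[[1L]]
        pos <- seq_len(length(ch) - 3L)[seq_len(m$plant_mismatches)]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
        fwd <- paste(ch, collapse = "")
      }
      eL <- nchar(built$exons[i])
      fs <- eL - m$flank_up + 1L
      substr(built$exons[i], fs, fs + nchar(fwd) - 1L) <- fwd
      rcrev <- revcomp(rev_)
      re <- m$flank_down
      substr(built$exons[i + 1L], re - nchar(rcrev) + 1L, re) <- rcrev
    }
    # assemble gene and genomic coordinates
    n <- length(built$exons)
    pieces <- character(2L * n - 1L)
    pieces[seq(1L, 2L * n - 1L, 2L)] <- built$exons
    if (n > 1L) pieces[seq(2L, 2L * n - 2L, 2L)] <- built$introns
    gseq <- paste(pieces, collapse = "")
    gstart <- offset + 1L
    exon_starts <- gstart +
      cumsum(c(0L, utils::head(nchar(built$exons), -1L) +
                 nchar(built$introns)))
    exons <- data.frame(start = exon_starts,
                        end = exon_starts + nchar(built$exons) - 1L)
    z_parts <- c(z_parts, gseq, .rand_dna(cfg$pad))
    offset <- offset + nchar(gseq) + cfg$pad
    gene_info[[g$gene_id]] <- list(exons = exons, spec = g)
  }
  z <- paste(z_parts, collapse = "")

  # genomic amplicon coordinates and allowed footprints
  for (m in cfg$markers) {
    gi <- gene_info[[m$gene_id]]
    i <- m$intron_index
    amp_start <- gi$exons$end[i] - m$flank_up + 1L
    amp_end <- gi$exons$start[i + 1L] + m$flank_down - 1L
    fl <- nchar(m$fwd_seq); rl <- nchar(m$rev_seq)
    z_allowed <- c(z_allowed,
                   list(c(amp_start, amp_start + fl - 1L),
                        c(amp_end - rl + 1L, amp_end)))
    iz <- gi$exons$start[i + 1L] - gi$exons$end[i] - 1L
    truth_amps[[m$marker_id]] <- data.frame(
      marker_id = m$marker_id, seq_id = "Zsim",
      start = amp_start, end = amp_end,
      length = amp_end - amp_start + 1L,
      composition = sprintf("E%d(%d)/I%d(%d)/E%d(%d)", i, m$flank_up,
                            i, iz, i + 1L, m$flank_down),
      stringsAsFactors = FALSE)
    truth_sites[[m$marker_id]] <- data.frame(
      marker_id = m$marker_id,
      fwd_pos5 = amp_start, rev_pos5 = amp_end)
  }

  # nonspecific plants in trailing Z background
  set.seed(.subseed(cfg$seed, 5L, attempt))
  if (!is.null(cfg$nonspecific)) {
    tailroom <- 0L
    for (ns in cfg$nonspecific) {
      m <- cfg$markers[[which(vapply(cfg$markers, `[[`, "", "marker_id") ==
                                ns$marker_id)]]
      fwd <- .realize_primer(m$fwd_seq, 1L)
      rcrev <- revcomp(.realize_primer(m$rev_seq, 1L))
      filler <- .rand_dna(ns$length - nchar(fwd) - nchar(rcrev))
      insert <- paste0(fwd, filler, rcrev)
      at <- nchar(z) + 200L + tailroom
      z <- paste0(z, .rand_dna(at - nchar(z) - 1L + nchar(insert)))
      substr(z, at, at + nchar(insert) - 1L) <- insert
      z_allowed <- c(z_allowed,
                     list(c(at, at + nchar(fwd) - 1L),
                          c(at + nchar(insert) - nchar(rcrev),
                            at + nchar(insert) - 1L)))
      tailroom <- tailroom + nchar(insert) + 200L
    }
    z <- paste0(z, .rand_dna(100L))
  }

  seqs[["Zsim"]] <- z
  allowed[["Zsim"]] <- z_allowed
  roles["Zsim"] <- "Z"
  for (gid in names(gene_info)) {
    truth_models[[gid]] <- gene_model(gid, "Zsim", gene_info[[gid]]$exons)
    mid <- paste0(gid, "_mrna")
    mrnas[[mid]] <- paste(substring(z, gene_info[[gid]]$exons$start,
                                    gene_info[[gid]]$exons$end),
                          collapse = "")
    mrna_targets[[mid]] <- data.frame(mrna_id = mid, seq_id = "Zsim",
                                      gene_id = gid)
  }

  # ---- second copies (W and/or decoy scaffold) ----------------------
  build_copy <- function(m, stream, variant) {
    gi <- gene_info[[m$gene_id]]
    i <- m$intron_index
    amp <- truth_amps[[m$marker_id]]
    from <- amp$start - cfg$copy_flank
    to <- amp$end + cfg$copy_flank
    region <- substring(z, from, to)
    loc <- function(p) p - from + 1L
    fl <- nchar(m$fwd_seq); rl <- nchar(m$rev_seq)
    f_iv <- c(loc(amp$start), loc(amp$start) + fl - 1L)
    r_iv <- c(loc(amp$end) - rl + 1L, loc(amp$end))
    # re-realize degenerate positions on the second copy
    if (isTRUE(cfg$degenerate_divergent)) {
      substr(region, f_iv[1L], f_iv[2L]) <- .realize_primer(m$fwd_seq, variant)
      substr(region, r_iv[1L], r_iv[2L]) <-
        revcomp(.realize_primer(m$rev_seq, variant))
    }
    int_lo <- loc(gi$exons$end[i] + 1L)
    int_hi <- loc(gi$exons$start[i + 1L] - 1L)
    iz <- int_hi - int_lo + 1L
    mid <- if (m$delta > 0L) int_lo + (iz - m$delta) %/% 2L
           else int_lo + iz %/% 2L
    region <- .apply_divergence(region, cfg$divergence,
                                protect = list(f_iv, r_iv,
                                               c(1L, 5L),
                                               c(nchar(region) - 4L,
                                                 nchar(region)),
                                               c(mid - 4L,
                                                 mid + abs(m$delta) + 4L)))
    if (m$delta > 0L) {
      region <- paste0(substring(region, 1L, mid - 1L),
                       substring(region, mid + m$delta))
    } else if (m$delta < 0L) {
      region <- paste0(substring(region, 1L, mid - 1L), .rand_dna(-m$delta),
                       substring(region, mid))
    }
    shift <- function(p) if (p >= mid) p - m$delta else p
    fp <- list(f_iv, c(shift(r_iv[1L]), shift(r_iv[2L])))
    if (!is.null(m$truncate_to)) {
      qlo <- loc(amp$start) + m$truncate_to[1L] - 1L
      qhi_pre <- loc(amp$start) + m$truncate_to[2L] - 1L
      region <- substring(region, qlo, shift(qhi_pre))
      fp <- list(c(1L, nchar(region)))  # whole fragment is planted material
    }
    list(region = region, footprints = fp)
  }

  w_parts <- character(); w_allowed <- list(); w_off <- 0L
  sc_parts <- character(); sc_allowed <- list(); sc_off <- 0L
  set.seed(.subseed(cfg$seed, 2L, attempt))
  for (m in Filter(function(m) m$second_location == "W", cfg$markers)) {
    cp <- build_copy(m, 2L, 2L)
    pad <- .rand_dna(250L)
    w_parts <- c(w_parts, pad, cp$region)
    for (iv in cp$footprints)
      w_allowed <- c(w_allowed, list(iv + w_off + 250L))
    w_off <- w_off + 250L + nchar(cp$region)
  }
  w_parts <- c(w_parts, .rand_dna(250L))
  set.seed(.subseed(cfg$seed, 3L, attempt))
  for (m in Filter(function(m) m$second_location == "scaffold",
                   cfg$markers)) {
    cp <- build_copy(m, 3L, 2L)
    pad <- .rand_dna(250L)
    sc_parts <- c(sc_parts, pad, cp$region)
    for (iv in cp$footprints)
      sc_allowed <- c(sc_allowed, list(iv + sc_off + 250L))
    sc_off <- sc_off + 250L + nchar(cp$region)
  }
  sc_parts <- c(sc_parts, .rand_dna(250L))

  seqs[["Wsim"]] <- paste(w_parts, collapse = "")
  allowed[["Wsim"]] <- w_allowed
  roles["Wsim"] <- "W"
  if (length(sc_parts) > 1L || cfg$decoy_scaffold) {
    seqs[["SCsim"]] <- paste(sc_parts, collapse = "")
    allowed[["SCsim"]] <- sc_allowed
    roles["SCsim"] <- "scaffold"
  }

  # marker-level truth
  for (m in cfg$markers) {
    amp_len <- truth_amps[[m$marker_id]]$length
    partial <- !is.null(m$truncate_to)
    truth_markers[[m$marker_id]] <- data.frame(
      marker_id = m$marker_id,
      z_length = amp_len,
      second_location = m$second_location,
      second_span = if (m$second_location == "absent") NA_integer_
                    else if (partial)
                      m$truncate_to[2L] - m$truncate_to[1L] + 1L
                    else amp_len - m$delta,
      delta_L = if (m$second_location == "absent" || partial) NA_integer_
                else abs(m$delta),
      z_longer = if (m$second_location == "absent" || partial) NA
                 else m$delta > 0L,
      partial = partial,
      stringsAsFactors = FALSE)
  }

  if (.spurious_sites(seqs, data.frame(
        fwd_seq = vapply(cfg$markers, `[[`, "", "fwd_seq"),
        rev_seq = vapply(cfg$markers, `[[`, "", "rev_seq"),
        stringsAsFactors = FALSE), allowed) > 0L)
    return(NULL)

  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  mr <- Biostrings::DNAStringSet(unlist(mrnas))
  list(sequences = sequences,
       roles = role_map(roles),
       mrnas = mr,
       mrna_targets = do.call(rbind, mrna_targets),
       primers = data.frame(
         marker = vapply(cfg$markers, `[[`, "", "marker_id"),
         fwd_name = paste0(vapply(cfg$markers, `[[`, "", "marker_id"), "-F"),
         fwd_seq = vapply(cfg$markers, `[[`, "", "fwd_seq"),
         rev_name = paste0(vapply(cfg$markers, `[[`, "", "marker_id"), "-R"),
         rev_seq = vapply(cfg$markers, `[[`, "", "rev_seq"),
         gene = vapply(cfg$markers, `[[`, "", "gene_id"),
         stringsAsFactors = FALSE),
       truth = list(models = truth_models,
                    amplicons = do.call(rbind, truth_amps),
                    sites = do.call(rbind, truth_sites),
                    markers = do.call(rbind, truth_markers),
                    nonspecific = cfg$nonspecific),
       config = cfg)
}

#' Generate a synthetic ZW genome with ground truth
#'
#' Deterministic given the configuration seed. The Z sequence carries each
#' gene with planted primer sites; W (and optionally a decoy scaffold)
#' carries diverged copies of each marker's amplicon region with the
#' configured intron indel; a truth set records every planted gene model,
#' binding site, amplicon, and expected length polymorphism.
#'
#' @param cfg a [sim_config()].
#' @param max_attempts rebuild attempts when the rejection pass finds an
#'   unplanned primer site (default 25).
#' @return list: `sequences` (DNAStringSet: Zsim, Wsim, optionally SCsim),
#'   `roles`, `mrnas`, `mrna_targets`, `primers`, `truth`, `config`.
#' @export
simulate_zw <- function(cfg, max_attempts = 25L) {
  stopifnot(inherits(cfg, "sim_config"))
  for (attempt in 0:(max_attempts - 1L)) {
    res <- .simulate_attempt(cfg, attempt)
    if (!is.null(res)) return(res)
  }
  stop("could not build a clean synthetic genome in ", max_attempts,
       " attempts")
}

#' Write a simulated genome bundle to disk
#'
#' FASTA sequences + truth JSON + role-map YAML, the generator's external
#' interface.
#'
#' @param sim output of [simulate_zw()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "genome.fasta")
  write_genome_fasta(sim$sequences, p1)
  p2 <- file.path(dir, "mrna.fasta")
  write_genome_fasta(sim$mrnas, p2)
  p3 <- file.path(dir, "roles.yaml")
  write_role_map(sim$roles, p3)
  p4 <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$models <- lapply(truth$models, function(m)
    list(gene_id = m$gene_id, seq_id = m$seq_id, strand = m$strand,
         exons = m$exons))
  jsonlite::write_json(truth, p4, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(p1, p2, p3, p4))
}
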