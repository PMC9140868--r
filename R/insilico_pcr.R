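# In-silico PCR: degenerate primer binding-site scanning, product
# enumeration, and exon/intron composition annotation.
#
# Coordinates are 1-based inclusive throughout. A binding site's `pos5` is
# the genomic coordinate of the primer's own 5'-terminal base: for a
# plus-strand site that is the leftmost footprint base, for a minus-strand
# site the rightmost. With that convention the product length of a
# converging pair is rev.pos5 - fwd.pos5 + 1, which is the only reading
# consistent with published marker position/length arithmetic.

# Internal: integer mask vector for a target sequence (A/C/G/T/N).
.target_masks <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- .TARGET_MASK[ch]
  if (anyNA(m))
    stop("target sequence contains non-ACGTN character(s): ",
         paste(unique(ch[is.na(m)]), collapse = ","))
  unname(m)
}

.primer_masks <- function(primer) {
  ch <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  m <- .IUPAC_MASK[ch]
  if (anyNA(m))
    stop("primer contains non-IUPAC character(s): ",
         paste(unique(ch[is.na(m)]), collapse = ","))
  unname(m)
}

# Internal: mismatch count of `pmask` at every offset of `tmask`
# (one strand). Returns integer vector of length L - k + 1.
.scan_masks <- function(pmask, tmask) {
  k <- length(pmask)
  L <- length(tmask)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  mm <- integer(n)
  for (p in seq_len(k)) {
    mm <- mm + as.integer(bitwAnd(pmask[p], tmask[p:(p + n - 1L)]) == 0L)
  }
  mm
}

#' Scan a sequence for degenerate-primer binding sites
#'
#' Finds, on both strands, every footprint with at most `max_mismatch`
#' mismatches under IUPAC matching, requiring the `three_prime_exact` bases
#' at the primer 3' end to match exactly (mispriming at the 3' terminus
#' aborts extension). `N` in the target never matches.
#'
#' @param subject genome sequence (character, `DNAString`, or single-record
#'   `DNAStringSet`).
#' @param primer IUPAC primer string.
#' @param max_mismatch maximum mismatches per site (default 2).
#' @param three_prime_exact number of 3'-terminal primer bases that must
#'   match exactly (default 3).
#' @param seq_id id to record in the output (default "subject").
#' @return data.frame of sites sorted by ascending `pos5`:
#'   `seq_id`, `strand`, `pos5`, `start`, `end` (footprint), `mismatches`.
#' @export
scan_primer <- function(subject, primer, max_mismatch = 2L,
                        three_prime_exact = 3L, seq_id = "subject") {
  pm <- .primer_masks(primer)
  k <- length(pm)
  if (k < three_prime_exact)
    stop("primer shorter than three_prime_exact")
  tm <- .target_masks(.seq_chr(subject))

  hit_one <- function(pmask, strand) {
    mm_all <- .scan_masks(pmask, tm)
    if (!length(mm_all)) return(NULL)
    # 3'-end bases: last `tpe` primer positions on '+', first on '-'
    # (the pattern scanned on '-' is the reverse complement).
    tpe <- three_prime_exact
    idx3 <- if (strand == "+") (k - tpe + 1L):k else seq_len(tpe)
    mm3 <- .scan_masks(pmask[idx3], tm)
    # align mm3 windows to full-footprint offsets
    off3 <- if (strand == "+") idx3[1L] - 1L else 0L
    n <- length(mm_all)
    mm3 <- mm3[(1L + off3):(n + off3)]
    keep <- which(mm_all <= max_mismatch & mm3 == 0L)
    if (!length(keep)) return(NULL)
    data.frame(
      seq_id = seq_id, strand = strand,
      pos5 = if (strand == "+") keep else keep + k - 1L,
      start = keep, end = keep + k - 1L,
      mismatches = mm_all[keep], stringsAsFactors = FALSE)
  }

  plus <- hit_one(pm, "+")
  minus <- hit_one(.primer_masks(revcomp(primer)), "-")
  out <- rbind(plus, minus)
  if (is.null(out))
    return(data.frame(seq_id = character(), strand = character(),
                      pos5 = integer(), start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out[order(out$pos5, out$strand), , drop = FALSE]
}

#' Enumerate PCR products from forward/reverse binding sites
#'
#' Every convergent combination -- one primer of the pair on the plus
#' strand, the other on the minus strand, plus-strand site to the left --
#' with product length at most `max_product` is reported (multiple and
#' nonspecific products are real phenomena, so no "shortest wins" rule).
#' Product length is `right.pos5 - left.pos5 + 1`.
#'
#' @param fwd_sites,rev_sites site data.frames from [scan_primer()] for the
#'   forward and reverse primer of one pair, on one sequence.
#' @param max_product maximum product length in bp (default 5000).
#' @param marker_id marker name recorded in the output.
#' @param subject optional sequence; when given, product sequences are
#'   attached.
#' @return data.frame of amplicons sorted by start then length: `marker_id`,
#'   `seq_id`, `start`, `end`, `length`, `left_primer` ("fwd"/"rev"),
#'   `fwd_pos5`, `rev_pos5`, `fwd_mm`, `rev_mm`, and `sequence` if
#'   `subject` was supplied.
#' @export
enumerate_amplicons <- function(fwd_sites, rev_sites, max_product = 5000L,
                                marker_id = NA_character_, subject = NULL) {
  combos <- list(list(left = fwd_sites, right = rev_sites, lp = "fwd"),
                 list(left = rev_sites, right = fwd_sites, lp = "rev"))
  rows <- list()
  for (cb in combos) {
    L <- cb$left[cb$left$strand == "+", , drop = FALSE]
    R <- cb$right[cb$right$strand == "-", , drop = FALSE]
    if (!nrow(L) || !nrow(R)) next
    for (i in seq_len(nrow(L))) for (j in seq_len(nrow(R))) {
      len <- R$pos5[j] - L$pos5[i] + 1L
      if (len < 1L || len > max_product) next
      # require non-overlapping convergent footprints
      if (R$start[j] <= L$end[i]) next
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = marker_id, seq_id = L$seq_id[i],
        start = L$pos5[i], end = R$pos5[j], length = len,
        left_primer = cb$lp,
        fwd_pos5 = if (cb$lp == "fwd") L$pos5[i] else R$pos5[j],
        rev_pos5 = if (cb$lp == "fwd") R$pos5[j] else L$pos5[i],
        fwd_mm = if (cb$lp == "fwd") L$mismatches[i] else R$mismatches[j],
        rev_mm = if (cb$lp == "fwd") R$mismatches[j] else L$mismatches[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(marker_id = character(), seq_id = character(),
                      start = integer(), end = integer(), length = integer(),
                      left_primer = character(), fwd_pos5 = integer(),
                      rev_pos5 = integer(), fwd_mm = integer(),
                      rev_mm = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(subject)) {
    s <- .seq_chr(subject)
    out$sequence <- substring(s, out$start, out$end)
  }
  out
}

#' Predict amplicons for a set of primer pairs over a sequence collection
#'
#' Convenience driver: scans each marker's primers over every sequence and
#' enumerates products, attaching product sequences.
#'
#' @param seqs [Biostrings::DNAStringSet] (or named character vector).
#' @param primers primer table from [read_primer_table()].
#' @param max_mismatch,three_prime_exact,max_product see [scan_primer()] and
#'   [enumerate_amplicons()].
#' @return data.frame of amplicons across all markers and sequences.
#' @export
predict_amplicons <- function(seqs, primers, max_mismatch = 2L,
                              three_prime_exact = 3L, max_product = 5000L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  out <- list()
  for (si in seq_along(seqs)) {
    sid <- names(seqs)[si]
    s <- as.character(seqs[[si]])
    for (mi in seq_len(nrow(primers))) {
      f <- scan_primer(s, primers$fwd_seq[mi], max_mismatch,
                       three_prime_exact, seq_id = sid)
      r <- scan_primer(s, primers$rev_seq[mi], max_mismatch,
                       three_prime_exact, seq_id = sid)
      a <- enumerate_amplicons(f, r, max_product,
                               marker_id = primers$marker[mi], subject = s)
      if (nrow(a)) out[[length(out) + 1L]] <- a
    }
  }
  if (!length(out))
    return(enumerate_amplicons(scan_primer("ACGT", "AAAA", 0L, 1L),
                               scan_primer("ACGT", "AAAA", 0L, 1L)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate an amplicon with its exon/intron composition
#'
#' Intersects the amplicon interval with a gene model's exon and intron
#' features, in genomic order. Feature tags follow the model's transcription
#' order (E1, I1, E2, ...). An amplicon outside the gene gets an empty
#' composition and `outside_gene = TRUE`.
#'
#' @param amp one amplicon row from [enumerate_amplicons()] (or any list
#'   with `start` and `end`).
#' @param model a `gene_model` (see [gene_model()]).
#' @return list with `segments` (data.frame `tag`, `start`, `end`,
#'   `overlap`), `composition` (string like `"E22(30)/I22(185)/E23(152)"`),
#'   `total` (sum of overlaps) and `outside_gene`.
#' @export
annotate_composition <- function(amp, model) {
  stopifnot(inherits(model, "gene_model"))
  s <- as.integer(amp$start); e <- as.integer(amp$end)
  feats <- gene_features(model)
  ov_s <- pmax(feats$start, s)
  ov_e <- pmin(feats$end, e)
  keep <- ov_s <= ov_e
  segs <- data.frame(tag = feats$tag[keep],
                     start = ov_s[keep], end = ov_e[keep],
                     overlap = ov_e[keep] - ov_s[keep] + 1L,
                     stringsAsFactors = FALSE)
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  outside <- nrow(segs) == 0L
  if (outside)
    warning("amplicon [", s, ",", e, "] lies outside gene ", model$gene_id)
  list(segments = segs,
       composition = paste(sprintf("%s(%d)", segs$tag, segs$overlap),
                           collapse = "/"),
       total = sum(segs$overlap),
       outside_gene = outside)
}

#' Export amplicons as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention (start-1, end) exactly.
#'
#' @param amps amplicon data.frame.
#' @param path output BED file.
#' @export
amplicons_to_bed <- function(amps, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = amps$seq_id,
    ranges = IRanges::IRanges(start = amps$start, end = amps$end),
    strand = "+")
  names(gr) <- amps$marker_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export amplicons as a marker table TSV
#'
#' One row per amplicon with marker, positions, length and (if annotated)
#' composition -- the in-silico analogue of a predicted-product table.
#'
#' @param amps amplicon data.frame; may carry a `composition` column.
#' @param path output TSV.
#' @export
amplicons_to_tsv <- function(amps, path) {
  keep <- intersect(c("marker_id", "seq_id", "fwd_pos5", "rev_pos5",
                      "start", "end", "length", "composition"), names(amps))
  utils::write.table(amps[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
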