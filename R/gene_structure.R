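# Gene structure inference: spliced mapping of an mRNA onto a genomic
# sequence to recover exon/intron coordinates, the step behind intron
# numbering and intron-length determination.
#
# The mapper is a maximal-exact-match chainer: exact anchor seeds (length
# >= min_anchor) are clustered by diagonal into candidate exon blocks,
# blocks are chained co-linearly, and each exon/exon junction is placed at
# the leftmost sequence-consistent position, preferring a placement whose
# intron starts with GT and ends with AG when one exists in the ambiguity
# window. This is deliberately not a general splice-aware aligner: it
# assumes near-identical (same individual/species) mRNA and genome.

#' Construct a gene model
#'
#' @param gene_id gene name.
#' @param seq_id id of the genomic sequence the model lives on.
#' @param exons data.frame or matrix with columns `start`, `end`
#'   (1-based inclusive genomic coordinates, strictly increasing,
#'   non-overlapping).
#' @param strand "+" or "-" (transcription direction on `seq_id`).
#' @return object of class `gene_model` with derived `introns`.
#' @export
gene_model <- function(gene_id, seq_id, exons, strand = "+") {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  stopifnot(nrow(exons) >= 1L, strand %in% c("+", "-"))
  if (any(exons$end < exons$start))
    stop("exon end before start")
  if (nrow(exons) > 1L) {
    if (any(diff(exons$start) <= 0L))
      stop("exons must be strictly increasing")
    if (any(exons$start[-1L] <= exons$end[-nrow(exons)] + 1L))
      stop("adjacent exons must be separated by at least 1 intron base")
  }
  n <- nrow(exons)
  introns <- if (n > 1L)
    data.frame(index = seq_len(n - 1L),
               start = exons$end[-n] + 1L,
               end = exons$start[-1L] - 1L)
  else
    data.frame(index = integer(), start = integer(), end = integer())
  introns$length <- introns$end - introns$start + 1L
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, introns = introns),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s on %s (%s): %d exons, %d introns, span %d..%d\n",
              x$gene_id, x$seq_id, x$strand, nrow(x$exons), nrow(x$introns),
              x$exons$start[1L], x$exons$end[nrow(x$exons)]))
  invisible(x)
}

#' Exon and intron features of a model, in genomic order
#'
#' Feature tags (`E<i>`, `I<i>`) are numbered in transcription order:
#' for a minus-strand model exon 1 is the rightmost.
#'
#' @param model a `gene_model`.
#' @return data.frame `tag`, `type`, `index`, `start`, `end`, `length`.
#' @export
gene_features <- function(model) {
  n <- nrow(model$exons)
  eidx <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  iidx <- if (model$strand == "+") seq_len(max(n - 1L, 0L))
          else rev(seq_len(max(n - 1L, 0L)))
  ex <- data.frame(tag = paste0("E", eidx), type = "exon", index = eidx,
                   start = model$exons$start, end = model$exons$end,
                   stringsAsFactors = FALSE)
  feats <- ex
  if (n > 1L) {
    it <- data.frame(tag = paste0("I", iidx), type = "intron", index = iidx,
                     start = model$introns$start, end = model$introns$end,
                     stringsAsFactors = FALSE)
    feats <- rbind(ex, it)
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  feats$length <- feats$end - feats$start + 1L
  rownames(feats) <- NULL
  feats
}

#' Intron table of a gene model
#'
#' Intron `i` follows exon `i` in transcription order; lengths are
#' `end - start + 1`.
#'
#' @param model a `gene_model`.
#' @return data.frame `intron`, `start`, `end`, `length` ordered by intron
#'   index (empty for a single-exon gene).
#' @export
intron_table <- function(model) {
  f <- gene_features(model)
  it <- f[f$type == "intron", c("index", "start", "end", "length")]
  it <- it[order(it$index), , drop = FALSE]
  names(it)[1L] <- "intron"
  rownames(it) <- NULL
  it
}

# Internal: all exact k-mer anchor matches of `q` in `g` as (qpos, gpos).
.anchor_seeds <- function(q, g, k) {
  nq <- nchar(q)
  if (nq < k) return(data.frame(qpos = integer(), gpos = integer()))
  kmers <- substring(q, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(g))
  st <- IRanges::start(m)
  qpos <- rep.int(seq_along(st), lengths(st))
  data.frame(qpos = qpos, gpos = unlist(st, use.names = FALSE))
}

# Internal: merge seeds into maximal exact blocks per diagonal, then close
# small same-diagonal gaps (mismatch runs) subject to the mismatch budget.
.seed_blocks <- function(seeds, k, q, g, max_mismatch_rate) {
  if (!nrow(seeds)) return(NULL)
  seeds$diag <- seeds$gpos - seeds$qpos
  blocks <- list()
  for (d in unique(seeds$diag)) {
    qp <- sort(seeds$qpos[seeds$diag == d])
    brk <- c(0L, which(diff(qp) > 1L), length(qp))
    for (b in seq_len(length(brk) - 1L)) {
      qs <- qp[brk[b] + 1L]; qe <- qp[brk[b + 1L]] + k - 1L
      blocks[[length(blocks) + 1L]] <- c(qs = qs, qe = qe, diag = d)
    }
  }
  bl <- as.data.frame(do.call(rbind, blocks))
  # close gaps between consecutive blocks on the same diagonal when the gap
  # bases are mere mismatches within budget
  out <- list()
  for (d in unique(bl$diag)) {
    sub <- bl[bl$diag == d, , drop = FALSE]
    sub <- sub[order(sub$qs), , drop = FALSE]
    cur <- sub[1L, ]
    mism <- 0L
    if (nrow(sub) > 1L) for (i in 2L:nrow(sub)) {
      gap_q <- (cur$qe + 1L):(sub$qs[i] - 1L)
      gap_mm <- sum(substring(q, gap_q, gap_q) !=
                    substring(g, gap_q + d, gap_q + d))
      # budget: the whole-mRNA mismatch allowance. Same-diagonal blocks
      # always belong to one exon region (a zero-length intron is
      # impossible), so the only false merges are across long random
      # gaps, whose ~75% mismatch density blows any sane budget.
      if ((mism + gap_mm) <= max_mismatch_rate * nchar(q)) {
        mism <- mism + gap_mm
        cur$qe <- sub$qe[i]
      } else {
        cur$mism <- mism
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, ]; mism <- 0L
      }
    }
    cur$mism <- mism
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res[order(res$qs), , drop = FALSE]
}

# Internal: chain blocks co-linearly maximising query coverage.
# Returns list(chain = data.frame, ties = number of distinct optimal chains).
.chain_blocks <- function(bl) {
  n <- nrow(bl)
  cov <- bl$qe - bl$qs + 1L
  best <- cov
  prev <- rep.int(0L, n)
  nbest <- rep.int(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      # successor must start after predecessor's start, not extend the same
      # diagonal backwards, and lie strictly downstream in the genome
      if (bl$diag[i] <= bl$diag[j]) next
      if (bl$qs[i] <= bl$qs[j]) next
      if (bl$qs[i] > bl$qe[j] + 1L) next        # query gap: unmapped bases
      gain <- bl$qe[i] - max(bl$qe[j], bl$qs[i] - 1L)
      if (gain <= 0L) next
      # genomic intron must be >= 1 bp at every junction placement
      if ((bl$diag[i] - bl$diag[j]) < 1L) next
      sc <- best[j] + gain
      if (sc > best[i]) {
        best[i] <- sc; prev[i] <- j; nbest[i] <- nbest[j]
      } else if (sc == best[i] && prev[i] != j) {
        nbest[i] <- nbest[i] + nbest[j]
      }
    }
  }
  top <- max(best)
  ends <- which(best == top)
  ties <- sum(nbest[ends])
  i <- ends[1L]
  idx <- integer()
  while (i != 0L) { idx <- c(i, idx); i <- prev[i] }
  list(chain = bl[idx, , drop = FALSE], coverage = top, ties = ties)
}

# Internal: map on one orientation; returns NULL if no usable chain.
.map_one_strand <- function(q, g, min_anchor, max_mismatch_rate) {
  seeds <- .anchor_seeds(q, g, min_anchor)
  if (!nrow(seeds)) return(NULL)
  bl <- .seed_blocks(seeds, min_anchor, q, g, max_mismatch_rate)
  if (is.null(bl) || !nrow(bl)) return(NULL)
  ch <- .chain_blocks(bl)
  chain <- ch$chain
  nq <- nchar(q)
  # extend terminal blocks to the mRNA ends through mismatches within budget
  ext_ok <- function(qr, d) {
    if (!length(qr)) return(TRUE)
    gp <- qr + d
    if (any(gp < 1L | gp > nchar(g))) return(FALSE)
    mm <- sum(substring(q, qr, qr) != substring(g, gp, gp))
    (mm + chain$mism[1L]) <= max_mismatch_rate * nq
  }
  if (chain$qs[1L] > 1L && ext_ok(seq_len(chain$qs[1L] - 1L), chain$diag[1L]))
    chain$qs[1L] <- 1L
  nlast <- nrow(chain)
  if (chain$qe[nlast] < nq &&
      ext_ok((chain$qe[nlast] + 1L):nq, chain$diag[nlast]))
    chain$qe[nlast] <- nq
  covered <- sum(pmin(chain$qe, nq) - chain$qs + 1L) -
    sum(pmax(0L, chain$qe[-nlast] - chain$qs[-1L] + 1L))
  list(chain = chain, coverage = covered, ties = ch$ties)
}

# Internal: place junction between consecutive chain blocks.
# Returns the query position at which the upstream exon ends.
.place_junction <- function(q, g, b1, b2) {
  lo <- b2[["qs"]] - 1L   # leftmost candidate junction (exon ends here)
  hi <- b1[["qe"]]        # rightmost: end of the upstream block
  cand <- lo:hi
  d1 <- b1[["diag"]]; d2 <- b2[["diag"]]
  for (j in cand) {
    don <- substring(g, j + d1 + 1L, j + d1 + 2L)
    acc <- substring(g, j + d2 - 1L, j + d2)
    if (don == "GT" && acc == "AG") return(j)
  }
  cand[1L]
}

#' Infer exon/intron structure by spliced mapping of an mRNA
#'
#' Maps `mrna` onto `genome` by exact-anchor seeding (seed length
#' `min_anchor`), same-diagonal extension through isolated mismatches up to
#' `max_mismatch_rate`, and co-linear chaining. Exon/exon junctions that are
#' ambiguous (sequence-identical shifts) are placed at the leftmost position
#' whose implied intron has GT..AG terminal dinucleotides if one exists in
#' the window, else leftmost. Minus-strand genes are handled by mapping
#' against the reverse complement and lifting coordinates back.
#'
#' @param mrna mRNA sequence (character/DNAString/1-record DNAStringSet).
#' @param genome genomic sequence (same types).
#' @param min_anchor minimum exact seed length (default 20).
#' @param max_mismatch_rate tolerated mismatch fraction per exon
#'   (default 0.02; same-individual mRNA should map near-exactly).
#' @param gene_id,seq_id ids recorded in the model.
#' @param min_coverage minimum fraction of the mRNA that must be covered by
#'   the exon chain (default 0.95); below it mapping fails.
#' @return a [gene_model()].
#' @export
map_exons <- function(mrna, genome, min_anchor = 20L,
                      max_mismatch_rate = 0.02,
                      gene_id = "gene", seq_id = "genome",
                      min_coverage = 0.95) {
  q <- .seq_chr(mrna); g <- .seq_chr(genome)
  if (!nchar(q)) stop("empty mRNA")
  if (nchar(q) > nchar(g)) stop("mRNA longer than genomic sequence")
  res_p <- .map_one_strand(q, g, min_anchor, max_mismatch_rate)
  cov_p <- if (is.null(res_p)) 0 else res_p$coverage / nchar(q)
  use <- NULL; strand <- "+"
  if (cov_p >= min_coverage) {
    use <- res_p
  } else {
    res_m <- .map_one_strand(q, revcomp(g), min_anchor, max_mismatch_rate)
    cov_m <- if (is.null(res_m)) 0 else res_m$coverage / nchar(q)
    if (cov_m >= min_coverage) { use <- res_m; strand <- "-" }
  }
  if (is.null(use))
    stop("unmappable mRNA: no exon chain covers ", min_coverage * 100,
         "% of ", gene_id)
  if (use$ties > 1L)
    stop("ambiguous mapping for ", gene_id, ": ", use$ties,
         " equally scoring exon chains")
  chain <- use$chain
  gg <- if (strand == "+") g else revcomp(g)
  # resolve junctions
  n <- nrow(chain)
  qends <- integer(n); qstarts <- integer(n)
  qstarts[1L] <- chain$qs[1L]
  if (n > 1L) for (i in seq_len(n - 1L)) {
    b1 <- c(qs = chain$qs[i], qe = chain$qe[i], diag = chain$diag[i])
    b2 <- c(qs = chain$qs[i + 1L], qe = chain$qe[i + 1L],
            diag = chain$diag[i + 1L])
    j <- .place_junction(q, gg, b1, b2)
    qends[i] <- j
    qstarts[i + 1L] <- j + 1L
  }
  qends[n] <- chain$qe[n]
  exons <- data.frame(start = qstarts + chain$diag,
                      end = qends + chain$diag)
  if (strand == "-") {
    gl <- nchar(g)
    exons <- data.frame(start = gl - exons$end + 1L,
                        end = gl - exons$start + 1L)
    exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  }
  model <- gene_model(gene_id, seq_id, exons, strand)
  # verify reconstruction within the mismatch budget
  spl <- paste(substring(g, model$exons$start, model$exons$end),
               collapse = "")
  if (strand == "-") spl <- revcomp(spl)
  if (nchar(spl) == nchar(q)) {
    mm <- sum(strsplit(spl, "")[[1L]] != strsplit(q, "")[[1L]])
    if (mm > max_mismatch_rate * nchar(q))
      stop("mapped exons diverge from mRNA beyond max_mismatch_rate (",
           mm, " mismatches)")
  }
  model
}

#' Export a gene model as GFF3
#'
#' Writes gene and exon features with 1-based inclusive coordinates per the
#' GFF3 specification.
#'
#' @param model a `gene_model`.
#' @param path output file.
#' @export
export_gff3 <- function(model, path) {
  n <- nrow(model$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = model$seq_id,
    ranges = IRanges::IRanges(
      start = c(model$exons$start[1L], model$exons$start),
      end = c(model$exons$end[n], model$exons$end)),
    strand = model$strand)
  S4Vectors::mcols(gr)$type <- c("gene", rep("exon", n))
  S4Vectors::mcols(gr)$ID <- c(model$gene_id,
                               paste0(model$gene_id, ".exon", seq_len(n)))
  S4Vectors::mcols(gr)$Parent <- c(NA_character_, rep(model$gene_id, n))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
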