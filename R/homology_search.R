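# Desk-scale local-alignment homology search: k-mer seeded, banded
# seed-and-extend local alignments used to find second (gametolog or
# translocated) copies of amplicons and to classify gene locations.
#
# Scoring is fixed at match +1 / mismatch -2 / gap open -5 / gap extend -2
# so that results are well-defined and comparable against an exhaustive
# Smith-Waterman computed independently in the tests.

.SW_SCORING <- list(match = 1L, mismatch = 2L, gap_open = 5L, gap_ext = 2L)

# Internal: seed matches (qpos, spos) of word_size-mers of q in s.
# Query words are sampled at `stride` to keep the dictionary small; the
# alignment band margin absorbs the coarser seed bounds.
.word_seeds <- function(q, s, word_size, stride = 4L) {
  nq <- nchar(q)
  if (nq < word_size || nchar(s) < word_size)
    return(data.frame(qpos = integer(), spos = integer()))
  starts <- unique(c(seq(1L, nq - word_size + 1L, by = stride),
                     nq - word_size + 1L))
  kmers <- substring(q, starts, starts + word_size - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  if (!any(ok)) return(data.frame(qpos = integer(), spos = integer()))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[ok]))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(s))
  st <- IRanges::start(m)
  qpos <- rep.int(starts[ok], lengths(st))
  data.frame(qpos = qpos, spos = unlist(st, use.names = FALSE))
}

# Internal: cluster seeds into diagonal bands. Seeds join a cluster when
# their diagonal is within `diag_tol` of the cluster's diagonal range and
# their subject position within `pos_gap` of it. Large interior indels
# (> diag_tol) therefore split into separate clusters, which are aligned
# separately and reassembled by co-linear chaining downstream.
.seed_clusters <- function(seeds, diag_tol = 20L, pos_gap = 1500L) {
  if (!nrow(seeds)) return(list())
  seeds$diag <- seeds$spos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$spos), , drop = FALSE]
  clusters <- list()
  cur <- seeds[1L, , drop = FALSE]
  dmin <- cur$diag; dmax <- cur$diag
  smin <- cur$spos; smax <- cur$spos
  rows <- 1L
  flush <- function() {
    clusters[[length(clusters) + 1L]] <<- list(
      dmin = dmin, dmax = dmax, smin = smin, smax = smax,
      qmin = min(seeds$qpos[rows]), qmax = max(seeds$qpos[rows]))
  }
  if (nrow(seeds) > 1L) for (i in 2L:nrow(seeds)) {
    d <- seeds$diag[i]; sp <- seeds$spos[i]
    if (d - dmax <= diag_tol &&
        (sp >= smin - pos_gap && sp <= smax + pos_gap)) {
      dmax <- max(dmax, d); dmin <- min(dmin, d)
      smin <- min(smin, sp); smax <- max(smax, sp)
      rows <- c(rows, i)
    } else {
      flush()
      dmin <- dmax <- d; smin <- smax <- sp; rows <- i
    }
  }
  flush()
  clusters
}

# Internal: run one banded alignment for a seed cluster.
.align_cluster <- function(q, s, cl, margin = 25L) {
  sc <- .SW_SCORING
  res <- .sw_align_cpp(q, s, sc$match, sc$mismatch, sc$gap_open, sc$gap_ext,
                       cl$dmin - margin, cl$dmax + margin)
  if (res$score <= 0L || is.na(res$qstart)) return(NULL)
  as.data.frame(res)
}

#' Seed-and-extend local-alignment search
#'
#' Searches `query` against every subject on both strands. Word-size exact
#' seeds are clustered by diagonal; each cluster is extended by banded
#' affine local alignment under the fixed scoring (+1/-2, gap -5/-2).
#' Overlapping hits on the same subject and strand are reduced to the
#' maximal-scoring one; co-linear non-overlapping hits (e.g. the two sides
#' of a large interior indel) are reported separately and can be
#' reassembled with [chain_hits()].
#'
#' @param query query sequence (character/DNAString/1-record DNAStringSet).
#' @param subjects [Biostrings::DNAStringSet] or named character vector.
#' @param min_identity minimum hit identity fraction (default 0.70,
#'   tolerant of diverged gametolog copies).
#' @param min_hit_len minimum alignment length in columns (default 50).
#' @param word_size seed length (default 11; must be >= 8).
#' @param query_id id recorded in the output.
#' @param completeness query-span coverage below which a hit is flagged
#'   `partial` (default 0.90). Span coverage, not aligned-column coverage:
#'   a copy with a large interior indel is complete, a truncated copy is
#'   not.
#' @return data.frame of hits sorted by decreasing score with columns
#'   `query_id`, `subject_id`, `strand`, `score`, `identity`, `nident`,
#'   `aligned`, `qstart`, `qend`, `sstart`, `send`, `subject_span`,
#'   `query_cover`, `partial`.
#' @export
local_search <- function(query, subjects, min_identity = 0.70,
                         min_hit_len = 50L, word_size = 11L,
                         query_id = "query", completeness = 0.90) {
  if (word_size < 8L) stop("word_size must be >= 8")
  q <- .seq_chr(query)
  if (is.character(subjects)) subjects <- Biostrings::DNAStringSet(subjects)
  nq <- nchar(q)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      strand = character(), score = integer(),
                      identity = double(), nident = integer(),
                      aligned = integer(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      subject_span = integer(), qlen = integer(),
                      query_cover = double(), partial = logical(),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (si in seq_along(subjects)) {
    sid <- names(subjects)[si]
    s <- as.character(subjects[[si]])
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else revcomp(q)
      seeds <- .word_seeds(qq, s, word_size)
      for (cl in .seed_clusters(seeds)) {
        al <- .align_cluster(qq, s, cl)
        if (is.null(al)) next
        if (al$aligned < min_hit_len) next
        identity <- al$nident / al$aligned
        if (identity < min_identity) next
        qs <- al$qstart; qe <- al$qend
        if (strand == "-") { qs <- nq - al$qend + 1L; qe <- nq - al$qstart + 1L }
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query_id, subject_id = sid, strand = strand,
          score = al$score, identity = identity, nident = al$nident,
          aligned = al$aligned, qstart = qs, qend = qe,
          sstart = al$sstart, send = al$send,
          subject_span = al$send - al$sstart + 1L,
          qlen = nq,
          query_cover = (qe - qs + 1L) / nq,
          partial = (qe - qs + 1L) / nq < completeness,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, hits$subject_id, hits$sstart), ,
               drop = FALSE]
  # drop lower-scoring hits substantially overlapping a kept hit on the
  # same subject/strand (alternate views of one region); hits that merely
  # abut -- the two flanks of an interior indel -- are both kept
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    if (i > 1L) for (j in which(keep)) {
      if (hits$subject_id[j] != hits$subject_id[i] ||
          hits$strand[j] != hits$strand[i]) next
      ovl <- min(hits$send[i], hits$send[j]) -
        max(hits$sstart[i], hits$sstart[j]) + 1L
      if (ovl > 0.5 * min(hits$subject_span[i], hits$subject_span[j])) {
        ov <- TRUE; break
      }
    }
    keep[i] <- !ov
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Chain co-linear hits into copy regions
#'
#' Merges hits of one query on one subject/strand that are consistently
#' ordered in both query and subject (ascending, subject gap at most
#' `max_gap`) into a single region -- reassembling the two flanks of a
#' copy interrupted by a large insertion or deletion. The region's
#' `subject_span` is the indel-inclusive subject-side extent, which is the
#' quantity compared between Z and W copies.
#'
#' @param hits data.frame from [local_search()].
#' @param max_gap maximum subject/query gap bridged by chaining
#'   (default 5000).
#' @param completeness query-span coverage below which the chained region
#'   is flagged `partial` (default 0.90).
#' @return data.frame of regions, one per (subject, strand, chain), sorted
#'   by decreasing score, same columns as [local_search()].
#' @export
chain_hits <- function(hits, max_gap = 5000L, completeness = 0.90) {
  if (!nrow(hits)) return(hits)
  out <- list()
  for (sid in unique(hits$subject_id)) for (strand in c("+", "-")) {
    h <- hits[hits$subject_id == sid & hits$strand == strand, , drop = FALSE]
    if (!nrow(h)) next
    ord <- if (strand == "+") order(h$qstart) else order(-h$qstart)
    h <- h[ord, , drop = FALSE]
    # greedy chains: successor must advance in query and subject
    used <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      if (used[i]) next
      chain <- i; used[i] <- TRUE
      repeat {
        last <- chain[length(chain)]
        nxt <- 0L
        for (j in seq_len(nrow(h))) {
          if (used[j]) next
          q_ok <- if (strand == "+")
            h$qstart[j] > h$qstart[last] &&
              h$qstart[j] - h$qend[last] - 1L <= max_gap &&
              h$qstart[j] >= h$qend[last] - 15L
          else
            h$qstart[j] < h$qstart[last] &&
              h$qstart[last] - h$qend[j] - 1L <= max_gap &&
              h$qend[j] <= h$qstart[last] + 15L
          s_ok <- h$sstart[j] > h$send[last] - 15L &&
            h$sstart[j] - h$send[last] - 1L <= max_gap
          if (q_ok && s_ok) { nxt <- j; break }
        }
        if (nxt == 0L) break
        chain <- c(chain, nxt); used[nxt] <- TRUE
      }
      ch <- h[chain, , drop = FALSE]
      nq_len <- ch$qlen[1L]
      qs <- min(ch$qstart); qe <- max(ch$qend)
      out[[length(out) + 1L]] <- data.frame(
        query_id = ch$query_id[1L], subject_id = sid, strand = strand,
        score = sum(ch$score),
        identity = sum(ch$nident) / sum(ch$aligned),
        nident = sum(ch$nident), aligned = sum(ch$aligned),
        qstart = qs, qend = qe,
        sstart = min(ch$sstart), send = max(ch$send),
        subject_span = max(ch$send) - min(ch$sstart) + 1L,
        qlen = nq_len,
        query_cover = (qe - qs + 1L) / nq_len,
        partial = (qe - qs + 1L) / nq_len < completeness,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Locate a gene across a labelled assembly
#'
#' Searches each exon of a gene against every assembly sequence and
#' aggregates, per subject, mean best-hit identity and mean query cover
#' over the exons (an exon with no hit counts as zero cover). Subjects
#' passing both thresholds are reported best-first; role labels come from
#' `roles`.
#'
#' @param exon_seqs [Biostrings::DNAStringSet] of the gene's exon
#'   sequences.
#' @param assembly [Biostrings::DNAStringSet] of assembly sequences.
#' @param roles named role vector (see [role_map()]).
#' @param min_identity,min_query_cover acceptance thresholds
#'   (defaults 0.70 and 0.50).
#' @param min_hit_len,word_size passed to [local_search()]
#'   (`min_hit_len` default 30: exons are short).
#' @return data.frame of candidate locations sorted best-first
#'   (`subject_id`, `role`, `identity`, `query_cover`, `score`); zero rows
#'   mean the gene is absent.
#' @export
locate_gene <- function(exon_seqs, assembly, roles,
                        min_identity = 0.70, min_query_cover = 0.50,
                        min_hit_len = 30L, word_size = 11L) {
  roles <- role_map(roles)
  agg <- list()
  for (sid in names(assembly)) {
    idents <- covers <- scores <- numeric(length(exon_seqs))
    for (ei in seq_along(exon_seqs)) {
      h <- local_search(as.character(exon_seqs[[ei]]), assembly[sid],
                        min_identity = 0, min_hit_len = min_hit_len,
                        word_size = word_size)
      if (nrow(h)) {
        idents[ei] <- h$identity[1L]
        covers[ei] <- h$query_cover[1L]
        scores[ei] <- h$score[1L]
      }
    }
    agg[[sid]] <- data.frame(
      subject_id = sid,
      role = unname(roles[sid]),
      identity = mean(idents), query_cover = mean(covers),
      score = sum(scores), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, agg)
  res <- res[res$identity >= min_identity &
               res$query_cover >= min_query_cover, , drop = FALSE]
  res <- res[order(-res$score, -res$identity, res$subject_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene presence/absence matrix across a labelled assembly
#'
#' @param genes named list of exon [Biostrings::DNAStringSet]s, one per
#'   gene.
#' @param assembly [Biostrings::DNAStringSet].
#' @param roles named role vector.
#' @param ... thresholds passed to [locate_gene()].
#' @return list with logical `present` (gene x subject), numeric
#'   `identity` and `query_cover` matrices, and `roles` giving each
#'   column's label. Best location per gene is the highest-scoring
#'   passing subject.
#' @export
presence_matrix <- function(genes, assembly, roles, ...) {
  roles <- role_map(roles)
  sids <- names(assembly)
  present <- matrix(FALSE, nrow = length(genes), ncol = length(sids),
                    dimnames = list(names(genes), sids))
  identity <- qcover <- matrix(NA_real_, nrow = length(genes),
                               ncol = length(sids),
                               dimnames = dimnames(present))
  for (gi in seq_along(genes)) {
    loc <- locate_gene(genes[[gi]], assembly, roles, ...)
    if (nrow(loc)) {
      present[gi, loc$subject_id] <- TRUE
      identity[gi, loc$subject_id] <- loc$identity
      qcover[gi, loc$subject_id] <- loc$query_cover
    }
  }
  list(present = present, identity = identity, query_cover = qcover,
       roles = roles[sids])
}

#' Export homology hits as tabular TSV
#'
#' BLAST outfmt-6-style columns: qseqid, sseqid, pident, length, qstart,
#' qend, sstart, send, qcovs (percentages on 0--100 scale).
#'
#' @param hits data.frame from [local_search()] or [chain_hits()].
#' @param path output TSV.
#' @export
hits_to_tsv <- function(hits, path) {
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                    pident = round(hits$identity * 100, 2),
                    length = hits$aligned,
                    qstart = hits$qstart, qend = hits$qend,
                    sstart = hits$sstart, send = hits$send,
                    qcovs = round(hits$query_cover * 100, 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
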