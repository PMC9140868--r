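# Z/W copy pairing and intron length polymorphism (delta-L) computation:
# the Z-specific amplicon is paired with its best second copy elsewhere in
# the genome and the length difference between the two copies is the
# sexing signal.

#' Pair a Z-specific amplicon with its second genomic copy
#'
#' Co-linear hit regions (see [chain_hits()]) on non-Z subjects are ranked
#' by `identity * query_cover`; ties prefer a W-labelled subject over a
#' scaffold (a sex-chromosome copy is the more parsimonious reading), then
#' higher identity, then lexical subject id. The second copy's length is
#' the subject-side span, indel-inclusive, because genomic copy lengths --
#' not alignment lengths -- are what differ between gametologs. A partial
#' (end-truncated) copy is reported but excluded from delta-L: an
#' incomplete longer copy must not masquerade as a shorter variant.
#'
#' @param z_amplicon one amplicon row (needs `marker_id`, `seq_id`,
#'   `length`; the amplicon must come from a Z-labelled sequence).
#' @param hits data.frame from [local_search()] run with the amplicon
#'   sequence as query against the genome.
#' @param roles named role vector (see [role_map()]).
#' @param species_id recorded in the report.
#' @param completeness query-span coverage below which the copy is partial
#'   (default 0.90).
#' @param max_gap chaining gap, see [chain_hits()].
#' @return one-row data.frame: `marker_id`, `species_id`, `z_seq`,
#'   `z_length`, `second_seq`, `second_length`, `second_location`,
#'   `partial`, `delta_L`, `z_longer`, `identity`, `query_cover`.
#' @export
pair_copies <- function(z_amplicon, hits, roles, species_id = NA_character_,
                        completeness = 0.90, max_gap = 5000L) {
  roles <- role_map(roles)
  if (!identical(unname(roles[z_amplicon$seq_id]), "Z"))
    stop("z_amplicon must come from a Z-labelled sequence, got role '",
         roles[z_amplicon$seq_id], "'")
  report <- data.frame(
    marker_id = z_amplicon$marker_id, species_id = species_id,
    z_seq = z_amplicon$seq_id, z_length = as.integer(z_amplicon$length),
    second_seq = NA_character_, second_length = NA_integer_,
    second_location = "absent", partial = FALSE,
    delta_L = NA_integer_, z_longer = NA,
    identity = NA_real_, query_cover = NA_real_,
    stringsAsFactors = FALSE)
  if (!nrow(hits)) return(report)
  h <- hits[roles[hits$subject_id] != "Z", , drop = FALSE]
  if (!nrow(h)) return(report)
  reg <- chain_hits(h, max_gap = max_gap, completeness = completeness)
  reg$role <- unname(roles[reg$subject_id])
  # rank: identity * query_cover, then W before other roles, then identity
  qual <- reg$identity * reg$query_cover
  role_rank <- ifelse(reg$role == "W", 0L, 1L)
  ord <- order(-round(qual, 6), role_rank, -reg$identity, reg$subject_id)
  best <- reg[ord[1L], , drop = FALSE]
  report$second_seq <- best$subject_id
  report$second_length <- best$subject_span
  report$second_location <- best$role
  report$partial <- best$partial
  report$identity <- best$identity
  report$query_cover <- best$query_cover
  if (!best$partial) {
    report$delta_L <- abs(report$z_length - best$subject_span)
    report$z_longer <- report$z_length > best$subject_span
  }
  report
}

#' Per-species, per-marker copy summary table
#'
#' Flattens copy-pair reports into a long table, one row per copy, with
#' partial copies flagged "(p)" -- the layout of a published copy-length
#' comparison across species.
#'
#' @param reports data.frame of rows from [pair_copies()] (rbind-ed).
#' @return data.frame `species_id`, `marker_id`, `copy` ("Z"/"second"),
#'   `seq_id`, `length`, `flag`, ordered by species, marker, copy.
#' @export
species_summary <- function(reports) {
  if (!nrow(reports))
    return(data.frame(species_id = character(), marker_id = character(),
                      copy = character(), seq_id = character(),
                      length = character(), flag = character(),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(reports))) {
    r <- reports[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = r$species_id, marker_id = r$marker_id, copy = "Z",
      seq_id = r$z_seq, length = as.character(r$z_length), flag = "",
      stringsAsFactors = FALSE)
    second_len <- if (is.na(r$second_length)) "-" else
      as.character(r$second_length)
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = r$species_id, marker_id = r$marker_id, copy = "second",
      seq_id = if (is.na(r$second_seq)) "-" else r$second_seq,
      length = second_len,
      flag = if (isTRUE(r$partial)) "(p)" else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$species_id, out$marker_id, out$copy), , drop = FALSE]
  rownames(out) <- NULL
  out
}
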