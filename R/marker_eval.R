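# Marker evaluation: turn copy-pair reports and gel resolvability into
# per-marker sexing verdicts, per-individual sex calls, and a ranked
# marker panel per species.

.VERDICTS <- c("informative", "z_only", "unresolvable_polymorphism",
               "not_found", "partial_copy_only", "confounded")

#' Evaluate one marker for one species
#'
#' Decision rules: no Z amplicon at all -> `not_found`; second copy absent
#' -> `z_only` (a single-band marker cannot separate the sexes); second
#' copy partial -> `partial_copy_only` (no trustworthy delta-L); delta-L
#' zero or unresolvable on any standard gel -> `unresolvable_polymorphism`;
#' otherwise `informative` at the smallest resolving gel percentage.
#' Nonspecific products that co-migrate with (or are indistinct from) a
#' diagnostic band at that gel confound interpretation -> `confounded`.
#'
#' @param pair one-row report from [pair_copies()], or `NULL`/NA `z_length`
#'   when no Z amplicon was predicted.
#' @param time electrophoresis run time in minutes (default 60).
#' @param nonspecific optional numeric vector of nonspecific product
#'   lengths observed/planted for this marker and species.
#' @param voltage_gradient,band_sigma,lane_length,params gel settings,
#'   see [gel_config()].
#' @return one-row data.frame: `marker_id`, `species_id`, `verdict`,
#'   `gel_pct_required`, `delta_L`, `notes`.
#' @export
evaluate_marker <- function(pair, time = 60, nonspecific = NULL,
                            voltage_gradient = 5, band_sigma = 1,
                            lane_length = 80,
                            params = default_gel_params()) {
  mk <- if (is.null(pair)) NA_character_ else pair$marker_id
  sp <- if (is.null(pair)) NA_character_ else pair$species_id
  out <- data.frame(marker_id = mk, species_id = sp,
                    verdict = NA_character_, gel_pct_required = NA_real_,
                    delta_L = NA_integer_, notes = "",
                    stringsAsFactors = FALSE)
  notes <- character()
  if (is.null(pair) || is.na(pair$z_length)) {
    out$verdict <- "not_found"
    return(out)
  }
  if (pair$second_location == "absent") {
    out$verdict <- "z_only"
  } else if (isTRUE(pair$partial)) {
    out$verdict <- "partial_copy_only"
    notes <- c(notes, sprintf("second copy truncated (query cover %.2f)",
                              pair$query_cover))
  } else {
    out$delta_L <- pair$delta_L
    if (pair$delta_L == 0L) {
      out$verdict <- "unresolvable_polymorphism"
      notes <- c(notes, "copies equal in length")
    } else {
      g <- min_gel_percent(pair$z_length, pair$second_length, time,
                           voltage_gradient, band_sigma, lane_length,
                           params)
      if (is.na(g)) {
        out$verdict <- "unresolvable_polymorphism"
        notes <- c(notes, sprintf("delta-L %d bp below gel resolution",
                                  pair$delta_L))
      } else {
        out$verdict <- "informative"
        out$gel_pct_required <- g
        cfg <- gel_config(g, voltage_gradient, band_sigma, lane_length,
                          params)
        for (b in nonspecific) {
          sep_z <- band_separation(b, pair$z_length, cfg, time)
          sep_w <- band_separation(b, pair$second_length, cfg, time)
          if (sep_z != "separated" || sep_w != "separated") {
            out$verdict <- "confounded"
            out$gel_pct_required <- NA_real_
            notes <- c(notes, sprintf(
              "nonspecific %d bp band overlaps the diagnostic window", b))
            break
          }
        }
        if (out$verdict == "informative" && length(nonspecific))
          notes <- c(notes, sprintf("nonspecific band(s) %s bp clear of diagnostic bands",
                                    paste(nonspecific, collapse = "/")))
      }
    }
  }
  out$notes <- paste(notes, collapse = "; ")
  out
}

#' Call the sex of one individual from its band pattern
#'
#' Two gel-separable diagnostic bands mean ZW (female); a single diagnostic
#' band means ZZ (male) but only under an `informative` marker verdict --
#' with any other verdict a single band is uninterpretable (it would call
#' males for degraded DNA or for species where the marker drops out), so
#' the call is `indeterminate`, never a guessed sex.
#'
#' @param bands numeric vector of observed fragment lengths (bp) in one
#'   lane.
#' @param verdict one-row data.frame from [evaluate_marker()].
#' @param time run time in minutes (default 60).
#' @param voltage_gradient,band_sigma,lane_length,params gel settings.
#' @return one-row data.frame: `call` ("male"/"female"/"indeterminate"),
#'   `band_count`, `reason`.
#' @export
sex_call <- function(bands, verdict, time = 60, voltage_gradient = 5,
                     band_sigma = 1, lane_length = 80,
                     params = default_gel_params()) {
  res <- function(call, reason)
    data.frame(call = call, band_count = length(bands), reason = reason,
               stringsAsFactors = FALSE)
  if (!length(bands)) return(res("indeterminate", "no amplification"))
  if (verdict$verdict != "informative")
    return(res("indeterminate",
               paste0("marker verdict is ", verdict$verdict)))
  cfg <- gel_config(verdict$gel_pct_required, voltage_gradient, band_sigma,
                    lane_length, params)
  # count visually distinct bands at this gel
  lens <- sort(unique(bands))
  groups <- list(lens[1L])
  if (length(lens) > 1L) for (b in lens[-1L]) {
    last <- groups[[length(groups)]]
    if (band_separation(max(last), b, cfg, time) == "separated")
      groups[[length(groups) + 1L]] <- b
    else
      groups[[length(groups)]] <- c(last, b)
  }
  n_distinct <- length(groups)
  if (n_distinct >= 2L) return(res("female", "two separable bands"))
  res("male", "single band under an informative marker")
}

#' Rank markers per species
#'
#' Informative markers are ranked by (lowest required gel percentage,
#' largest delta-L, fewest notes), with a deterministic marker-id
#' tie-break; output is invariant under permutation of the input rows.
#'
#' @param verdicts data.frame of rows from [evaluate_marker()] covering a
#'   marker x species grid.
#' @return data.frame `species_id`, `rank`, `marker_id`,
#'   `gel_pct_required`, `delta_L`, `note`; species with no informative
#'   marker get a single row with `note` explaining the absence.
#' @export
recommend_panel <- function(verdicts) {
  out <- list()
  for (sp in sort(unique(verdicts$species_id))) {
    v <- verdicts[verdicts$species_id == sp & verdicts$verdict ==
                    "informative", , drop = FALSE]
    if (!nrow(v)) {
      out[[length(out) + 1L]] <- data.frame(
        species_id = sp, rank = NA_integer_, marker_id = NA_character_,
        gel_pct_required = NA_real_, delta_L = NA_integer_,
        note = "no informative marker for this species",
        stringsAsFactors = FALSE)
      next
    }
    n_notes <- nchar(v$notes) > 0L
    ord <- order(v$gel_pct_required, -v$delta_L, n_notes, v$marker_id)
    v <- v[ord, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      species_id = sp, rank = seq_len(nrow(v)), marker_id = v$marker_id,
      gel_pct_required = v$gel_pct_required, delta_L = v$delta_L,
      note = v$notes, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Human-readable per-species marker report
#'
#' @param verdicts data.frame of rows from [evaluate_marker()].
#' @param panel optional output of [recommend_panel()] (recomputed when
#'   missing).
#' @return character vector of markdown lines.
#' @export
species_report <- function(verdicts, panel = recommend_panel(verdicts)) {
  lines <- c("# Marker evaluation report", "")
  for (sp in sort(unique(verdicts$species_id))) {
    lines <- c(lines, paste0("## Species ", sp), "")
    v <- verdicts[verdicts$species_id == sp, , drop = FALSE]
    v <- v[order(v$marker_id), , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      extra <- if (!is.na(v$gel_pct_required[i]))
        sprintf(" (resolves on a %g%% gel, delta-L %d bp)",
                v$gel_pct_required[i], v$delta_L[i]) else ""
      note <- if (nzchar(v$notes[i])) paste0(" -- ", v$notes[i]) else ""
      lines <- c(lines, sprintf("- %s: %s%s%s", v$marker_id[i],
                                v$verdict[i], extra, note))
    }
    p <- panel[panel$species_id == sp, , drop = FALSE]
    top <- if (all(is.na(p$marker_id))) "none"
           else p$marker_id[which.min(p$rank)]
    lines <- c(lines, "", paste0("Recommended marker: ", top), "")
  }
  lines
}
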