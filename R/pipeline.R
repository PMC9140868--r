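# End-to-end driver: gene structure -> in-silico PCR -> second-copy
# search -> copy pairing -> gel/verdicts, over one sequence bundle
# (a simulated genome or a reference fixture species).

#' Run the full marker-evaluation pipeline on one sequence bundle
#'
#' A bundle is a list with `sequences` (DNAStringSet), `roles` (see
#' [role_map()]), and optionally `mrnas` plus `mrna_targets` (data.frame
#' `mrna_id`, `seq_id`, `gene_id`) for gene-structure inference.
#'
#' Steps: (1) map each mRNA onto its target sequence to get gene models;
#' (2) scan all primers over all sequences and enumerate products;
#' (3) keep, per marker, the best-supported Z amplicon (fewest total
#' primer mismatches, then lexically smallest sequence id) and annotate
#' its exon/intron composition against the covering gene model;
#' (4) search each Z amplicon against all non-Z sequences and pair it
#' with its best second copy; (5) evaluate each marker's sexing verdict.
#'
#' @param bundle sequence bundle (see above).
#' @param primers primer table ([read_primer_table()] format).
#' @param species_id id recorded in reports.
#' @param max_mismatch,three_prime_exact,max_product scanning parameters.
#' @param min_identity,word_size,completeness homology-search parameters.
#' @param time electrophoresis time (minutes) for verdicts.
#' @param nonspecific optional named list: marker id -> lengths of known
#'   nonspecific products for this species.
#' @return list: `models` (per mRNA), `amplicons` (all products),
#'   `z_amplicons` (per-marker chosen Z product with `composition`),
#'   `reports` (copy pairing), `verdicts`, `panel`.
#' @export
run_marker_pipeline <- function(bundle, primers,
                                species_id = "species",
                                max_mismatch = 2L, three_prime_exact = 3L,
                                max_product = 5000L,
                                min_identity = 0.70, word_size = 11L,
                                completeness = 0.90, time = 60,
                                nonspecific = NULL) {
  seqs <- bundle$sequences
  roles <- role_map(bundle$roles)

  models <- list()
  if (!is.null(bundle$mrnas)) {
    for (i in seq_len(nrow(bundle$mrna_targets))) {
      tg <- bundle$mrna_targets[i, ]
      models[[tg$mrna_id]] <- map_exons(
        as.character(bundle$mrnas[[tg$mrna_id]]),
        as.character(seqs[[tg$seq_id]]),
        gene_id = tg$gene_id, seq_id = tg$seq_id)
    }
  }

  amps <- predict_amplicons(seqs, primers, max_mismatch,
                            three_prime_exact, max_product)

  z_rows <- list()
  for (mk in primers$marker) {
    a <- amps[amps$marker_id == mk & roles[amps$seq_id] == "Z", ,
              drop = FALSE]
    if (!nrow(a)) next
    a <- a[order(a$fwd_mm + a$rev_mm, a$seq_id, a$start), , drop = FALSE]
    z <- a[1L, , drop = FALSE]
    model <- NULL
    for (m in models)
      if (m$seq_id == z$seq_id &&
          m$exons$start[1L] <= z$start &&
          m$exons$end[nrow(m$exons)] >= z$end) { model <- m; break }
    if (!is.null(model)) {
      comp <- annotate_composition(z, model)
      z$composition <- comp$composition
      z$gene_id <- model$gene_id
    } else {
      z$composition <- NA_character_
      z$gene_id <- NA_character_
    }
    z_rows[[mk]] <- z
  }
  z_amps <- if (length(z_rows)) do.call(rbind, z_rows) else NULL

  non_z <- seqs[roles[names(seqs)] != "Z"]
  reports <- list()
  verdicts <- list()
  for (mk in primers$marker) {
    if (is.null(z_rows[[mk]])) {
      verdicts[[mk]] <- evaluate_marker(
        data.frame(marker_id = mk, species_id = species_id,
                   z_length = NA_integer_, stringsAsFactors = FALSE),
        time = time)
      verdicts[[mk]]$marker_id <- mk
      verdicts[[mk]]$species_id <- species_id
      next
    }
    z <- z_rows[[mk]]
    hits <- if (length(non_z))
      local_search(z$sequence, non_z, min_identity = min_identity,
                   word_size = word_size, query_id = mk,
                   completeness = completeness)
    else
      local_search(z$sequence, Biostrings::DNAStringSet(), query_id = mk)
    rep <- pair_copies(z, hits, roles, species_id = species_id,
                       completeness = completeness)
    reports[[mk]] <- rep
    verdicts[[mk]] <- evaluate_marker(rep, time = time,
                                      nonspecific = nonspecific[[mk]])
  }
  reports <- if (length(reports)) do.call(rbind, reports) else NULL
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL
  if (!is.null(reports)) rownames(reports) <- NULL

  list(models = models, amplicons = amps, z_amplicons = z_amps,
       reports = reports, verdicts = verdicts,
       panel = recommend_panel(verdicts))
}

#' Compare pipeline output against a generator truth set
#'
#' Per-stage exact-match summary: gene models (exon coordinates), Z
#' amplicons (coordinates and length), length polymorphism (delta-L,
#' direction) and second-copy location.
#'
#' @param run output of [run_marker_pipeline()] on a [simulate_zw()]
#'   bundle.
#' @param truth the bundle's `truth` element.
#' @return list with `stages` (data.frame `stage`, `n_expected`,
#'   `n_exact`), `exact` (overall logical), and `mismatches`
#'   (character description of each discrepancy).
#' @export
recovery_report <- function(run, truth) {
  mism <- character()
  n_exp <- n_ok <- c(models = 0L, amplicons = 0L, delta = 0L,
                     location = 0L)

  for (gid in names(truth$models)) {
    n_exp["models"] <- n_exp["models"] + 1L
    tm <- truth$models[[gid]]
    got <- NULL
    for (m in run$models)
      if (m$gene_id == tm$gene_id && m$seq_id == tm$seq_id) got <- m
    if (!is.null(got) && identical(got$exons, tm$exons))
      n_ok["models"] <- n_ok["models"] + 1L
    else
      mism <- c(mism, paste0("gene model mismatch: ", gid))
  }

  ta <- truth$amplicons
  for (i in seq_len(nrow(ta))) {
    n_exp["amplicons"] <- n_exp["amplicons"] + 1L
    mk <- ta$marker_id[i]
    z <- run$z_amplicons[run$z_amplicons$marker_id == mk, , drop = FALSE]
    ok <- nrow(z) == 1L && z$start == ta$start[i] && z$end == ta$end[i] &&
      z$length == ta$length[i] &&
      (is.na(z$composition) || z$composition == ta$composition[i])
    if (isTRUE(ok)) n_ok["amplicons"] <- n_ok["amplicons"] + 1L
    else mism <- c(mism, paste0("amplicon mismatch: ", mk))
  }

  tm <- truth$markers
  for (i in seq_len(nrow(tm))) {
    mk <- tm$marker_id[i]
    r <- run$reports[run$reports$marker_id == mk, , drop = FALSE]
    n_exp["delta"] <- n_exp["delta"] + 1L
    ok_d <- nrow(r) == 1L &&
      identical(r$delta_L, tm$delta_L[i]) &&
      identical(r$z_longer, tm$z_longer[i]) &&
      identical(r$partial, tm$partial[i])
    if (isTRUE(ok_d)) n_ok["delta"] <- n_ok["delta"] + 1L
    else mism <- c(mism, paste0("delta-L mismatch: ", mk))
    n_exp["location"] <- n_exp["location"] + 1L
    ok_l <- nrow(r) == 1L &&
      identical(r$second_location, tm$second_location[i])
    if (isTRUE(ok_l)) n_ok["location"] <- n_ok["location"] + 1L
    else mism <- c(mism, paste0("location mismatch: ", mk))
  }

  stages <- data.frame(stage = names(n_exp), n_expected = unname(n_exp),
                       n_exact = unname(n_ok))
  list(stages = stages, exact = all(n_exp == n_ok), mismatches = mism)
}
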