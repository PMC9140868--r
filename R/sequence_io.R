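# Sequence and table input/output.
#
# Genome and mRNA collections are carried as Biostrings::DNAStringSet with
# record ids in names(); role labels (Z / W / scaffold / unknown) live in a
# sidecar map because assemblies differ in how headers encode chromosomes.

.ROLE_LEVELS <- c("Z", "W", "scaffold", "unknown")

#' Read a (multi-)FASTA file of genome or mRNA sequences
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' the IUPAC nucleotide alphabet is rejected with an error naming the
#' offending record. Record ids (first word of each header) must be unique.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop("empty sequence for record ", ids[i])
    .check_alphabet(seqs[i], .iupac_letters, paste0("record ", ids[i]))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA with 60-column wrapping
#'
#' Round-trips with [read_genome_fasta()]: sequence content is reproduced
#' byte-identically.
#'
#' @param x a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file.
#' @export
write_genome_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a primer table
#'
#' A TSV with columns `marker`, `fwd_name`, `fwd_seq`, `rev_name`, `rev_seq`,
#' `gene`. With no `path` the packaged table of the seven turaco sexing
#' marker primer pairs (M1--M7; CHD1, SPIN and NIPBL genes) is read.
#'
#' @param path TSV file; `NULL` for the packaged primer set.
#' @return data.frame with one row per marker, primer sequences validated
#'   against the IUPAC alphabet.
#' @export
read_primer_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "primers.tsv", package = "zwmarkers",
                        mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("marker", "fwd_name", "fwd_seq", "rev_name", "rev_seq", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("primer table missing column(s): ",
                         paste(miss, collapse = ","))
  if (anyDuplicated(df$marker))
    stop("duplicate marker id(s) in primer table")
  df$fwd_seq <- toupper(df$fwd_seq)
  df$rev_seq <- toupper(df$rev_seq)
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$fwd_seq[i]) || !nzchar(df$rev_seq[i]))
      stop("empty primer sequence for marker ", df$marker[i])
    .check_alphabet(df$fwd_seq[i], .iupac_letters,
                    paste0("primer ", df$fwd_name[i]))
    .check_alphabet(df$rev_seq[i], .iupac_letters,
                    paste0("primer ", df$rev_name[i]))
  }
  df[, need]
}

#' Read a sequence-role map
#'
#' YAML mapping record id to a role label (`Z`, `W`, `scaffold`, `unknown`),
#' e.g. `NW_010038079.1: Z`.
#'
#' @param path YAML file.
#' @return named character vector of roles.
#' @export
read_role_map <- function(path) {
  m <- yaml::read_yaml(path)
  role_map(unlist(m))
}

#' Construct/validate a sequence-role map
#'
#' @param x named character vector mapping sequence id to role.
#' @return the validated map.
#' @export
role_map <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("role map must be named by sequence id")
  bad <- setdiff(unique(x), .ROLE_LEVELS)
  if (length(bad))
    stop("unknown role label(s): ", paste(bad, collapse = ","),
         " (expected ", paste(.ROLE_LEVELS, collapse = "/"), ")")
  x
}

#' Write a sequence-role map as YAML
#'
#' @param roles named character vector (see [role_map()]).
#' @param path output file.
#' @export
write_role_map <- function(roles, path) {
  yaml::write_yaml(as.list(role_map(roles)), path)
  invisible(path)
}

# Internal: fetch one sequence as a plain uppercase character string.
.seq_chr <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x[[1L]]))
  }
  if (methods::is(x, "DNAString")) return(as.character(x))
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}
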