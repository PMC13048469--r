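#' Read an HMMER3 per-domain table (`domtblout`)
#'
#' Parses the 22 fixed whitespace-delimited columns of hmmscan
#' `--domtblout` output plus the free-text description. In an hmmscan
#' run with domain sequences as queries, the target is the Pfam model:
#' target accession gives the Pfam accession (release suffix such as
#' `.24` is stripped), `tlen` the model length, the query name the
#' domain id. Hit extent on the query is taken from the envelope
#' columns (`env from`/`env to`), HMMER's inclusive estimate of the
#' homologous region; per-hit bit score and independent E-value come
#' from the domain-level columns.
#'
#' Gathering-threshold status: hits produced by a real `hmmscan
#' --cut_ga` run all pass GA, so `passes_ga` defaults to `TRUE`. A
#' description field of `ga=0` (as written by [simulate_dataset()] and
#' [write_domtblout()] for planted sub-threshold hits) marks a hit as
#' failing GA.
#'
#' @param path Path to the domtblout file.
#' @param release Release tag to attach to every hit (e.g. `"38.2"`).
#' @return A tibble of hits with columns `query_domain_id`, `pfam_acc`,
#'   `pfam_name`, `bit_score`, `evalue`, `env_from`, `env_to`,
#'   `hmm_from`, `hmm_to`, `model_len`, `passes_ga`, `release`.
#' @export
read_domtblout <- function(path, release = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(tibble(query_domain_id = character(), pfam_acc = character(),
                  pfam_name = character(), bit_score = numeric(),
                  evalue = numeric(), env_from = integer(), env_to = integer(),
                  hmm_from = integer(), hmm_to = integer(),
                  model_len = integer(), passes_ga = logical(),
                  release = character()))
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  short <- which(lengths(fields) < 22L)
  if (length(short)) {
    stop(sprintf("domtblout line %d has %d columns (expected >= 22)",
                 keep[short[1]], lengths(fields)[short[1]]), call. = FALSE)
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  desc <- vapply(fields, function(f) {
    if (length(f) > 22L) paste(f[23:length(f)], collapse = " ") else "-"
  }, character(1))
  hits <- tibble(
    query_domain_id = col(4),
    pfam_acc = sub("\\.[0-9]+$", "", col(2)),
    pfam_name = col(1),
    bit_score = as.numeric(col(14)),
    evalue = as.numeric(col(13)),
    env_from = as.integer(col(20)),
    env_to = as.integer(col(21)),
    hmm_from = as.integer(col(16)),
    hmm_to = as.integer(col(17)),
    model_len = as.integer(col(3)),
    passes_ga = desc != "ga=0",
    release = release
  )
  bad <- which(hits$env_from > hits$env_to | hits$hmm_from > hits$hmm_to |
                 hits$hmm_to > hits$model_len | !is.finite(hits$bit_score))
  if (length(bad)) {
    stop(sprintf("inconsistent hit coordinates at domtblout line %d",
                 keep[bad[1]]), call. = FALSE)
  }
  hits
}

#' Write hits in HMMER3 domtblout layout
#'
#' Emits the genuine 23-column domtblout layout (space-delimited, `#`
#' header comments) so that files written here exercise the same parser
#' as real hmmscan output. Columns the hit tibble does not carry
#' (biases, accuracy, alignment coordinates) are filled with neutral
#' values; alignment coordinates repeat the envelope. Hits failing GA
#' get description `ga=0`.
#'
#' @param hits A hit tibble (see [read_domtblout()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  ), con, sep = "\n")
  if (nrow(hits)) {
    qlen <- hits$env_to  # query length unknown; envelope end is a safe floor
    lines <- sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
      hits$pfam_name, hits$pfam_acc, hits$model_len, hits$query_domain_id,
      "-", qlen, hits$evalue, hits$bit_score, 0, 1L, 1L, hits$evalue,
      hits$evalue, hits$bit_score, 0, hits$hmm_from, hits$hmm_to,
      hits$env_from, hits$env_to, hits$env_from, hits$env_to, 0.99,
      ifelse(hits$passes_ga, "-", "ga=0"))
    writeLines(lines, con, sep = "\n")
  }
  writeLines("#", con, sep = "\n")
  invisible(path)
}
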