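#' @import tibble
#' @importFrom dplyr %>% arrange bind_rows count filter group_by group_modify
#'   inner_join mutate n n_distinct pull rename row_number select semi_join
#'   slice summarise ungroup
#' @importFrom rlang .data
#' @importFrom stats median runif setNames
#' @importFrom utils head read.delim data
NULL

# Required columns of the domain table; extra columns are preserved on
# read/write for forward compatibility.
DOMAIN_COLUMNS <- c(
  "domain_id", "protein_acc", "range", "dpam_prob", "hit_ecod_domain_id",
  "tgroup_id", "hgroup_id", "xgroup_id", "arch_id", "ref_coverage",
  "ss_string", "plddt", "taxid"
)

#' Read a domain table
#'
#' The domain table is a TSV with one row per parsed domain. Required
#' columns: `domain_id`, `protein_acc`, `range` (segmented range string,
#' see [parse_range_string()]), `dpam_prob` (assignment probability in
#' \[0,1\]), `hit_ecod_domain_id`, `tgroup_id`, `hgroup_id`, `xgroup_id`,
#' `arch_id` (empty string when absent), `ref_coverage` (alignment
#' coverage of the reference domain in \[0,1\]), `ss_string` (per-residue
#' 8-state secondary-structure characters), `plddt` (comma-separated
#' per-residue values in \[0,100\]), `taxid`. Per-residue fields must
#' match the residue count of `range`; violations are an error.
#' Unknown columns are preserved.
#'
#' @param path Path to the TSV file.
#' @return A tibble of domains.
#' @export
read_domains <- function(path) {
  df <- read_tsv_strict(path)
  missing <- setdiff(DOMAIN_COLUMNS, names(df))
  if (length(missing)) {
    stop("domain table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$dpam_prob <- as.numeric(df$dpam_prob)
  df$ref_coverage <- as.numeric(df$ref_coverage)
  df$taxid <- as.integer(df$taxid)
  validate_domains(df)
  df
}

#' Write a domain table
#' @param domains A domain tibble (see [read_domains()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path) {
  validate_domains(domains)
  extra <- setdiff(names(domains), DOMAIN_COLUMNS)
  write_tsv_canonical(domains[, c(DOMAIN_COLUMNS, extra)], path)
}

validate_domains <- function(df) {
  if (anyDuplicated(df$domain_id)) {
    stop("duplicate domain_id in domain table", call. = FALSE)
  }
  if (any(df$dpam_prob < 0 | df$dpam_prob > 1, na.rm = TRUE)) {
    stop("dpam_prob outside [0,1]", call. = FALSE)
  }
  if (any(df$ref_coverage < 0 | df$ref_coverage > 1, na.rm = TRUE)) {
    stop("ref_coverage outside [0,1]", call. = FALSE)
  }
  nres <- ranges_nres(df$range)
  has_ss <- !is.na(df$ss_string) & nzchar(df$ss_string)
  bad_ss <- has_ss & nchar(df$ss_string) != nres
  if (any(bad_ss)) {
    stop("ss_string length differs from residue count for: ",
         paste(head(df$domain_id[bad_ss], 5), collapse = ", "), call. = FALSE)
  }
  np <- vapply(parse_plddt(df$plddt), length, integer(1))
  bad_p <- np != nres
  if (any(bad_p)) {
    stop("plddt length differs from residue count for: ",
         paste(head(df$domain_id[bad_p], 5), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Parse the compact per-residue pLDDT field
#' @param x Character vector of comma-separated pLDDT values.
#' @return A list of numeric vectors (values in \[0,100\]).
#' @export
parse_plddt <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    out <- as.numeric(v)
    if (anyNA(out) || any(out < 0 | out > 100)) {
      stop("pLDDT values must be numeric in [0,100]", call. = FALSE)
    }
    out
  })
}

#' Mean per-domain pLDDT
#' @param x Character vector of comma-separated pLDDT values.
#' @return Numeric vector of per-domain means.
#' @export
mean_plddt <- function(x) {
  vapply(parse_plddt(x), mean, numeric(1))
}

#' Read a taxonomic lineage table
#'
#' TSV with columns `taxid`, `species`, `family`, `order`, `class`,
#' `phylum`, `superkingdom`; absent ranks hold the label
#' `"unresolved"`. One row per taxid.
#'
#' @param path Path to the TSV file.
#' @return A tibble of lineages.
#' @export
read_lineages <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("taxid", TAX_RANKS, "superkingdom")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("lineage table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$taxid <- as.integer(df$taxid)
  if (anyDuplicated(df$taxid)) stop("duplicate taxid in lineage table", call. = FALSE)
  df
}

#' Write a taxonomic lineage table
#' @param lineages A lineage tibble (see [read_lineages()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  write_tsv_canonical(lineages, path)
}

#' Read an ECOD-style hierarchy table
#'
#' One row per node: `id`, `level` (one of A/X/H/T/F), `parent` (empty
#' for A nodes), `pfam_list` (comma-separated Pfam accessions for F
#' nodes; empty for a '.0' pseudo group and for non-F nodes). Parent
#' links are checked level by level: F under T under H under X under A.
#'
#' @param path Path to the TSV file.
#' @return A tibble of hierarchy nodes.
#' @export
read_hierarchy <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("id", "level", "parent", "pfam_list")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("hierarchy table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_hierarchy(df)
  df
}

#' Write an ECOD-style hierarchy table
#' @param hierarchy A hierarchy tibble (see [read_hierarchy()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  validate_hierarchy(hierarchy)
  write_tsv_canonical(hierarchy, path)
}

validate_hierarchy <- function(df) {
  if (anyDuplicated(df$id)) stop("duplicate node id in hierarchy", call. = FALSE)
  lev <- c(A = "", X = "A", H = "X", T = "H", F = "T")
  bad_level <- setdiff(unique(df$level), names(lev))
  if (length(bad_level)) {
    stop("unknown hierarchy level: ", paste(bad_level, collapse = ", "),
         call. = FALSE)
  }
  level_of <- setNames(df$level, df$id)
  for (l in c("X", "H", "T", "F")) {
    rows <- df[df$level == l, ]
    ok <- rows$parent %in% df$id & level_of[rows$parent] == lev[[l]]
    if (!all(ok)) {
      stop(sprintf("%s-node without %s parent: %s", l, lev[[l]],
                   paste(head(rows$id[!ok], 5), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a Pfam-to-F-group correspondence table
#'
#' TSV with columns `fgroup_id`, `tgroup_id`, `pfam_list`
#' (comma-separated Pfam accessions; one accession for a simple family,
#' several for a composite). The pfam set is canonicalised (sorted,
#' de-duplicated) on read.
#'
#' @param path Path to the TSV file.
#' @return A tibble with an added canonical `pfam_key` column.
#' @export
read_correspondence <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("fgroup_id", "tgroup_id", "pfam_list")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("correspondence table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$pfam_key <- pfam_set_key(df$pfam_list)
  if (anyDuplicated(df[, c("tgroup_id", "pfam_key")])) {
    stop("duplicate (tgroup, pfam set) in correspondence table", call. = FALSE)
  }
  df
}

#' Write a Pfam-to-F-group correspondence table
#' @param corr A correspondence tibble (see [read_correspondence()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_correspondence <- function(corr, path) {
  write_tsv_canonical(corr[, c("fgroup_id", "tgroup_id", "pfam_list")], path)
}

# Canonical key for a Pfam accession set: sorted, unique, comma-joined.
pfam_set_key <- function(pfam_list) {
  vapply(strsplit(pfam_list, ",", fixed = TRUE), function(v) {
    v <- sort(unique(trimws(v[nzchar(trimws(v))])))
    paste(v, collapse = ",")
  }, character(1))
}

#' Read domain sequences from FASTA
#' @param path FASTA path; record ids are domain ids.
#' @return A named character vector of amino-acid sequences.
#' @export
read_domain_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Write domain sequences to FASTA
#' @param seqs Named character vector of sequences (names = domain ids).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_domain_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60)
  invisible(path)
}

# -- shared TSV plumbing -----------------------------------------------------

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as_tibble(read.delim(path, sep = "\t", header = TRUE,
                       colClasses = "character", check.names = FALSE,
                       na.strings = NULL, quote = ""))
}

# Canonical TSV writer: tab-separated, no quoting, "\n" line endings,
# numbers via format() with 15 significant digits so write -> read -> write
# is byte-stable.
write_tsv_canonical <- function(df, path) {
  df <- as.data.frame(df)
  for (i in seq_along(df)) {
    if (is.numeric(df[[i]])) {
      df[[i]] <- vapply(df[[i]], function(x) {
        format(x, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
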