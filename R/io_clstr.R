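#' Cluster sets
#'
#' A `cluster_set` stores the memberships of one sequence-identity
#' clustering: the identity threshold, and one row per member with its
#' cluster index (0-based, as in CD-HIT output), amino-acid length,
#' representative flag, and identity to the representative (`NA` for the
#' representative itself).
#'
#' @param members A tibble with columns `member_id`, `cluster`, `aa`,
#'   `is_rep`, `identity`.
#' @param threshold Identity threshold in (0, 1].
#' @return An object of class `cluster_set`.
#' @export
cluster_set <- function(members, threshold = NA_real_) {
  members <- as_tibble(members)
  need <- c("member_id", "cluster", "aa", "is_rep", "identity")
  missing <- setdiff(need, names(members))
  if (length(missing)) {
    stop("cluster members lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(members$member_id)) {
    dup <- members$member_id[duplicated(members$member_id)][1]
    stop("member '", dup, "' appears in more than one cluster", call. = FALSE)
  }
  if (nrow(members)) {
    reps <- members %>% group_by(.data$cluster) %>%
      summarise(n_rep = sum(.data$is_rep), .groups = "drop")
    if (any(reps$n_rep != 1L)) {
      stop("cluster without exactly one representative: cluster ",
           reps$cluster[reps$n_rep != 1L][1], call. = FALSE)
    }
  }
  structure(list(threshold = threshold, members = members),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d members in %d clusters (threshold %s)\n",
              nrow(x$members), n_distinct(x$members$cluster),
              if (is.na(x$threshold)) "?" else format(x$threshold)))
  invisible(x)
}

#' Cluster sizes of a cluster set
#' @param cs A `cluster_set`.
#' @return A tibble with columns `cluster`, `size`.
#' @export
cluster_sizes <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cs$members %>% count(.data$cluster, name = "size")
}

#' Read a CD-HIT `.clstr` file
#'
#' Parses the CD-HIT cluster dialect: `>Cluster n` headers followed by
#' member lines such as `0\t123aa, >dom00017... *` (representative) or
#' `1\t120aa, >dom00018... at 98.33%`. FASTA decoration is stripped from
#' member ids.
#'
#' @param path Path to the `.clstr` file.
#' @param threshold Optional identity threshold to record on the set.
#' @return A [cluster_set()].
#' @export
read_clstr <- function(path, threshold = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(cluster_set(tibble(member_id = character(), cluster = integer(),
                              aa = integer(), is_rep = logical(),
                              identity = numeric()), threshold))
  }
  is_hdr <- startsWith(lines, ">Cluster")
  if (!is_hdr[1]) stop("clstr file does not start with a cluster header", call. = FALSE)
  cluster <- cumsum(is_hdr) - 1L
  hdr_n <- as.integer(sub("^>Cluster\\s+", "", lines[is_hdr]))
  cl_id <- hdr_n[cluster + 1L]
  mem_lines <- lines[!is_hdr]
  mem_cl <- cl_id[!is_hdr]
  m <- regmatches(mem_lines,
                  regexec("^[0-9]+\t([0-9]+)aa, >(.*)\\.\\.\\. (\\*|at ([0-9.]+)%)$",
                          mem_lines))
  bad <- which(lengths(m) == 0L)
  if (length(bad)) {
    stop("malformed clstr member line: ", mem_lines[bad[1]], call. = FALSE)
  }
  members <- tibble(
    member_id = vapply(m, `[`, character(1), 3),
    cluster = mem_cl,
    aa = as.integer(vapply(m, `[`, character(1), 2)),
    is_rep = vapply(m, `[`, character(1), 4) == "*",
    identity = vapply(m, function(x) {
      if (x[4] == "*") NA_real_ else as.numeric(x[5]) / 100
    }, numeric(1))
  )
  cluster_set(members, threshold)
}

#' Write a cluster set in CD-HIT `.clstr` dialect
#' @param cs A [cluster_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(cs, path) {
  stopifnot(inherits(cs, "cluster_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (cl in unique(cs$members$cluster)) {
    writeLines(sprintf(">Cluster %d", cl), con, sep = "\n")
    rows <- cs$members[cs$members$cluster == cl, ]
    tail_txt <- ifelse(rows$is_rep, "*",
                       sprintf("at %.2f%%", 100 * rows$identity))
    writeLines(sprintf("%d\t%daa, >%s... %s",
                       seq_len(nrow(rows)) - 1L, rows$aa, rows$member_id,
                       tail_txt), con, sep = "\n")
  }
  invisible(path)
}
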