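#' Greedy incremental sequence-identity clustering
#'
#' A transparent stand-in for CD-HIT-style clustering at small scale:
#' sequences are sorted longest-first (ties by id, ascending) and each
#' sequence joins the first existing cluster whose representative it
#' matches at or above the identity threshold, otherwise it founds a new
#' cluster with itself as representative. Identity is matches divided by
#' the number of alignment columns of a global alignment with affine
#' gaps (BLOSUM62, gap open 10, extend 1). The procedure is
#' deterministic for a fixed input; no claim of cluster-for-cluster
#' equivalence with CD-HIT (whose word-filter heuristics and identity
#' definition differ) is made -- large runs should import real CD-HIT
#' `.clstr` files via [read_clstr()].
#'
#' @param seqs Named character vector of amino-acid sequences
#'   (names = domain ids), or an `AAStringSet`.
#' @param threshold Identity threshold in (0, 1].
#' @return A [cluster_set()]; clusters are numbered in founding order.
#' @export
greedy_cluster <- function(seqs, threshold) {
  if (inherits(seqs, "AAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (!length(seqs)) stop("no sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || !all(nzchar(names(seqs)))) {
    stop("sequences must be named by domain id", call. = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs))) {
    stop("non-amino-acid characters in sequence", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1)
  o <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[o]
  lens <- nchar(seqs)
  n <- length(seqs)
  rep_idx <- integer(0)      # indices (into seqs) of representatives
  assign_cl <- integer(n)    # cluster index per sequence (founding order)
  ident <- rep(NA_real_, n)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(rep_idx)) {
      # identity <= min(len)/max(len): skip representatives that cannot reach
      # the threshold on length grounds alone
      cand <- rep_idx[pmin(lens[rep_idx], lens[i]) /
                        pmax(lens[rep_idx], lens[i]) >= threshold]
      if (length(cand)) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(seqs[cand]), Biostrings::AAString(seqs[[i]]),
          substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
          type = "global")
        npair <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
        id <- Biostrings::nmatch(aln) / (lens[cand] + lens[i] - npair)
        ok <- which(id >= threshold)
        if (length(ok)) {
          pick <- ok[1]  # first founded cluster among the candidates
          hit <- match(cand[pick], rep_idx)
          ident[i] <- id[pick]
        }
      }
    }
    if (hit) {
      assign_cl[i] <- hit
    } else {
      rep_idx <- c(rep_idx, i)
      assign_cl[i] <- length(rep_idx)
    }
  }
  members <- tibble(
    member_id = names(seqs),
    cluster = assign_cl - 1L,
    aa = lens,
    is_rep = seq_len(n) %in% rep_idx,
    identity = ident
  ) %>% arrange(.data$cluster, !.data$is_rep, .data$member_id)
  cluster_set(members, threshold)
}

#' Pairwise global-alignment identity
#'
#' Matches divided by alignment columns (including gap columns) of a
#' global alignment with affine gaps (BLOSUM62, open 10, extend 1) --
#' the identity definition used by [greedy_cluster()].
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @return Identity fraction in \[0,1\].
#' @export
pairwise_identity <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
    type = "global")
  npair <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  Biostrings::nmatch(aln) / (nchar(a) + nchar(b) - npair)
}

#' Summary statistics of a cluster set
#'
#' @param cs A [cluster_set()].
#' @return A one-row tibble: `threshold`, `n_domains`, `n_clusters`,
#'   `n_singletons`, `singleton_cluster_fraction` (singletons as a
#'   fraction of clusters), `singleton_domain_fraction` (singleton
#'   members as a fraction of all domains), `max_cluster_size`,
#'   `mean_cluster_size`.
#' @export
cluster_stats <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!nrow(cs$members)) stop("empty cluster set", call. = FALSE)
  sizes <- cluster_sizes(cs)$size
  tibble(
    threshold = cs$threshold,
    n_domains = sum(sizes),
    n_clusters = length(sizes),
    n_singletons = sum(sizes == 1L),
    singleton_cluster_fraction = sum(sizes == 1L) / length(sizes),
    singleton_domain_fraction = sum(sizes == 1L) / sum(sizes),
    max_cluster_size = max(sizes),
    mean_cluster_size = mean(sizes)
  )
}

#' Singleton ids of a cluster set
#' @param cs A [cluster_set()].
#' @return Character vector of member ids that form size-1 clusters.
#' @export
singleton_ids <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  sz <- cluster_sizes(cs)
  cs$members %>%
    semi_join(sz[sz$size == 1L, "cluster"], by = "cluster") %>%
    pull("member_id")
}

#' Cross-threshold singleton consistency
#'
#' Fraction of singletons of the coarse set (lower identity threshold,
#' e.g. 40%) that are also singletons in the fine set (higher threshold,
#' e.g. 70%). Genuinely unique sequences stay singletons as the
#' threshold rises; borderline threshold cases do not.
#'
#' @param fine,coarse [cluster_set()]s over the same domain universe;
#'   `coarse` has the lower threshold.
#' @param restrict_to Optional character vector of domain ids (e.g. the
#'   well-assigned subset) to which coarse singletons are restricted
#'   before the ratio is taken.
#' @return A list with `fraction`, `n` (numerator) and `d`
#'   (denominator).
#' @export
singleton_consistency <- function(fine, coarse, restrict_to = NULL) {
  u_fine <- fine$members$member_id
  u_coarse <- coarse$members$member_id
  only <- c(setdiff(u_fine, u_coarse), setdiff(u_coarse, u_fine))
  if (length(only)) {
    stop("domains present in one cluster set only: ",
         paste(head(only, 5), collapse = ", "), call. = FALSE)
  }
  s_coarse <- singleton_ids(coarse)
  if (!is.null(restrict_to)) s_coarse <- intersect(s_coarse, restrict_to)
  if (!length(s_coarse)) stop("empty denominator: no coarse singletons", call. = FALSE)
  s_fine <- singleton_ids(fine)
  n <- sum(s_coarse %in% s_fine)
  list(fraction = n / length(s_coarse), n = n, d = length(s_coarse))
}
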