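#' Judge thresholds
#'
#' Cutoffs for the post-assignment quality ("judge") categorization of
#' parsed domains. `prob_high` separates high-confidence from uncertain
#' assignments (default 0.85; good domains dominate above this
#' assignment probability). `cov_good` separates good from partial
#' coverage of the reference domain (default 0.70, the conventional
#' domain-coverage cutoff). A domain needs at least `min_sse`
#' secondary-structure elements to escape the `simple_topology` class;
#' an SSE is a maximal helix run (states H/G/I) of length >=
#' `min_helix_len` or strand run (E/B) of length >= `min_strand_len`.
#'
#' @param prob_high Assignment-probability cutoff in \[0,1\].
#' @param cov_good Reference-coverage cutoff in \[0,1\].
#' @param min_sse Minimum SSE count for a non-trivial topology.
#' @param min_helix_len,min_strand_len Minimum run lengths.
#' @return A list of class `judge_thresholds`.
#' @export
judge_thresholds <- function(prob_high = 0.85, cov_good = 0.70, min_sse = 3L,
                             min_helix_len = 3L, min_strand_len = 2L) {
  stopifnot(prob_high >= 0, prob_high <= 1, cov_good >= 0, cov_good <= 1,
            min_sse >= 1, min_helix_len >= 1, min_strand_len >= 1)
  structure(list(prob_high = prob_high, cov_good = cov_good,
                 min_sse = as.integer(min_sse),
                 min_helix_len = as.integer(min_helix_len),
                 min_strand_len = as.integer(min_strand_len)),
            class = "judge_thresholds")
}

JUDGE_LEVELS <- c("good_domain", "partial_domain", "low_confidence",
                  "simple_topology")

SS_HELIX <- c("H", "G", "I")
SS_STRAND <- c("E", "B")
SS_COIL <- c("T", "S", "C", "-", " ")

#' Count secondary-structure elements in a DSSP-style state string
#'
#' Helix states H/G/I and strand states E/B are each collapsed to one
#' class; an element is a maximal run of one class meeting the minimum
#' run length (helix >= `min_helix_len`, strand >= `min_strand_len`).
#' All other 8-state characters (T, S, C) plus `-` and space are coil.
#'
#' @param ss_string Character vector of per-residue state strings.
#' @param thresholds A [judge_thresholds()].
#' @return Integer vector of SSE counts.
#' @export
count_sse <- function(ss_string, thresholds = judge_thresholds()) {
  vapply(ss_string, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty ss_string", call. = FALSE)
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(chars, c(SS_HELIX, SS_STRAND, SS_COIL))
    if (length(bad)) {
      stop("unknown secondary-structure state '", bad[1], "'", call. = FALSE)
    }
    cls <- ifelse(chars %in% SS_HELIX, "H",
                  ifelse(chars %in% SS_STRAND, "E", "C"))
    r <- rle(cls)
    sum((r$values == "H" & r$lengths >= thresholds$min_helix_len) |
          (r$values == "E" & r$lengths >= thresholds$min_strand_len))
  }, integer(1), USE.NAMES = FALSE)
}

#' Categorize domains into the four judge classes
#'
#' `simple_topology` iff the SSE count is below `min_sse`, regardless of
#' assignment probability or coverage. Otherwise: `good_domain` iff
#' probability >= `prob_high` and coverage >= `cov_good`;
#' `partial_domain` iff probability >= `prob_high` with coverage below
#' `cov_good`; `low_confidence` otherwise. Domains with an empty
#' `ss_string` cannot be judged and are dropped with a warning.
#'
#' @param domains A domain tibble (see [read_domains()]).
#' @param thresholds A [judge_thresholds()].
#' @return The domain tibble with added columns `sse_count`, `judge`
#'   (factor over the four classes), `continuity` and `nres`.
#' @export
judge_domains <- function(domains, thresholds = judge_thresholds()) {
  no_ss <- is.na(domains$ss_string) | !nzchar(domains$ss_string)
  if (any(no_ss)) {
    warning(sum(no_ss), " domain(s) lack an ss_string and were excluded")
    domains <- domains[!no_ss, ]
  }
  sse <- count_sse(domains$ss_string, thresholds)
  judge <- ifelse(
    sse < thresholds$min_sse, "simple_topology",
    ifelse(domains$dpam_prob >= thresholds$prob_high,
           ifelse(domains$ref_coverage >= thresholds$cov_good,
                  "good_domain", "partial_domain"),
           "low_confidence"))
  nseg <- ranges_nseg(domains$range)
  domains %>%
    mutate(sse_count = sse,
           judge = factor(judge, levels = JUDGE_LEVELS),
           continuity = ifelse(nseg == 1L, "continuous", "discontinuous"),
           nres = ranges_nres(domains$range))
}

#' Continuity class of a segmented range
#' @param r A [seg_range()].
#' @return A list with `label` (`"continuous"` or `"discontinuous"`) and
#'   `residue_count`.
#' @export
continuity_class <- function(r) {
  list(label = if (n_segments(r) == 1L) "continuous" else "discontinuous",
       residue_count = residue_count(r))
}

#' Summarise judge categories and continuity
#'
#' @param judged Output of [judge_domains()].
#' @return A list with `by_category` (per-class domain counts/fractions
#'   and residue counts/fractions) and `continuity` (fractions by count
#'   and by residues).
#' @export
judge_summary <- function(judged) {
  if (!nrow(judged)) stop("no judged domains", call. = FALSE)
  total_res <- sum(judged$nres)
  by_cat <- judged %>%
    group_by(judge = .data$judge, .drop = FALSE) %>%
    summarise(n_domains = n(), n_residues = sum(.data$nres), .groups = "drop") %>%
    mutate(domain_fraction = .data$n_domains / sum(.data$n_domains),
           residue_fraction = .data$n_residues / total_res)
  cont <- judged %>%
    group_by(continuity = .data$continuity) %>%
    summarise(n_domains = n(), n_residues = sum(.data$nres), .groups = "drop") %>%
    mutate(domain_fraction = .data$n_domains / sum(.data$n_domains),
           residue_fraction = .data$n_residues / total_res)
  list(by_category = by_cat, continuity = cont)
}
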