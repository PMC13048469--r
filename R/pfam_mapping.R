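#' Mapping confidence rules
#'
#' Tier cutoffs for per-domain Pfam mapping confidence. A mapping is
#' `high` when model coverage >= 0.80 and bit score strictly > 50 (the
#' boundary bit score 50 is not high). The lower tiers are package
#' defaults: `medium` at coverage >= 0.60 and bits > 35, `low` at
#' coverage >= 0.40 and bits > 20, `uncertain` otherwise. Tiers are
#' evaluated in order high, medium, low; the first match wins, so they
#' partition all mappings.
#'
#' @param high,medium,low Each a list with elements `cov` (minimum
#'   coverage, inclusive) and `bits` (bit score, exclusive).
#' @return A list of class `confidence_rules`.
#' @export
confidence_rules <- function(high = list(cov = 0.80, bits = 50),
                             medium = list(cov = 0.60, bits = 35),
                             low = list(cov = 0.40, bits = 20)) {
  structure(list(high = high, medium = medium, low = low),
            class = "confidence_rules")
}

TIER_LEVELS <- c("high", "medium", "low", "uncertain")

#' Keep hits passing the Pfam gathering threshold
#' @param hits Hit tibble (see [read_domtblout()]).
#' @return The GA-passing subset, order preserved.
#' @export
filter_hits_ga <- function(hits) {
  hits[hits$passes_ga, ]
}

#' Best series of non-overlapping hits
#'
#' Selects the subset of hits, pairwise non-overlapping on the query
#' envelope (two hits may share at most `overlap_tolerance` residues),
#' that maximises the summed bit score. Solved exactly by weighted
#' interval scheduling over the envelope intervals; ties are broken
#' toward fewer hits, then the lexicographically smallest sorted Pfam
#' accession list.
#'
#' @param hits GA-filtered hit tibble for one query domain.
#' @param overlap_tolerance Residues two chosen envelopes may share.
#' @return The chosen subset of `hits`, sorted by `env_from`.
#' @export
select_nonoverlapping <- function(hits, overlap_tolerance = 0L) {
  if (overlap_tolerance < 0) stop("negative overlap tolerance", call. = FALSE)
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  if (n_distinct(hits$query_domain_id) > 1L) {
    stop("hits from more than one query domain", call. = FALSE)
  }
  o <- order(hits$env_to, hits$env_from)
  h <- hits[o, ]
  # key(sel): list(bits, nhits, acc_key) -- prefer higher bits, then fewer
  # hits, then lexicographically smaller sorted accession string
  sol_key <- function(idx) {
    list(bits = sum(h$bit_score[idx]), nhits = length(idx),
         accs = paste(sort(h$pfam_acc[idx]), collapse = ","))
  }
  better <- function(a, b) {
    if (abs(a$bits - b$bits) > 1e-9) return(a$bits > b$bits)
    if (a$nhits != b$nhits) return(a$nhits < b$nhits)
    a$accs < b$accs
  }
  # best[[i]]: optimal selection among h[1..i]
  best <- vector("list", n + 1L)
  best[[1L]] <- integer(0)
  for (i in seq_len(n)) {
    # last j (by end order) compatible with i: overlap <= tolerance
    p <- 0L
    for (j in seq_len(i - 1L)) {
      if (h$env_to[j] - h$env_from[i] + 1L <= overlap_tolerance) p <- j
    }
    with_i <- c(best[[p + 1L]], i)
    without_i <- best[[i]]
    best[[i + 1L]] <- if (better(sol_key(with_i), sol_key(without_i)))
      with_i else without_i
  }
  chosen <- h[sort(best[[n + 1L]]), ]
  chosen[order(chosen$env_from), ]
}

#' Confidence tier of one mapping
#' @param coverage Model coverage fraction in \[0,1\].
#' @param bit_score Bit score.
#' @param rules A [confidence_rules()].
#' @return One of `"high"`, `"medium"`, `"low"`, `"uncertain"`.
#' @export
mapping_confidence <- function(coverage, bit_score, rules = confidence_rules()) {
  stopifnot(coverage >= 0, coverage <= 1)
  for (tier in c("high", "medium", "low")) {
    r <- rules[[tier]]
    if (coverage >= r$cov && bit_score > r$bits) return(tier)
  }
  "uncertain"
}

#' Map domains to Pfam from HMM hits
#'
#' GA-filters the hits, selects the best series of non-overlapping hits
#' per domain, and assigns a confidence tier. Coverage is model
#' coverage, `(hmm_to - hmm_from + 1) / model_len`. The tier uses the
#' best single chosen hit per Pfam family; a composite mapping (several
#' families) is tiered by its weakest family, conservatively.
#'
#' @param hits Hit tibble (any number of query domains).
#' @param domain_ids Optional character vector of all domain ids; ids
#'   without any GA-passing hit appear in the result as unmapped rows.
#' @param rules A [confidence_rules()].
#' @param overlap_tolerance Passed to [select_nonoverlapping()].
#' @return A tibble with one row per domain: `domain_id`, `mapped`,
#'   `pfam_accs` (comma-joined sorted set), `n_hits`, `total_bits`,
#'   `min_coverage`, `tier`.
#' @export
map_domains <- function(hits, domain_ids = NULL, rules = confidence_rules(),
                        overlap_tolerance = 0L) {
  ga <- filter_hits_ga(hits)
  mapped <- if (nrow(ga)) {
    ga %>%
      group_by(domain_id = .data$query_domain_id) %>%
      group_modify(function(g, key) {
        g$query_domain_id <- key$domain_id
        chosen <- select_nonoverlapping(g, overlap_tolerance)
        chosen$coverage <- (chosen$hmm_to - chosen$hmm_from + 1) / chosen$model_len
        per_fam <- chosen %>%
          group_by(.data$pfam_acc) %>%
          slice(which.max(.data$bit_score)) %>%
          ungroup()
        tiers <- mapply(mapping_confidence, per_fam$coverage,
                        per_fam$bit_score, MoreArgs = list(rules = rules))
        tibble(mapped = TRUE,
               pfam_accs = paste(sort(unique(chosen$pfam_acc)), collapse = ","),
               n_hits = nrow(chosen),
               total_bits = sum(chosen$bit_score),
               min_coverage = min(per_fam$coverage),
               tier = TIER_LEVELS[max(match(tiers, TIER_LEVELS))])
      }) %>%
      ungroup()
  } else {
    tibble(domain_id = character(), mapped = logical(), pfam_accs = character(),
           n_hits = integer(), total_bits = numeric(), min_coverage = numeric(),
           tier = character())
  }
  if (!is.null(domain_ids)) {
    missing <- setdiff(domain_ids, mapped$domain_id)
    if (length(missing)) {
      mapped <- bind_rows(mapped, tibble(
        domain_id = missing, mapped = FALSE, pfam_accs = "", n_hits = 0L,
        total_bits = 0, min_coverage = NA_real_, tier = NA_character_))
    }
    mapped <- mapped[match(domain_ids, mapped$domain_id), ]
  }
  mapped
}

#' Assign a Pfam accession set to an F-group under a T-group
#'
#' Looks the set up in the Pfam-to-F-group correspondence restricted to
#' the domain's T-group. An exact set match returns the existing
#' F-group; an unseen singleton set proposes a new simple family, an
#' unseen multi-accession set a new composite family; an empty set is a
#' T-group-only ('.0' pseudo group) placement.
#'
#' @param pfam_accs Character vector (or comma-joined string) of Pfam
#'   accessions; may be empty.
#' @param correspondence Correspondence tibble (see
#'   [read_correspondence()]).
#' @param hierarchy Hierarchy tibble (see [read_hierarchy()]).
#' @param tgroup_id The domain's T-group id.
#' @return A list with `status` (one of `"existing"`, `"new_simple"`,
#'   `"new_composite"`, `"tgroup_only"`), `fgroup_id` (for existing) and
#'   `pfam_key`.
#' @export
assign_fgroup <- function(pfam_accs, correspondence, hierarchy, tgroup_id) {
  if (!tgroup_id %in% hierarchy$id[hierarchy$level == "T"]) {
    stop("T-group '", tgroup_id, "' absent from hierarchy", call. = FALSE)
  }
  if (length(pfam_accs) == 1L && grepl(",", pfam_accs)) {
    pfam_accs <- strsplit(pfam_accs, ",", fixed = TRUE)[[1]]
  }
  pfam_accs <- sort(unique(pfam_accs[nzchar(pfam_accs)]))
  key <- paste(pfam_accs, collapse = ",")
  if (!length(pfam_accs)) {
    return(list(status = "tgroup_only", fgroup_id = NA_character_, pfam_key = key))
  }
  rows <- correspondence[correspondence$tgroup_id == tgroup_id &
                           correspondence$pfam_key == key, ]
  if (nrow(rows) == 1L) {
    return(list(status = "existing", fgroup_id = rows$fgroup_id, pfam_key = key))
  }
  if (nrow(rows) > 1L) {
    stop("duplicate F-group Pfam set under T-group ", tgroup_id, call. = FALSE)
  }
  list(status = if (length(pfam_accs) == 1L) "new_simple" else "new_composite",
       fgroup_id = NA_character_, pfam_key = key)
}

#' Pfam mapping rates by judge category
#'
#' @param mappings Output of [map_domains()].
#' @param judged Output of [judge_domains()].
#' @return A tibble with one row per judge category present in the
#'   data: `judge`, `n` (denominator), `n_mapped`, `mapped_fraction`.
#'   Domains present in only one input are an error.
#' @export
mapping_rates <- function(mappings, judged) {
  only <- c(setdiff(judged$domain_id, mappings$domain_id),
            setdiff(mappings$domain_id, judged$domain_id))
  if (length(only)) {
    stop("unjoined domain ids: ", paste(head(only, 5), collapse = ", "),
         call. = FALSE)
  }
  judged %>%
    select("domain_id", "judge") %>%
    inner_join(mappings %>% select("domain_id", "mapped"), by = "domain_id") %>%
    group_by(judge = .data$judge) %>%
    summarise(n = n(), n_mapped = sum(.data$mapped),
              mapped_fraction = sum(.data$mapped) / n(), .groups = "drop")
}
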