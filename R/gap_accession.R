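GAP_LEVELS <- c("sensitivity_gap", "underspecified_subgroup",
                "unrepresented_tgroup")

#' Classify the Pfam mapping gap for unmapped well-assigned domains
#'
#' Each unmapped `good_domain` is classified by how its T-group relates
#' to Pfam: `unrepresented_tgroup` when no domain of the T-group maps to
#' Pfam at all; `sensitivity_gap` when the domain's ECOD structural
#' reference (`hit_ecod_domain_id`) is also hit by Pfam-mapped siblings
#' in the T-group (an appropriate family exists but does not detect this
#' sequence); `underspecified_subgroup` when its reference is used by no
#' Pfam-mapped sibling (a structurally resolved sub-group without a
#' sequence family).
#'
#' @param judged Output of [judge_domains()].
#' @param mappings Output of [map_domains()].
#' @return A tibble with one row per unmapped good domain: `domain_id`,
#'   `tgroup_id`, `hit_ecod_domain_id`, `gap_class`.
#' @export
classify_unmapped <- function(judged, mappings) {
  dat <- judged %>%
    inner_join(mappings %>% select("domain_id", "mapped"), by = "domain_id")
  good <- dat[dat$judge == "good_domain", ]
  un <- good[!good$mapped, ]
  if (!nrow(un)) {
    return(tibble(domain_id = character(), tgroup_id = character(),
                  hit_ecod_domain_id = character(),
                  gap_class = factor(character(), levels = GAP_LEVELS)))
  }
  no_ref <- is.na(un$hit_ecod_domain_id) | !nzchar(un$hit_ecod_domain_id)
  if (any(no_ref)) {
    stop("unmapped good domain(s) without hit_ecod_domain_id: ",
         paste(head(un$domain_id[no_ref], 5), collapse = ", "), call. = FALSE)
  }
  mapped_sibs <- dat[dat$mapped, c("tgroup_id", "hit_ecod_domain_id")]
  tg_mapped <- unique(mapped_sibs$tgroup_id)
  ref_key <- paste(mapped_sibs$tgroup_id, mapped_sibs$hit_ecod_domain_id)
  cls <- ifelse(
    !(un$tgroup_id %in% tg_mapped), "unrepresented_tgroup",
    ifelse(paste(un$tgroup_id, un$hit_ecod_domain_id) %in% ref_key,
           "sensitivity_gap", "underspecified_subgroup"))
  tibble(domain_id = un$domain_id, tgroup_id = un$tgroup_id,
         hit_ecod_domain_id = un$hit_ecod_domain_id,
         gap_class = factor(cls, levels = GAP_LEVELS))
}

#' Temporal capture of an unmapped domain across Pfam releases
#'
#' Given GA-filtered hit tables from several Pfam releases, finds for
#' each domain the first release (in version order) with at least one
#' GA-passing hit, and classifies the capture: `new_family` when every
#' capturing family has a numeric accession at or above
#' `new_family_floor` (families created after the release that the
#' floor marks), `improved_model` otherwise.
#'
#' @param hits Hit tibble carrying a `release` column (concatenate the
#'   per-release [read_domtblout()] outputs).
#' @param domain_ids Domain ids to report (captured or not).
#' @param new_family_floor Numeric accession floor; default 25159, i.e.
#'   PF25159 and above are new families.
#' @return A tibble: `domain_id`, `first_release` (`NA` when never
#'   captured), `captured_by` (`"new_family"`, `"improved_model"` or
#'   `"none"`).
#' @export
temporal_capture <- function(hits, domain_ids, new_family_floor = 25159L) {
  rel <- unique(hits$release)
  ord <- tryCatch(order(numeric_version(rel)), error = function(e) {
    stop("unordered release tags: ", paste(rel, collapse = ", "), call. = FALSE)
  })
  rel_sorted <- rel[ord]
  ga <- filter_hits_ga(hits)
  ga$rel_rank <- match(ga$release, rel_sorted)
  res <- lapply(domain_ids, function(d) {
    h <- ga[ga$query_domain_id == d, ]
    if (!nrow(h)) {
      return(tibble(domain_id = d, first_release = NA_character_,
                    captured_by = "none"))
    }
    first <- min(h$rel_rank)
    capt <- h[h$rel_rank == first, ]
    accnum <- as.integer(sub("^PF", "", capt$pfam_acc))
    tibble(domain_id = d, first_release = rel_sorted[first],
           captured_by = if (all(accnum >= new_family_floor))
             "new_family" else "improved_model")
  })
  bind_rows(res)
}

#' Flag candidate clusters for novel Pfam family designation
#'
#' Large, taxonomically broad clusters made entirely of unmapped
#' domains are prime candidates for new sequence families: the flag
#' requires size strictly greater than `min_size` (default 100) and at
#' least `min_phyla` distinct resolved phyla (default 15).
#'
#' @param cs A [cluster_set()].
#' @param tax_metrics Output of [cluster_tax_metrics()] on `cs`.
#' @param mappings Output of [map_domains()] covering the members.
#' @param min_size Cluster size lower bound (exclusive).
#' @param min_phyla Distinct-phyla lower bound (inclusive).
#' @return A tibble of flagged clusters: `cluster`, `n_members`,
#'   `n_phyla`, `diversity_score`.
#' @export
flag_novel_family_candidates <- function(cs, tax_metrics, mappings,
                                         min_size = 100L, min_phyla = 15L) {
  mapped_flag <- setNames(mappings$mapped, mappings$domain_id)
  per <- tax_metrics$per_cluster
  all_unmapped <- cs$members %>%
    group_by(cluster = .data$cluster) %>%
    summarise(all_unmapped = all(!mapped_flag[.data$member_id]),
              .groups = "drop")
  per %>%
    inner_join(all_unmapped, by = "cluster") %>%
    filter(.data$all_unmapped, .data$n_members > min_size,
           .data$n_phyla >= min_phyla) %>%
    select("cluster", "n_members", "n_phyla", "diversity_score")
}

#' Defer new domains overlapping existing classified domains
#'
#' A new domain is deferred when an already-classified domain on the
#' same protein shares at least `min_overlap` of the shorter domain's
#' residues. Diagnostics record, for each deferred domain, whether its
#' T-group matches the best-overlapping existing domain, whether the
#' ranges are exactly identical, and whether they are identical within
#' a two-residue boundary jitter.
#'
#' @param new_domains Domain tibble of candidates (needs `domain_id`,
#'   `protein_acc`, `range`, `tgroup_id`).
#' @param existing Tibble of classified domains (`protein_acc`, `range`,
#'   `tgroup_id`).
#' @param min_overlap Shared residues / min(length) cutoff (inclusive).
#' @return A list with `retained` (domain ids), `deferred` (tibble:
#'   `domain_id`, `overlap`, `same_tgroup`, `identical_range`,
#'   `near_identical_range`).
#' @export
defer_overlaps <- function(new_domains, existing, min_overlap = 0.5) {
  ex_ranges <- ranges_parse(existing$range)
  ex_by_prot <- split(seq_len(nrow(existing)), existing$protein_acc)
  new_ranges <- ranges_parse(new_domains$range)
  rows <- lapply(seq_len(nrow(new_domains)), function(i) {
    idx <- ex_by_prot[[new_domains$protein_acc[i]]]
    if (is.null(idx)) return(NULL)
    r <- new_ranges[[i]]
    ov <- vapply(idx, function(j) {
      range_overlap(r, ex_ranges[[j]]) /
        min(residue_count(r), residue_count(ex_ranges[[j]]))
    }, numeric(1))
    best <- which.max(ov)
    if (ov[best] < min_overlap) return(NULL)
    j <- idx[best]
    tibble(domain_id = new_domains$domain_id[i], overlap = ov[best],
           same_tgroup = identical(new_domains$tgroup_id[i], existing$tgroup_id[j]),
           identical_range = range_near_identical(r, ex_ranges[[j]], 0L),
           near_identical_range = range_near_identical(r, ex_ranges[[j]], 2L))
  })
  deferred <- bind_rows(rows)
  if (!nrow(deferred)) {
    deferred <- tibble(domain_id = character(), overlap = numeric(),
                       same_tgroup = logical(), identical_range = logical(),
                       near_identical_range = logical())
  }
  list(retained = setdiff(new_domains$domain_id, deferred$domain_id),
       deferred = deferred)
}

#' Overlap-aware accession of candidate domains into the hierarchy
#'
#' Runs the accession pipeline: restrict to well-assigned
#' (`good_domain`) domains; defer those overlapping existing classified
#' domains ([defer_overlaps()]); assign every retained domain an
#' F-group under its T-group ([assign_fgroup()]); aggregate unseen Pfam
#' sets into newly created F-groups (one per distinct (T-group, Pfam
#' set), simple or composite by set size) and promote as representative
#' the member with the highest assignment probability (ties: higher
#' mean pLDDT, then smaller domain id); place retained unmapped domains
#' at the T-group level only ('.0'). Statuses partition the input:
#' non-good domains are `rejected`, overlapping good domains
#' `deferred`, the rest `accessioned`.
#'
#' @param judged Output of [judge_domains()].
#' @param mappings Output of [map_domains()].
#' @param hierarchy Hierarchy tibble (see [read_hierarchy()]).
#' @param correspondence Correspondence tibble (see
#'   [read_correspondence()]).
#' @param existing Existing classified domains (see [defer_overlaps()]).
#' @param min_overlap Deferral cutoff, shared / min(length).
#' @return A list: `status` (tibble `domain_id`, `status`, `fgroup_status`,
#'   `fgroup_id`, `pfam_key`), `new_fgroups` (tibble `fgroup_id`,
#'   `tgroup_id`, `pfam_list`, `kind`, `n_members`, `representative`),
#'   `tgroup_only` (domain ids placed '.0'), `deferred` (diagnostics
#'   from [defer_overlaps()]), `summary` (named list of counts).
#' @export
accession_run <- function(judged, mappings, hierarchy, correspondence,
                          existing, min_overlap = 0.5) {
  if (anyDuplicated(correspondence[, c("tgroup_id", "pfam_key")])) {
    stop("duplicate F-group Pfam set under one T-group", call. = FALSE)
  }
  good <- judged[judged$judge == "good_domain", ]
  rejected <- setdiff(judged$domain_id, good$domain_id)
  ov <- defer_overlaps(good, existing, min_overlap)
  retained <- good[good$domain_id %in% ov$retained, ]
  map_idx <- match(retained$domain_id, mappings$domain_id)
  if (anyNA(map_idx)) {
    stop("retained domain(s) missing from mappings: ",
         paste(head(retained$domain_id[is.na(map_idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  accs <- mappings$pfam_accs[map_idx]
  assigns <- lapply(seq_len(nrow(retained)), function(i) {
    assign_fgroup(accs[i], correspondence, hierarchy, retained$tgroup_id[i])
  })
  status <- tibble(
    domain_id = retained$domain_id,
    status = "accessioned",
    fgroup_status = vapply(assigns, `[[`, character(1), "status"),
    fgroup_id = vapply(assigns, `[[`, character(1), "fgroup_id"),
    pfam_key = vapply(assigns, `[[`, character(1), "pfam_key")
  )
  # create new F-groups, one per distinct (T-group, Pfam set)
  is_new <- status$fgroup_status %in% c("new_simple", "new_composite")
  new_fgroups <- tibble(fgroup_id = character(), tgroup_id = character(),
                        pfam_list = character(), kind = character(),
                        n_members = integer(), representative = character())
  if (any(is_new)) {
    nd <- tibble(domain_id = retained$domain_id[is_new],
                 tgroup_id = retained$tgroup_id[is_new],
                 pfam_key = status$pfam_key[is_new],
                 kind = ifelse(status$fgroup_status[is_new] == "new_simple",
                               "simple", "composite"),
                 dpam_prob = retained$dpam_prob[is_new],
                 mplddt = mean_plddt(retained$plddt[is_new]))
    new_fgroups <- nd %>%
      group_by(.data$tgroup_id, .data$pfam_key, .data$kind) %>%
      summarise(n_members = n(),
                representative = {
                  o <- order(-.data$dpam_prob, -.data$mplddt, .data$domain_id)
                  .data$domain_id[o][1]
                }, .groups = "drop") %>%
      arrange(.data$tgroup_id, .data$pfam_key)
    new_fgroups <- new_fgroups %>%
      group_by(.data$tgroup_id) %>%
      mutate(fgroup_id = paste0(.data$tgroup_id, ".",
                                next_f_suffix(hierarchy, .data$tgroup_id[1]) +
                                  row_number() - 1L)) %>%
      ungroup() %>%
      rename(pfam_list = "pfam_key") %>%
      select("fgroup_id", "tgroup_id", "pfam_list", "kind", "n_members",
             "representative")
    fg_id <- setNames(new_fgroups$fgroup_id,
                      paste(new_fgroups$tgroup_id, new_fgroups$pfam_list))
    status$fgroup_id[is_new] <-
      fg_id[paste(retained$tgroup_id[is_new], status$pfam_key[is_new])]
  }
  tg_only <- status$domain_id[status$fgroup_status == "tgroup_only"]
  status$fgroup_id[status$fgroup_status == "tgroup_only"] <-
    paste0(retained$tgroup_id[status$fgroup_status == "tgroup_only"], ".0")
  all_status <- bind_rows(
    status,
    tibble(domain_id = ov$deferred$domain_id, status = "deferred",
           fgroup_status = NA_character_, fgroup_id = NA_character_,
           pfam_key = NA_character_),
    tibble(domain_id = rejected, status = "rejected",
           fgroup_status = NA_character_, fgroup_id = NA_character_,
           pfam_key = NA_character_)
  )
  list(
    status = all_status,
    new_fgroups = new_fgroups,
    tgroup_only = tg_only,
    deferred = ov$deferred,
    summary = list(
      n_input = nrow(judged),
      n_rejected = length(rejected),
      n_deferred = nrow(ov$deferred),
      n_accessioned = nrow(status),
      n_new_fgroups = nrow(new_fgroups),
      n_new_simple = sum(new_fgroups$kind == "simple"),
      n_new_composite = sum(new_fgroups$kind == "composite"),
      n_tgroup_only = length(tg_only)
    )
  )
}

# Next free numeric F suffix under a T-group ('.0' pseudo group excluded).
next_f_suffix <- function(hierarchy, tgroup_id) {
  kids <- hierarchy$id[hierarchy$level == "F" & hierarchy$parent == tgroup_id]
  suf <- suppressWarnings(as.integer(sub(".*\\.", "", kids)))
  suf <- suf[!is.na(suf) & suf > 0L]
  if (length(suf)) max(suf) + 1L else 1L
}
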