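TAX_RANKS <- c("species", "family", "order", "class", "phylum")

#' Rank weights for the taxonomic diversity score
#'
#' The composite diversity score is a weighted sum over five taxonomic
#' ranks of the ratio of distinct taxa to cluster size. The default
#' weights emphasise the finer ranks: species 0.30, family 0.25, order
#' 0.20, class 0.15, phylum 0.10. Weights must be non-negative and sum
#' to exactly 1.
#'
#' @param species,family,order,class,phylum Non-negative weights.
#' @return A named numeric vector of class `diversity_weights`.
#' @export
diversity_weights <- function(species = 0.30, family = 0.25, order = 0.20,
                              class = 0.15, phylum = 0.10) {
  w <- c(species = species, family = family, order = order, class = class,
         phylum = phylum)
  if (any(w < 0)) stop("negative diversity weight", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12) stop("diversity weights must sum to 1", call. = FALSE)
  structure(w, class = c("diversity_weights", "numeric"))
}

#' Resolve taxids against a lineage table
#'
#' @param taxids Integer vector of taxids.
#' @param lineages Lineage tibble (see [read_lineages()]).
#' @return The lineage rows for `taxids`, in the same order (taxids may
#'   repeat). Unknown taxids are an error, never a silent drop.
#' @export
resolve_lineage <- function(taxids, lineages) {
  idx <- match(taxids, lineages$taxid)
  if (anyNA(idx)) {
    stop("unknown taxid(s): ",
         paste(head(unique(taxids[is.na(idx)]), 5), collapse = ", "),
         call. = FALSE)
  }
  lineages[idx, ]
}

# Distinct resolved taxa at one rank. "unresolved" labels are not taxa:
# they do not count as distinct and two unresolved members never share a
# taxon.
n_distinct_resolved <- function(labels) {
  length(unique(labels[labels != "unresolved"]))
}

#' Weighted taxonomic diversity score of a cluster
#'
#' For each of the five weighted ranks the ratio of distinct resolved
#' taxa to the number of cluster members is computed; the score is the
#' weighted sum of these ratios. It ranges over (0, 1]: a cluster of n
#' members with identical lineages scores 1/n, and a cluster pairwise
#' distinct at every rank scores exactly 1. Scoring is restricted to
#' clusters with at least `min_members` members (default 3) so that the
#' ratios are informative.
#'
#' @param member_taxids Taxids of the cluster members (one per member;
#'   repeats allowed).
#' @param lineages Lineage tibble (see [read_lineages()]).
#' @param weights A [diversity_weights()].
#' @param min_members Minimum cluster size scored.
#' @return Numeric score in (0, 1].
#' @export
diversity_score <- function(member_taxids, lineages,
                            weights = diversity_weights(), min_members = 3L) {
  n <- length(member_taxids)
  if (n < min_members) {
    stop("below minimum cluster size (", n, " < ", min_members, ")",
         call. = FALSE)
  }
  lin <- resolve_lineage(member_taxids, lineages)
  ratios <- vapply(TAX_RANKS, function(r) n_distinct_resolved(lin[[r]]) / n,
                   numeric(1))
  sum(unclass(weights)[TAX_RANKS] * ratios)
}

#' Per-cluster taxonomic metrics and aggregates
#'
#' Computes, for every cluster with at least `min_members` members, the
#' distinct-taxa counts per rank, the weighted diversity score, the
#' "highly diverse" flag (score strictly greater than
#' `high_diversity_cutoff`; the boundary itself is not highly diverse)
#' and a multi-phylum flag (two or more distinct resolved phyla).
#' Smaller clusters are excluded before any metric is computed.
#'
#' @param cs A [cluster_set()].
#' @param domain_taxids Named integer vector mapping domain id to taxid.
#' @param lineages Lineage tibble (see [read_lineages()]).
#' @param weights A [diversity_weights()].
#' @param min_members Minimum cluster size analysed (default 3).
#' @param high_diversity_cutoff Score cutoff for the highly-diverse flag.
#' @return A list with `per_cluster` (tibble: `cluster`, `n_members`,
#'   `n_species`, `n_families`, `n_orders`, `n_classes`, `n_phyla`,
#'   `diversity_score`, `highly_diverse`, `multi_phylum`) and
#'   `aggregate` (one-row tibble of the fractions and means over
#'   retained clusters).
#' @export
cluster_tax_metrics <- function(cs, domain_taxids, lineages,
                                weights = diversity_weights(),
                                min_members = 3L,
                                high_diversity_cutoff = 0.7) {
  stopifnot(inherits(cs, "cluster_set"))
  sz <- cluster_sizes(cs)
  keep <- sz$cluster[sz$size >= min_members]
  members <- cs$members[cs$members$cluster %in% keep, ]
  if (!nrow(members)) {
    per <- tibble(cluster = integer(), n_members = integer(),
                  n_species = integer(), n_families = integer(),
                  n_orders = integer(), n_classes = integer(),
                  n_phyla = integer(), diversity_score = numeric(),
                  highly_diverse = logical(), multi_phylum = logical())
    agg <- tibble(n_clusters_analysed = 0L, fraction_highly_diverse = NA_real_,
                  fraction_multi_phylum = NA_real_, mean_species = NA_real_,
                  mean_families = NA_real_, mean_phyla = NA_real_)
    return(list(per_cluster = per, aggregate = agg))
  }
  taxid <- domain_taxids[members$member_id]
  if (anyNA(taxid)) {
    stop("no taxid for domain(s): ",
         paste(head(members$member_id[is.na(taxid)], 5), collapse = ", "),
         call. = FALSE)
  }
  lin <- resolve_lineage(taxid, lineages)
  lin$cluster <- members$cluster
  w <- unclass(weights)[TAX_RANKS]
  per <- lin %>%
    group_by(cluster = .data$cluster) %>%
    summarise(n_members = n(),
              n_species = n_distinct_resolved(.data$species),
              n_families = n_distinct_resolved(.data$family),
              n_orders = n_distinct_resolved(.data$order),
              n_classes = n_distinct_resolved(.data$class),
              n_phyla = n_distinct_resolved(.data$phylum),
              .groups = "drop") %>%
    mutate(diversity_score =
             (w[["species"]] * .data$n_species + w[["family"]] * .data$n_families +
                w[["order"]] * .data$n_orders + w[["class"]] * .data$n_classes +
                w[["phylum"]] * .data$n_phyla) / .data$n_members,
           highly_diverse = .data$diversity_score > high_diversity_cutoff,
           multi_phylum = .data$n_phyla >= 2L)
  agg <- tibble(
    n_clusters_analysed = nrow(per),
    fraction_highly_diverse = mean(per$highly_diverse),
    fraction_multi_phylum = mean(per$multi_phylum),
    mean_species = mean(per$n_species),
    mean_families = mean(per$n_families),
    mean_phyla = mean(per$n_phyla)
  )
  list(per_cluster = per, aggregate = agg)
}
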