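#' Pipeline configuration
#'
#' Collects input paths and tunable parameters for [run_pipeline()].
#' With the conventional file names written by [simulate_dataset()] /
#' [write_bundle()], only the data and output directories are needed.
#'
#' @param data_dir Directory holding the input files.
#' @param out_dir Output directory for stage outputs and the summary.
#' @param domains,proteins,fasta,lineages,hierarchy,correspondence,existing
#'   Paths to the individual inputs (defaults: conventional names under
#'   `data_dir`).
#' @param hits Named character vector of per-release domtblout paths
#'   (names are release tags); default: every `hits_<release>.domtblout`
#'   under `data_dir`.
#' @param mapping_release Release used for the Pfam mapping proper;
#'   later releases feed the temporal-capture analysis. Default: the
#'   first release in version order with a non-empty hit table.
#' @param cluster_thresholds Identity thresholds for the clustering
#'   stage, finest first.
#' @param judge A [judge_thresholds()].
#' @param rules A [confidence_rules()].
#' @param weights A [diversity_weights()].
#' @param min_overlap Deferral cutoff for [accession_run()].
#' @param new_family_floor Numeric Pfam accession floor for
#'   [temporal_capture()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            domains = file.path(data_dir, "domains.tsv"),
                            proteins = file.path(data_dir, "proteins.tsv"),
                            fasta = file.path(data_dir, "domains.fasta"),
                            lineages = file.path(data_dir, "lineages.tsv"),
                            hierarchy = file.path(data_dir, "hierarchy.tsv"),
                            correspondence = file.path(data_dir, "correspondence.tsv"),
                            existing = file.path(data_dir, "existing_domains.tsv"),
                            hits = NULL,
                            mapping_release = NULL,
                            cluster_thresholds = c(0.99, 0.70, 0.40),
                            judge = judge_thresholds(),
                            rules = confidence_rules(),
                            weights = diversity_weights(),
                            min_overlap = 0.5,
                            new_family_floor = 25159L) {
  if (is.null(hits)) {
    files <- list.files(data_dir, pattern = "^hits_.*\\.domtblout$",
                        full.names = TRUE)
    hits <- setNames(files, sub("^hits_(.*)\\.domtblout$", "\\1",
                                basename(files)))
  }
  cfg <- list(domains = domains, proteins = proteins, fasta = fasta,
              lineages = lineages, hierarchy = hierarchy,
              correspondence = correspondence, existing = existing,
              hits = hits, mapping_release = mapping_release,
              cluster_thresholds = cluster_thresholds, judge = judge,
              rules = rules, weights = weights, min_overlap = min_overlap,
              new_family_floor = new_family_floor, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file may set any scalar field of [pipeline_config()]
#' (`data_dir`, `out_dir`, `min_overlap`, `new_family_floor`,
#' `cluster_thresholds`, `mapping_release`) plus nested `judge`,
#' `rules` and `weights` blocks whose entries override the respective
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$data_dir) || is.null(y$out_dir)) {
    stop("config must set data_dir and out_dir", call. = FALSE)
  }
  args <- list(data_dir = y$data_dir, out_dir = y$out_dir)
  for (f in c("min_overlap", "new_family_floor", "cluster_thresholds",
              "mapping_release")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$judge)) args$judge <- do.call(judge_thresholds, y$judge)
  if (!is.null(y$rules)) {
    args$rules <- do.call(confidence_rules, lapply(y$rules, as.list))
  }
  if (!is.null(y$weights)) args$weights <- do.call(diversity_weights, y$weights)
  do.call(pipeline_config, args)
}

#' Run the full post-prediction annotation pipeline
#'
#' Executes, in order: judge categorization, multi-threshold greedy
#' clustering of the domain sequences, per-cluster taxonomic diversity,
#' Pfam mapping from the mapping-release hits, mapping-gap
#' classification and temporal capture over later releases,
#' novel-family candidate flagging, and overlap-aware accession. Stage
#' outputs are written under `out_dir` with a manifest of content
#' hashes; the summary lands in `summary.json`.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]) or the
#'   path to a YAML file for [read_pipeline_config()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with all stage results and the `summary`
#'   list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[triage] ", sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(config$out_dir, x)

  domains <- read_domains(config$domains)
  proteins <- read_tsv_strict(config$proteins)
  proteins$length <- as.integer(proteins$length)
  seqs <- read_domain_fasta(config$fasta)
  lineages <- read_lineages(config$lineages)
  hierarchy <- read_hierarchy(config$hierarchy)
  correspondence <- read_correspondence(config$correspondence)
  existing <- read_tsv_strict(config$existing)
  say("inputs: %d domains, %d proteins, %d lineages", nrow(domains),
      nrow(proteins), nrow(lineages))

  judged <- judge_domains(domains, config$judge)
  jsum <- judge_summary(judged)
  write_tsv_canonical(judged, fp("judged.tsv"))
  say("judge: %d in -> %d judged", nrow(domains), nrow(judged))

  domains_per_protein <- judged %>% count(.data$protein_acc, name = "k") %>%
    count(.data$k, name = "n_proteins")

  csets <- list()
  cstats <- list()
  for (th in config$cluster_thresholds) {
    cs <- greedy_cluster(seqs, th)
    tag <- sprintf("F%02.0f", th * 100)
    write_clstr(cs, fp(paste0(tag, ".clstr")))
    csets[[tag]] <- cs
    cstats[[tag]] <- cluster_stats(cs)
    say("cluster %s: %d clusters", tag, cstats[[tag]]$n_clusters)
  }
  cstats <- bind_rows(cstats)

  coarse_tag <- sprintf("F%02.0f", min(config$cluster_thresholds) * 100)
  domain_taxids <- setNames(judged$taxid, judged$domain_id)
  tax <- lapply(csets, cluster_tax_metrics, domain_taxids = domain_taxids,
                lineages = lineages, weights = config$weights)
  div_agg <- bind_rows(lapply(names(tax), function(t) {
    tax[[t]]$aggregate %>% mutate(set = t, .before = 1)
  }))
  write_tsv_canonical(tax[[coarse_tag]]$per_cluster, fp("divscores.tsv"))

  hit_releases <- names(config$hits)
  hit_tables <- lapply(hit_releases, function(r) {
    read_domtblout(config$hits[[r]], release = r)
  })
  names(hit_tables) <- hit_releases
  mapping_release <- config$mapping_release
  if (is.null(mapping_release)) {
    ord <- hit_releases[order(numeric_version(hit_releases))]
    nonempty <- ord[vapply(hit_tables[ord], nrow, integer(1)) > 0]
    if (!length(nonempty)) stop("no hits in any release", call. = FALSE)
    mapping_release <- nonempty[1]
  }
  mappings <- map_domains(hit_tables[[mapping_release]], judged$domain_id,
                          config$rules)
  write_tsv_canonical(mappings, fp("mappings.tsv"))
  rates <- mapping_rates(mappings, judged)
  say("pfam-map (release %s): %d/%d mapped", mapping_release,
      sum(mappings$mapped), nrow(mappings))

  gaps <- classify_unmapped(judged, mappings)
  write_tsv_canonical(gaps, fp("gap.tsv"))
  later <- hit_releases[numeric_version(hit_releases) >
                          numeric_version(mapping_release)]
  capture <- if (length(later) && nrow(gaps)) {
    temporal_capture(bind_rows(hit_tables[c(mapping_release, later)]),
                     gaps$domain_id, config$new_family_floor)
  } else {
    tibble(domain_id = character(), first_release = character(),
           captured_by = character())
  }
  say("gap: %d unmapped good domains, %d captured by later releases",
      nrow(gaps), sum(capture$captured_by != "none"))

  candidates <- flag_novel_family_candidates(csets[[coarse_tag]],
                                             tax[[coarse_tag]], mappings)

  acc <- accession_run(judged, mappings, hierarchy, correspondence, existing,
                       config$min_overlap)
  write_tsv_canonical(acc$status, fp("accession_status.tsv"))
  write_tsv_canonical(acc$new_fgroups, fp("new_fgroups.tsv"))
  writeLines(acc$tgroup_only, fp("tgroup_only.txt"))
  say("accession: %d accessioned, %d deferred, %d rejected, %d new F-groups",
      acc$summary$n_accessioned, acc$summary$n_deferred,
      acc$summary$n_rejected, acc$summary$n_new_fgroups)

  extras <- report_extras(judged, proteins)

  summary <- list(
    n_domains = nrow(judged),
    domains_per_protein = domains_per_protein,
    judge = jsum$by_category,
    continuity = jsum$continuity,
    cluster_stats = cstats,
    diversity = div_agg,
    mapping_rates = rates,
    gap_classes = as.list(table(gaps$gap_class)),
    temporal_capture = as.list(table(capture$captured_by)),
    novel_family_candidates = candidates,
    accession = acc$summary,
    extras = list(no_domain_proteins = nrow(extras$no_domain),
                  no_domain_median_length = extras$no_domain_median_length,
                  median_protein_plddt = extras$median_protein_plddt,
                  median_domain_plddt = extras$median_domain_plddt)
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)

  files <- list.files(config$out_dir, full.names = TRUE, recursive = TRUE)
  files <- setdiff(files, fp("manifest.tsv"))
  manifest <- tibble(file = basename(files), md5 = unname(tools::md5sum(files)))
  write_tsv_canonical(manifest, fp("manifest.tsv"))

  invisible(list(judged = judged, clusters = csets, cluster_stats = cstats,
                 tax = tax, mappings = mappings, rates = rates, gaps = gaps,
                 capture = capture, candidates = candidates, accession = acc,
                 extras = extras, summary = summary, manifest = manifest))
}

#' Duplication, no-domain and confidence-smoothing report
#'
#' Three small analyses around the main pipeline: per-protein counts of
#' domains sharing an H-group (domain duplication), the benchmark list
#' of proteins with no parsed domain (with their length statistics),
#' and the comparison of per-protein versus per-domain mean pLDDT --
#' domain parsing trims low-confidence linkers, so the domain-level
#' distribution is expected to sit higher.
#'
#' @param judged Output of [judge_domains()].
#' @param proteins Protein tibble (`protein_acc`, `length`, `taxid`,
#'   `plddt`), including proteins without domains.
#' @return A list: `duplication` (tibble `protein_acc`, `hgroup_id`,
#'   `n_domains`, for pairs with two or more), `no_domain` (protein
#'   rows without any domain), `no_domain_median_length`,
#'   `median_protein_plddt`, `median_domain_plddt`.
#' @export
report_extras <- function(judged, proteins) {
  dup <- judged %>%
    count(.data$protein_acc, .data$hgroup_id, name = "n_domains") %>%
    filter(.data$n_domains >= 2L) %>%
    arrange(-.data$n_domains)
  nodom <- proteins[!proteins$protein_acc %in% judged$protein_acc, ]
  list(
    duplication = dup,
    no_domain = nodom,
    no_domain_median_length = if (nrow(nodom)) median(nodom$length) else NA_real_,
    median_protein_plddt = median(mean_plddt(proteins$plddt)),
    median_domain_plddt = median(mean_plddt(judged$plddt))
  )
}
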