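# Shared builders for in-code fixtures. Everything is generated at test
# time; no binary fixtures on disk.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
        "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

# One domain-table row with judge-relevant fields under full control.
# n_sse countable elements by construction (helix-4 runs split by coil).
domain_row <- function(id, prob = 0.95, cov = 0.9, n_sse = 5L, len = NULL,
                       range = NULL, protein = "P1", tgroup = "2001.1.1",
                       ref = "eR1", taxid = 1001L) {
  ss_core <- paste(rep(paste0(strrep("H", 4), "CC"), n_sse), collapse = "")
  if (is.null(len)) len <- max(nchar(ss_core), 30L)
  stopifnot(len >= nchar(ss_core))
  ss <- paste0(ss_core, strrep("C", len - nchar(ss_core)))
  if (is.null(range)) range <- sprintf("1-%d", len)
  tibble::tibble(
    domain_id = id, protein_acc = protein, range = range, dpam_prob = prob,
    hit_ecod_domain_id = ref, tgroup_id = tgroup, hgroup_id = "2001.1",
    xgroup_id = "2001", arch_id = "a1", ref_coverage = cov, ss_string = ss,
    plddt = paste(rep("90.0", len), collapse = ","), taxid = taxid)
}

# Hit row(s) for select_nonoverlapping / map_domains tests.
hit_row <- function(from, to, bits, acc = "PF00001", query = "d1",
                    hmm_from = 1L, hmm_to = 95L, model_len = 100L,
                    ga = TRUE, release = "38") {
  tibble::tibble(
    query_domain_id = query, pfam_acc = acc, pfam_name = paste0("f_", acc),
    bit_score = bits, evalue = 1e-20, env_from = as.integer(from),
    env_to = as.integer(to), hmm_from = as.integer(hmm_from),
    hmm_to = as.integer(hmm_to), model_len = as.integer(model_len),
    passes_ga = ga, release = release)
}

# Minimal A/X/H/T hierarchy with the given T-groups and F-groups.
tiny_hierarchy <- function(tgroups = "2001.1.1",
                           fgroups = list(list(id = "2001.1.1.1",
                                               tgroup = "2001.1.1",
                                               pfam = "PF00001"))) {
  rows <- list(tibble::tibble(id = "a1", level = "A", parent = "",
                              pfam_list = ""))
  for (tg in tgroups) {
    x <- sub("\\.[0-9]+\\.[0-9]+$", "", tg)
    h <- sub("\\.[0-9]+$", "", tg)
    rows <- c(rows, list(
      tibble::tibble(id = x, level = "X", parent = "a1", pfam_list = ""),
      tibble::tibble(id = h, level = "H", parent = x, pfam_list = ""),
      tibble::tibble(id = tg, level = "T", parent = h, pfam_list = "")))
  }
  for (f in fgroups) {
    rows <- c(rows, list(tibble::tibble(id = f$id, level = "F",
                                        parent = f$tgroup,
                                        pfam_list = f$pfam)))
  }
  unique(dplyr::bind_rows(rows))
}

tiny_correspondence <- function(fgroups) {
  out <- dplyr::bind_rows(lapply(fgroups, function(f) {
    tibble::tibble(fgroup_id = f$id, tgroup_id = f$tgroup, pfam_list = f$pfam)
  }))
  out$pfam_key <- domaintriage:::pfam_set_key(out$pfam_list)
  out
}

# Lineage table where member i of each vector gets the i-th label at
# each rank; vectors are recycled.
tiny_lineages <- function(n, species = NULL, family = NULL, order = NULL,
                          class = NULL, phylum = NULL) {
  lab <- function(x, pre) if (is.null(x)) sprintf("%s%d", pre, seq_len(n))
  else rep_len(x, n)
  tibble::tibble(
    taxid = seq_len(n) + 1000L,
    species = lab(species, "s"), family = lab(family, "f"),
    order = lab(order, "o"), class = lab(class, "c"),
    phylum = lab(phylum, "p"), superkingdom = "Bacteria")
}
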