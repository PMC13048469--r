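test_that("unmapped well-assigned domains classify into the three gap classes", {
  # T-group A: mapped sibling hits reference R; T-group B: no mapped domains
  judged <- judge_domains(dplyr::bind_rows(
    domain_row("m1", ref = "R", tgroup = "2001.1.1"),
    domain_row("u_sens", ref = "R", tgroup = "2001.1.1"),
    domain_row("u_under", ref = "Rprime", tgroup = "2001.1.1"),
    domain_row("u_norep", ref = "R2", tgroup = "2002.1.1")))
  maps <- tibble::tibble(domain_id = c("m1", "u_sens", "u_under", "u_norep"),
                         mapped = c(TRUE, FALSE, FALSE, FALSE))
  g <- classify_unmapped(judged, maps)
  cls <- setNames(as.character(g$gap_class), g$domain_id)
  expect_equal(cls[["u_sens"]], "sensitivity_gap")
  expect_equal(cls[["u_under"]], "underspecified_subgroup")
  expect_equal(cls[["u_norep"]], "unrepresented_tgroup")
  # the mapped domain is not classified; the partition covers all unmapped good
  expect_equal(sort(g$domain_id), c("u_norep", "u_sens", "u_under"))

  bad <- judged
  bad$hit_ecod_domain_id[bad$domain_id == "u_sens"] <- ""
  expect_error(classify_unmapped(bad, maps), "without hit_ecod_domain_id")
})

test_that("temporal capture separates new families from improved models", {
  floor <- 25159L
  h_new <- hit_row(1, 80, 60, acc = "PF25596", query = "dA", release = "38.2")
  h_imp <- hit_row(1, 80, 60, acc = "PF00118", query = "dB", release = "38.1")
  hits <- dplyr::bind_rows(h_new, h_imp)
  r <- temporal_capture(hits, c("dA", "dB", "dC"), floor)
  expect_equal(r$first_release, c("38.2", "38.1", NA))
  expect_equal(r$captured_by, c("new_family", "improved_model", "none"))

  # a domain first captured in an early release keeps that release even
  # when later releases also hit it
  both <- dplyr::bind_rows(
    hit_row(1, 80, 60, acc = "PF25596", query = "dA", release = "37.4"),
    h_new)
  r2 <- temporal_capture(both, "dA", floor)
  expect_equal(r2$first_release, "37.4")

  # capture classification looks at all capturing families of the first release
  mixed <- dplyr::bind_rows(
    hit_row(1, 40, 60, acc = "PF25596", query = "dA", release = "38.2"),
    hit_row(50, 90, 55, acc = "PF00118", query = "dA", release = "38.2"))
  expect_equal(temporal_capture(mixed, "dA", floor)$captured_by,
               "improved_model")

  bad <- hit_row(1, 80, 60, acc = "PF25596", query = "dA", release = "not a tag")
  expect_error(temporal_capture(bad, "dA", floor), "unordered release tags")
})

test_that("adding hits in earlier releases never delays first capture", {
  set.seed(61)
  for (i in 1:20) {
    rel <- c("37.4", "38", "38.1", "38.2")
    base <- dplyr::bind_rows(lapply(sample(rel, 2), function(r) {
      hit_row(1, 80, 60, acc = "PF25596", query = "dA", release = r)
    }))
    r0 <- temporal_capture(base, "dA")$first_release
    more <- dplyr::bind_rows(base, hit_row(1, 80, 55, acc = "PF25700",
                                           query = "dA", release = rel[1]))
    r1 <- temporal_capture(more, "dA")$first_release
    expect_lte(which(rel == r1), which(rel == r0))
  }
})

test_that("novel-family candidates need size, breadth and total unmappedness", {
  mk_case <- function(size, phyla, all_unmapped = TRUE) {
    ids <- sprintf("n%d", seq_len(size))
    cs <- cluster_set(tibble::tibble(
      member_id = ids, cluster = 0L, aa = 100L,
      is_rep = seq_len(size) == 1L, identity = NA_real_))
    lin <- tiny_lineages(phyla)
    taxids <- setNames(rep_len(lin$taxid, size), ids)
    tm <- cluster_tax_metrics(cs, taxids, lin)
    maps <- tibble::tibble(domain_id = ids,
                           mapped = if (all_unmapped) FALSE
                           else c(TRUE, rep(FALSE, size - 1L)))
    flag_novel_family_candidates(cs, tm, maps)
  }
  hit <- mk_case(133, 40)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_members, 133L)
  expect_equal(hit$n_phyla, 40L)
  expect_equal(nrow(mk_case(150, 10)), 0L)   # too few phyla
  expect_equal(nrow(mk_case(90, 20)), 0L)    # too small
  expect_equal(nrow(mk_case(133, 40, all_unmapped = FALSE)), 0L)
})

test_that("overlap deferral uses shared residues over the shorter domain", {
  new <- domain_row("n1", range = "10-100", len = 91L)
  same <- tibble::tibble(protein_acc = "P1", range = "10-100",
                         tgroup_id = "2001.1.1")
  r <- defer_overlaps(new, same, 0.5)
  expect_equal(r$deferred$domain_id, "n1")
  expect_equal(r$deferred$overlap, 1.0)
  expect_true(r$deferred$identical_range)
  expect_true(r$deferred$near_identical_range)
  expect_true(r$deferred$same_tgroup)

  far <- tibble::tibble(protein_acc = "P1", range = "200-300",
                        tgroup_id = "2001.1.1")
  expect_equal(defer_overlaps(new, far, 0.5)$retained, "n1")

  # 41 shared residues over min length 91 = 0.4505...
  part <- tibble::tibble(protein_acc = "P1", range = "60-160",
                         tgroup_id = "2001.1.1")
  expect_equal(defer_overlaps(new, part, 0.40)$deferred$domain_id, "n1")
  expect_equal(defer_overlaps(new, part, 0.40)$deferred$overlap, 41 / 91)
  expect_equal(defer_overlaps(new, part, 0.50)$retained, "n1")

  # other proteins never interfere
  other <- tibble::tibble(protein_acc = "P2", range = "10-100",
                          tgroup_id = "2001.1.1")
  expect_equal(defer_overlaps(new, other, 0.5)$retained, "n1")
})

test_that("deferred and retained partition the candidates", {
  set.seed(62)
  doms <- dplyr::bind_rows(lapply(1:30, function(i) {
    domain_row(sprintf("d%d", i), range = sprintf("%d-%d", i * 200, i * 200 + 99),
               len = 100L, protein = sprintf("P%d", (i - 1) %% 5 + 1))
  }))
  existing <- tibble::tibble(
    protein_acc = sprintf("P%d", (0:9) %% 5 + 1),
    range = sprintf("%d-%d", (1:10) * 200, (1:10) * 200 + 99),
    tgroup_id = "2001.1.1")
  r <- defer_overlaps(doms, existing, 0.5)
  expect_setequal(c(r$retained, r$deferred$domain_id), doms$domain_id)
  expect_length(intersect(r$retained, r$deferred$domain_id), 0)
})

test_that("accession creates planted F-groups and promotes the best representative", {
  sc <- scenario(seed = 5, n_proteins = 60)
  b <- simulate_dataset(sc)
  judged <- judge_domains(b$domains)
  maps <- map_domains(b$hits[b$hits$release == "38", ], judged$domain_id)
  acc <- accession_run(judged, maps, b$hierarchy, b$correspondence, b$existing)

  expect_equal(acc$summary$n_new_simple, sc$withheld_simple)
  expect_equal(acc$summary$n_new_composite, sc$withheld_composite)
  expect_setequal(sort(acc$new_fgroups$pfam_list), sort(b$withheld$pfam_list))

  # statuses partition the input
  expect_setequal(acc$status$domain_id, judged$domain_id)
  expect_equal(anyDuplicated(acc$status$domain_id), 0L)
  expect_equal(table(acc$status$status)[["rejected"]],
               sum(judged$judge != "good_domain"))

  # representative has the maximum assignment probability in its group
  acc_ids <- acc$status$domain_id[acc$status$status == "accessioned"]
  for (i in seq_len(nrow(acc$new_fgroups))) {
    g <- acc$new_fgroups[i, ]
    members <- judged$domain_id[
      judged$domain_id %in% acc_ids &
        judged$tgroup_id == g$tgroup_id &
        maps$pfam_accs[match(judged$domain_id, maps$domain_id)] == g$pfam_list]
    expect_true(g$representative %in% members)
    expect_equal(judged$dpam_prob[judged$domain_id == g$representative],
                 max(judged$dpam_prob[judged$domain_id %in% members]))
  }

  # unmapped retained good domains land in '.0' pseudo groups
  expect_equal(sort(acc$tgroup_only),
               sort(acc$status$domain_id[acc$status$fgroup_status == "tgroup_only" &
                                           !is.na(acc$status$fgroup_status)]))
  expect_true(all(grepl("\\.0$", acc$status$fgroup_id[
    acc$status$fgroup_status %in% "tgroup_only"])))
})

test_that("all-overlapping input defers everything and accessioned domains never overlap", {
  doms <- dplyr::bind_rows(
    domain_row("d1", range = "1-100", len = 100L, protein = "P1"),
    domain_row("d2", range = "150-260", len = 111L, protein = "P1"))
  judged <- judge_domains(doms)
  maps <- tibble::tibble(domain_id = c("d1", "d2"), mapped = FALSE,
                         pfam_accs = "", n_hits = 0L, total_bits = 0,
                         min_coverage = NA_real_, tier = NA_character_)
  hier <- tiny_hierarchy()
  corr <- tiny_correspondence(list(list(id = "2001.1.1.1",
                                        tgroup = "2001.1.1", pfam = "PF00001")))
  existing <- doms[, c("protein_acc", "range", "tgroup_id")]
  acc <- accession_run(judged, maps, hier, corr, existing)
  expect_equal(acc$summary$n_accessioned, 0L)
  expect_equal(acc$summary$n_deferred, 2L)

  # with planted overlaps, no two accessioned domains on a protein overlap
  sc <- scenario(seed = 6, n_proteins = 60)
  b <- simulate_dataset(sc)
  judged2 <- judge_domains(b$domains)
  maps2 <- map_domains(b$hits[b$hits$release == "38", ], judged2$domain_id)
  acc2 <- accession_run(judged2, maps2, b$hierarchy, b$correspondence,
                        b$existing, min_overlap = 0.5)
  ad <- judged2[judged2$domain_id %in%
                  acc2$status$domain_id[acc2$status$status == "accessioned"], ]
  for (p in unique(ad$protein_acc)) {
    rs <- lapply(ad$range[ad$protein_acc == p], parse_range_string)
    if (length(rs) > 1) {
      for (a in seq_len(length(rs) - 1)) {
        for (bb in seq.int(a + 1, length(rs))) {
          frac <- range_overlap(rs[[a]], rs[[bb]]) /
            min(residue_count(rs[[a]]), residue_count(rs[[bb]]))
          expect_lt(frac, 0.5)
        }
      }
    }
  }
})
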