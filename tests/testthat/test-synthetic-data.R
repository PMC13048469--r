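test_that("scenario validation rejects inconsistent plans", {
  expect_s3_class(scenario(), "scenario")
  expect_error(scenario(n_tgroups = 0L))
  expect_error(scenario(judge_fractions = c(good_domain = 0.5,
                                            partial_domain = 0.2,
                                            low_confidence = 0.2,
                                            simple_topology = 0.2)),
               "sum to 1")
})

test_that("the reference builder creates a fully parented hierarchy with withheld sets", {
  sc <- scenario(n_tgroups = 5L, fgroups_per_tgroup = 3L,
                 withheld_simple = 2L, withheld_composite = 1L)
  ref <- make_reference(sc)
  expect_equal(sum(ref$hierarchy$level == "F"), 15L)
  expect_equal(sum(ref$hierarchy$level == "T"), 5L)
  expect_silent(domaintriage:::validate_hierarchy(ref$hierarchy))
  expect_equal(nrow(ref$withheld), 3L)
  expect_equal(sort(unique(ref$withheld$kind)), c("composite", "simple"))
  # withheld sets are genuinely absent from the correspondence
  expect_length(intersect(domaintriage:::pfam_set_key(ref$withheld$pfam_list),
                          ref$correspondence$pfam_key), 0)
  # composite F-groups list two accessions
  comp <- grepl(",", ref$correspondence$pfam_list)
  expect_true(any(comp))
})

test_that("the taxonomy builder produces a balanced ranked tree", {
  sc <- scenario(n_phyla = 3L, classes_per_phylum = 2L, orders_per_class = 2L,
                 families_per_order = 2L, species_per_family = 2L)
  lin <- make_taxonomy(sc)
  expect_equal(nrow(lin), 3L * 2L * 2L * 2L * 2L)
  expect_equal(dplyr::n_distinct(lin$phylum), 3L)
  expect_equal(anyDuplicated(lin$taxid), 0L)

  # single-species taxonomy: homogeneous clusters score 1/n
  lin1 <- make_taxonomy(scenario(n_phyla = 1L, classes_per_phylum = 1L,
                                 orders_per_class = 1L, families_per_order = 1L,
                                 species_per_family = 1L))
  expect_equal(nrow(lin1), 1L)
  expect_equal(diversity_score(rep(lin1$taxid, 5), lin1), 1 / 5)
})

test_that("class attributes are planted by quota, not sampled", {
  sc <- scenario(seed = 9, n_proteins = 80)
  b <- simulate_dataset(sc)
  n <- nrow(b$domains)
  q <- domaintriage:::quota_counts(n, sc$judge_fractions)
  expect_equal(as.vector(table(factor(b$truth$judge,
                                      levels = names(sc$judge_fractions)))), q)
  n_disc <- sum(b$truth$continuity == "discontinuous")
  expect_equal(n_disc, domaintriage:::quota_counts(
    n, c(sc$discontinuous_fraction, 1 - sc$discontinuous_fraction))[1])
  for (cl in names(sc$mapped_fractions)) {
    idx <- b$truth$judge == cl
    expect_equal(sum(b$truth$mapped[idx]),
                 domaintriage:::quota_counts(
                   sum(idx), c(sc$mapped_fractions[[cl]],
                               1 - sc$mapped_fractions[[cl]]))[1])
  }
})

test_that("planted attributes are recovered by the pipeline stages themselves", {
  sc <- scenario(seed = 10, n_proteins = 80)
  b <- simulate_dataset(sc)
  judged <- judge_domains(b$domains)
  expect_equal(as.character(judged$judge),
               b$truth$judge[match(judged$domain_id, b$truth$domain_id)])
  expect_equal(judged$continuity, b$truth$continuity)
  maps <- map_domains(b$hits[b$hits$release == "38", ], judged$domain_id)
  expect_equal(maps$mapped, b$truth$mapped)
  g <- classify_unmapped(judged, maps)
  expect_equal(as.character(g$gap_class),
               b$truth$gap_class[match(g$domain_id, b$truth$domain_id)])
  # SSE strings honor the planted class under the judge's own counter
  simple <- b$domains$ss_string[b$truth$judge == "simple_topology"]
  expect_true(all(count_sse(simple) < 3))
  other <- b$domains$ss_string[b$truth$judge != "simple_topology"]
  expect_true(all(count_sse(other) >= 3))
})

test_that("generation is deterministic in the seed", {
  sc <- scenario(seed = 12, n_proteins = 40)
  b1 <- simulate_dataset(sc)
  b2 <- simulate_dataset(sc)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1, sc$releases)
  simulate_dataset(sc, d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the data
  b3 <- simulate_dataset(scenario(seed = 13, n_proteins = 40))
  expect_false(identical(b1$domains, b3$domains))
})

test_that("per-residue vectors always match the segmented ranges", {
  b <- simulate_dataset(scenario(seed = 14, n_proteins = 30))
  nres <- domaintriage:::ranges_nres(b$domains$range)
  expect_equal(nchar(b$domains$ss_string), nres)
  expect_equal(vapply(parse_plddt(b$domains$plddt), length, integer(1)), nres)
  expect_equal(unname(nchar(b$seqs[b$domains$domain_id])), nres)
})
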