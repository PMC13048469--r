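test_that("lineages resolve by taxid with unresolved ranks preserved", {
  lin <- tiny_lineages(3)
  lin$family[2] <- "unresolved"
  got <- resolve_lineage(c(1002L, 1001L), lin)
  expect_equal(got$species, c("s2", "s1"))
  expect_equal(got$family[1], "unresolved")
  expect_error(resolve_lineage(9999L, lin), "unknown taxid")
})

test_that("diversity weights must be a unit simplex over the five ranks", {
  w <- diversity_weights()
  expect_equal(sum(unclass(w)), 1)
  expect_error(diversity_weights(species = 0.5), "sum to 1")
  expect_error(diversity_weights(species = -0.1, family = 0.65), "negative")
})

test_that("diversity score hits its analytic bounds and the worked example", {
  # 3 members pairwise distinct at all five ranks -> the upper bound 1
  expect_equal(diversity_score(1001:1003, tiny_lineages(3)), 1.0)
  # n identical lineages -> 1/n
  lin1 <- tiny_lineages(3, species = "s", family = "f", order = "o",
                        class = "c", phylum = "p")
  expect_equal(diversity_score(1001:1003, lin1), 1 / 3)
  # 4 members: 2 species, 2 families, 1 order, 1 class, 1 phylum
  lin4 <- tiny_lineages(4, species = c("sA", "sA", "sB", "sB"),
                        family = c("fA", "fA", "fB", "fB"),
                        order = "o", class = "c", phylum = "p")
  expect_equal(diversity_score(1001:1004, lin4), 0.3875)
  expect_equal(diversity_score(1001:1004, lin4),
               diversity_oracle(resolve_lineage(1001:1004, lin4)))
  expect_error(diversity_score(1001:1002, tiny_lineages(2)),
               "below minimum cluster size")
})

test_that("diversity score equals the literal formula on random clusters and is permutation-invariant", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    lin <- tibble::tibble(
      taxid = seq_len(n) + 1000L,
      species = sample(sprintf("s%d", 1:6), n, replace = TRUE),
      family = sample(sprintf("f%d", 1:4), n, replace = TRUE),
      order = sample(sprintf("o%d", 1:3), n, replace = TRUE),
      class = sample(c("c1", "c2", "c3"), n, replace = TRUE),
      phylum = sample(c("p1", "p2"), n, replace = TRUE),
      superkingdom = "Bacteria")
    ids <- sample(lin$taxid, n, replace = TRUE)
    s <- diversity_score(ids, lin)
    expect_equal(s, diversity_oracle(resolve_lineage(ids, lin)),
                 tolerance = 1e-12)
    expect_identical(s, diversity_score(rev(ids), lin))
    expect_gte(s, 1 / n - 1e-12)
    expect_lte(s, 1 + 1e-12)
  }
})

test_that("unresolved labels never count as distinct taxa", {
  lin <- tiny_lineages(3, phylum = "unresolved")
  lin$species <- c("s1", "s2", "s3")
  lin$family <- c("f1", "f2", "f3")
  lin$order <- c("o1", "o2", "o3")
  lin$class <- c("c1", "c2", "c3")
  # phylum ratio 0 instead of 1: score loses exactly the phylum weight
  expect_equal(diversity_score(1001:1003, lin), 0.90)
})

test_that("cluster taxonomic metrics respect the minimum size and flags", {
  members <- tibble::tibble(
    member_id = c("a", "b", "c", "d", "e"),
    cluster = c(0L, 0L, 1L, 1L, 1L), aa = 100L,
    is_rep = c(TRUE, FALSE, TRUE, FALSE, FALSE), identity = NA_real_)
  cs <- cluster_set(members, 0.4)
  lin <- tiny_lineages(5, phylum = c("p1", "p1", "p1", "p2", "p2"))
  taxids <- setNames(1001:1005, members$member_id)
  m <- cluster_tax_metrics(cs, taxids, lin)
  # the 2-member cluster is excluded before metrics
  expect_equal(m$per_cluster$cluster, 1L)
  expect_equal(m$per_cluster$n_members, 3L)
  expect_true(m$per_cluster$multi_phylum)
  expect_equal(m$aggregate$n_clusters_analysed, 1L)

  # homogeneous 10-member cluster: score 1/10, not highly diverse
  big <- cluster_set(tibble::tibble(
    member_id = sprintf("m%d", 1:10), cluster = 0L, aa = 100L,
    is_rep = c(TRUE, rep(FALSE, 9)), identity = NA_real_), 0.4)
  lin1 <- tiny_lineages(1, species = "s", family = "f", order = "o",
                        class = "c", phylum = "p")
  m2 <- cluster_tax_metrics(big, setNames(rep(1001L, 10), sprintf("m%d", 1:10)),
                            lin1)
  expect_equal(m2$per_cluster$diversity_score, 0.1)
  expect_false(m2$per_cluster$highly_diverse)
  expect_false(m2$per_cluster$multi_phylum)

  # highly_diverse is exactly score > 0.7 (boundary excluded)
  expect_identical(m$per_cluster$highly_diverse,
                   m$per_cluster$diversity_score > 0.7)
})
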