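test_that("gathering-threshold filtering keeps order and passes-only", {
  h <- dplyr::bind_rows(hit_row(1, 50, 60, acc = "PF00001"),
                        hit_row(60, 90, 40, acc = "PF00002", ga = FALSE),
                        hit_row(100, 150, 30, acc = "PF00003"))
  expect_equal(filter_hits_ga(h)$pfam_acc, c("PF00001", "PF00003"))
  expect_equal(nrow(filter_hits_ga(h[h$passes_ga == FALSE, ])), 0L)
  expect_equal(nrow(filter_hits_ga(h[0, ])), 0L)
})

test_that("non-overlapping selection maximizes summed bit score", {
  h <- dplyr::bind_rows(hit_row(1, 100, 60, acc = "PF00001"),
                        hit_row(50, 150, 80, acc = "PF00002"),
                        hit_row(160, 200, 30, acc = "PF00003"))
  sel <- select_nonoverlapping(h, 0L)
  expect_equal(sort(sel$pfam_acc), c("PF00002", "PF00003"))
  expect_equal(sum(sel$bit_score), 110)

  one <- hit_row(1, 50, 42)
  expect_equal(select_nonoverlapping(one, 0L), one)
  two <- dplyr::bind_rows(hit_row(1, 50, 42, acc = "PF00001"),
                          hit_row(60, 90, 13, acc = "PF00002"))
  expect_equal(nrow(select_nonoverlapping(two, 0L)), 2L)
  expect_error(select_nonoverlapping(two, -1L), "negative")

  # tolerance admits bounded sharing: A(1-100) and B(100-150) share 1 residue
  ab <- dplyr::bind_rows(hit_row(1, 100, 60, acc = "PF00001"),
                         hit_row(100, 150, 70, acc = "PF00002"))
  expect_equal(nrow(select_nonoverlapping(ab, 0L)), 1L)
  expect_equal(nrow(select_nonoverlapping(ab, 1L)), 2L)
})

test_that("dynamic program equals exhaustive subset maximization", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    h <- random_hit_instance(n)
    tol <- sample(0:3, 1)
    sel <- select_nonoverlapping(h, tol)
    # the selection is feasible ...
    if (nrow(sel) > 1) {
      for (a in seq_len(nrow(sel) - 1)) {
        for (b in seq.int(a + 1, nrow(sel))) {
          ov <- min(sel$env_to[a], sel$env_to[b]) -
            max(sel$env_from[a], sel$env_from[b]) + 1L
          expect_lte(ov, tol)
        }
      }
    }
    # ... and optimal
    expect_equal(sum(sel$bit_score),
                 brute_force_best_bits(h$env_from, h$env_to, h$bit_score, tol),
                 tolerance = 1e-9)
  }
})

test_that("adding a hit never decreases the selection optimum", {
  set.seed(52)
  for (i in 1:30) {
    h <- random_hit_instance(sample(2:10, 1))
    base <- sum(select_nonoverlapping(h, 0L)$bit_score)
    h2 <- dplyr::bind_rows(h, random_hit_instance(1))
    expect_gte(sum(select_nonoverlapping(h2, 0L)$bit_score), base - 1e-9)
  }
})

test_that("confidence tiers partition by coverage and bit score", {
  expect_equal(mapping_confidence(0.85, 60), "high")
  # bit score must be strictly above 50
  expect_equal(mapping_confidence(0.80, 50.0), "medium")
  expect_equal(mapping_confidence(0.85, 40), "medium")
  expect_equal(mapping_confidence(0.50, 30), "low")
  expect_equal(mapping_confidence(0.10, 300), "uncertain")
  expect_equal(mapping_confidence(0.95, 10), "uncertain")
  # every (coverage, bits) lands in exactly one tier
  set.seed(53)
  tiers <- vapply(1:100, function(i) {
    mapping_confidence(runif(1), runif(1, 0, 120))
  }, character(1))
  expect_true(all(tiers %in% c("high", "medium", "low", "uncertain")))
})

test_that("per-domain mapping tiles hits and tiers composites by their weakest family", {
  h <- dplyr::bind_rows(
    hit_row(1, 60, 90, acc = "PF00001", query = "d1",
            hmm_from = 1, hmm_to = 90, model_len = 100),     # high
    hit_row(70, 120, 25, acc = "PF00002", query = "d1",
            hmm_from = 1, hmm_to = 45, model_len = 100),     # low
    hit_row(1, 80, 70, acc = "PF00003", query = "d2",
            hmm_from = 1, hmm_to = 88, model_len = 100),
    hit_row(1, 50, 60, acc = "PF00004", query = "d3", ga = FALSE))
  m <- map_domains(h, domain_ids = c("d1", "d2", "d3"))
  expect_equal(m$domain_id, c("d1", "d2", "d3"))
  expect_equal(m$mapped, c(TRUE, TRUE, FALSE))
  expect_equal(m$pfam_accs[1], "PF00001,PF00002")
  expect_equal(m$tier[1], "low")     # weakest member governs the composite
  expect_equal(m$tier[2], "high")
  expect_equal(m$n_hits, c(2L, 1L, 0L))
})

test_that("F-group assignment distinguishes existing, new and pseudo groups", {
  fg <- list(list(id = "2001.1.1.1", tgroup = "2001.1.1", pfam = "PF00118"),
             list(id = "2001.1.1.2", tgroup = "2001.1.1",
                  pfam = "PF00001,PF00002"))
  hier <- tiny_hierarchy(fgroups = fg)
  corr <- tiny_correspondence(fg)
  a <- assign_fgroup("PF00118", corr, hier, "2001.1.1")
  expect_equal(a$status, "existing")
  expect_equal(a$fgroup_id, "2001.1.1.1")
  # set matching ignores order
  expect_equal(assign_fgroup(c("PF00002", "PF00001"), corr, hier,
                             "2001.1.1")$status, "existing")
  expect_equal(assign_fgroup("PF90001", corr, hier, "2001.1.1")$status,
               "new_simple")
  expect_equal(assign_fgroup(c("PF90001", "PF90002"), corr, hier,
                             "2001.1.1")$status, "new_composite")
  expect_equal(assign_fgroup(character(0), corr, hier, "2001.1.1")$status,
               "tgroup_only")
  expect_error(assign_fgroup("PF00118", corr, hier, "9.9.9"),
               "absent from hierarchy")
})

test_that("mapping rates are per-judge-category with reported denominators", {
  judged <- judge_domains(dplyr::bind_rows(lapply(1:10, function(i) {
    domain_row(paste0("g", i), prob = 0.95, cov = 0.9, n_sse = 4)
  })))
  maps <- tibble::tibble(domain_id = paste0("g", 1:10),
                         mapped = c(rep(TRUE, 9), FALSE))
  r <- mapping_rates(maps, judged)
  expect_equal(nrow(r), 1L)  # absent categories yield no row
  expect_equal(r$mapped_fraction, 0.9)
  expect_equal(r$n, 10L)
  expect_error(mapping_rates(maps[1:5, ], judged), "unjoined")
})
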