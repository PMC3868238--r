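# 3 drugs x 4 kinases: dX puts the query (MET, ALK) at ranks 1-2,
# dY and dZ put it at the bottom
three_drug_ref <- function() {
  m <- matrix(c(0.001, 0.002, 5, 9,
                8,     9,     0.1, 0.2,
                5,     7,     0.3, 0.1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("dX", "dY", "dZ"),
                              c("MET", "ALK", "K1", "K2")))
  rank_profiles(activity_matrix(m, "kd"))
}

test_that("the drug enriching the query tops the table with score 1", {
  res <- connect_query(three_drug_ref(), c("MET", "ALK"), permutations = 0)
  expect_equal(res$table$drug[1], "dX")
  expect_equal(res$table$normalized_score[1], 1)
  expect_equal(res$table$score[1], 1)
  expect_gt(res$table$ks[1], 0)
  expect_lt(res$table$ks[3], 0)
  expect_equal(res$table$normalized_score[3], 0)  # most anti-enriched
  expect_equal(res$table$rank, 1:3)
})

test_that("a single-drug reference is its own extreme", {
  m <- tiny_kd_matrix(c(0.001, 0.5, 9), "only", c("MET", "A", "B"))
  res <- connect_query(rank_profiles(m), "MET", permutations = 0)
  expect_true(res$table$score %in% c(-1, 0, 1))
  expect_equal(res$table$score, 1)  # MET at rank 1 -> positive ks
})

test_that("connectivity depends only on ranks (scale invariance)", {
  sp <- fixture_spec(n_drugs = 8, n_kinases = 30, seed = 12,
                     spikes = list(spike("s1", c("MET", "ALK"))))
  am <- generate_fixture(sp)
  r1 <- connect_query(rank_profiles(am), c("MET", "ALK"),
                      permutations = 100, seed = 5)
  am2 <- activity_matrix(am$values * 37.5, "kd")
  r2 <- connect_query(rank_profiles(am2), c("MET", "ALK"),
                      permutations = 100, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$running_sums, r2$running_sums)
})

test_that("p-values are independent of drug iteration order", {
  sp <- fixture_spec(n_drugs = 6, n_kinases = 20, seed = 3)
  am <- generate_fixture(sp)
  r1 <- connect_query(rank_profiles(am), am$kinases[1:3],
                      permutations = 200, seed = 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  am2 <- activity_matrix(am$values[perm, ], "kd")
  r2 <- connect_query(rank_profiles(am2), am$kinases[1:3],
                      permutations = 200, seed = 9)
  expect_identical(r1$table, r2$table)
})

test_that("drugs missing some query kinases score with per-drug M", {
  v <- matrix(c(0.001, 0.002, 1, 2,
                0.001, NA,    1, 2),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("full", "partial"),
                              c("MET", "ALK", "K1", "K2")))
  res <- connect_query(rank_profiles(activity_matrix(v, "kd")),
                       c("MET", "ALK"), permutations = 0)
  tab <- res$table
  expect_equal(tab$n_matched[tab$drug == "full"], 2L)
  expect_equal(tab$n_matched[tab$drug == "partial"], 1L)
  expect_equal(tab$n_ref[tab$drug == "partial"], 3L)
})

test_that("drugs assaying no query kinase are reported unscored", {
  v <- matrix(c(0.001, 1, NA,
                NA,    2, 0.5),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("hit", "blind"), c("MET", "K1", "K2")))
  res <- connect_query(rank_profiles(activity_matrix(v, "kd")),
                       "MET", permutations = 0)
  expect_equal(res$table$drug, "hit")
  expect_equal(res$unscored, "blind")
})

test_that("a query disjoint from the universe fails loudly", {
  expect_error(connect_query(three_drug_ref(), "NOTHERE"),
               "NOTHERE")
  # query_set whose kinases all miss the reference universe
  qs <- expand_family("TK", structure(
    list(family = data.frame(kinase = "ZAP70", family = "TK"), go = NULL),
    class = "annotation_map"))
  expect_error(connect_query(three_drug_ref(), qs),
               "no kinase with the reference universe")
})

test_that("ties in normalized score break by ascending drug id", {
  # two drugs with identical profiles on the query
  v <- matrix(c(0.001, 1, 2,
                0.001, 1, 2,
                9,     0.1, 0.2),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("zeta", "alpha", "anti"),
                              c("MET", "K1", "K2")))
  res <- connect_query(rank_profiles(activity_matrix(v, "kd")),
                       "MET", permutations = 0)
  expect_equal(res$table$drug[1:2], c("alpha", "zeta"))
})

test_that("running sums are attached per scored drug and peak at a", {
  res <- connect_query(three_drug_ref(), c("MET", "ALK"), permutations = 0)
  expect_named(res$running_sums, res$table$drug)
  for (i in seq_len(nrow(res$table))) {
    d <- res$running_sums[[res$table$drug[i]]]
    expect_length(d, res$table$n_ref[i])
    expect_equal(max(d), res$table$a[i])
  }
})

test_that("TSV and JSON round out the result with provenance", {
  res <- connect_query(three_drug_ref(), c("MET", "ALK"),
                       permutations = 50, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_tsv(res, tsv)
  lines <- readLines(tsv)
  expect_true(any(grepl("^# seed: 4$", lines)))
  expect_true(any(grepl("^# permutations: 50$", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(body[1],
               "rank\tdrug\tn_matched\tn_ref\tks\tscore\tnormalized_score\tp_value")
  expect_length(body, 4)  # header + 3 drugs

  js <- withr::local_tempfile(fileext = ".json")
  write_connectivity_json(res, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$table$drug, res$table$drug)
  expect_equal(parsed$seed, 4)
  expect_length(parsed$running_sums[["dX"]], 4)
})
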