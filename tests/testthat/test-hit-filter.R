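mk_hits <- function(query, target, tm, evalue = 1e-6, fident = 0.5,
                    qcov = 0.8, tcov = 0.8, alnlen = 150L,
                    source = NULL) {
  h <- tibble::tibble(query = query, target = target, fident = fident,
                      alnlen = alnlen, mismatch = 0L, gapopen = 0L,
                      qstart = 1L, qend = alnlen, tstart = 1L,
                      tend = alnlen, evalue = evalue, bits = 100L,
                      alntmscore = tm, qcov = qcov, tcov = tcov)
  if (!is.null(source)) h$source <- source
  h
}

test_that("best_hit_per_query maximizes identity times query coverage", {
  hits <- mk_hits(c("q", "q"), c("t1", "t2"), tm = c(0.9, 0.6),
                  fident = c(0.9, 0.7), qcov = c(0.5, 0.7))
  best <- best_hit_per_query(hits)
  expect_equal(best$target, "t2")  # 0.49 beats 0.45
  expect_equal(best$best_score, 0.49)

  single <- best_hit_per_query(mk_hits("q", "t9", 0.7))
  expect_equal(single$target, "t9")

  # product and TM tie: lexicographically smaller target
  tied <- mk_hits(c("q", "q"), c("tb", "ta"), tm = c(0.7, 0.7),
                  fident = c(0.8, 0.8), qcov = c(0.5, 0.5))
  expect_equal(best_hit_per_query(tied)$target, "ta")
  # TM breaks product ties before the label does
  tm_tie <- mk_hits(c("q", "q"), c("ta", "tb"), tm = c(0.6, 0.8),
                    fident = c(0.8, 0.8), qcov = c(0.5, 0.5))
  expect_equal(best_hit_per_query(tm_tie)$target, "tb")
  # exactly one winner per query with at least one hit
  set.seed(8)
  many <- mk_hits(sample(letters[1:5], 40, replace = TRUE),
                  sprintf("t%02d", 1:40), tm = runif(40),
                  fident = runif(40), qcov = runif(40))
  expect_equal(sort(unique(many$query)),
               sort(best_hit_per_query(many)$query))
})

test_that("the defense-library policy applies its strict thresholds", {
  pol <- filter_policy("defensefinder")
  # passes all four bounds (cluster of one: cluster mean tm = own tm)
  ok <- mk_hits("q", "DF1", tm = 0.66, evalue = 1e-4,
                qcov = 0.62, tcov = 0.60)
  expect_equal(nrow(apply_policy(ok, pol)), 1)
  # TM exactly at the bound fails (strict >)
  expect_equal(nrow(apply_policy(
    mk_hits("q", "DF1", tm = 0.65, evalue = 1e-4, qcov = 0.62,
            tcov = 0.60), pol)), 0)
  # average coverage (0.61) vs bound 0.6; dropping tcov to 0.55 fails
  expect_equal(nrow(apply_policy(
    mk_hits("q", "DF1", tm = 0.66, evalue = 1e-4, qcov = 0.62,
            tcov = 0.55), pol)), 0)
  expect_equal(nrow(apply_policy(
    mk_hits("q", "DF1", tm = 0.66, evalue = 0.01, qcov = 0.62,
            tcov = 0.60), pol)), 0)
})

test_that("the antidefense policy exempts sources without E-values", {
  pol <- filter_policy("antidefense")
  # a dbAPIS hit with a meaningless E-value still passes: the E-value
  # bound only binds antidefensefinder hits
  db <- mk_hits("q", "AP1", tm = 0.70, evalue = 1, qcov = 0.55,
                tcov = 0.55, alnlen = 120L, source = "dbapis")
  expect_equal(nrow(apply_policy(db, pol)), 1)
  adf <- mk_hits("q", "AD1", tm = 0.70, evalue = 1, qcov = 0.55,
                 tcov = 0.55, alnlen = 120L, source = "antidefensefinder")
  expect_equal(nrow(apply_policy(adf, pol)), 0)
  # intracluster alignment length must exceed 100
  short <- mk_hits("q", "AP1", tm = 0.70, evalue = 1, qcov = 0.55,
                   tcov = 0.55, alnlen = 90L, source = "dbapis")
  expect_equal(nrow(apply_policy(short, pol)), 0)
})

test_that("cluster-level criteria average over the query's cluster", {
  members <- tibble::tibble(cluster_id = "K", protein_id = c("q1", "q2"),
                            is_representative = c(TRUE, FALSE))
  # q1 passes per-hit bounds; the cluster mean TM (0.66 + 0.40)/2 = 0.53
  # still clears 0.5, but with a weaker clustermate it would not
  hits <- mk_hits(c("q1", "q2"), "DF1", tm = c(0.66, 0.40),
                  evalue = 1e-4, qcov = 0.62, tcov = 0.60)
  pol <- filter_policy("defensefinder")
  kept <- apply_policy(hits, pol, members = members)
  expect_equal(kept$query, "q1")
  weak <- mk_hits(c("q1", "q2"), "DF1", tm = c(0.66, 0.30),
                  evalue = 1e-4, qcov = 0.62, tcov = 0.60)
  expect_equal(nrow(apply_policy(weak, pol, members = members)), 0)
  # hits without a cluster-statistics entry fail with a warning
  stats <- cluster_hit_stats(hits[1, ], members)
  expect_warning(
    res <- apply_policy(hits, pol, members = tibble::tibble(
      cluster_id = "other", protein_id = "qX",
      is_representative = TRUE), cluster_stats = stats),
    "cluster statistics")
  expect_equal(nrow(res), 0)
})

test_that("policy filtering is monotone and idempotent", {
  set.seed(31)
  n <- 300
  hits <- mk_hits(sprintf("q%03d", sample(50, n, replace = TRUE)),
                  sprintf("t%02d", sample(10, n, replace = TRUE)),
                  tm = runif(n), evalue = 10^runif(n, -10, 0),
                  fident = runif(n), qcov = runif(n), tcov = runif(n),
                  alnlen = sample(50:300, n, replace = TRUE))
  stats <- cluster_hit_stats(hits)
  tm_bounds <- sort(runif(20, 0.2, 0.9))
  prev <- NULL
  for (b in tm_bounds) {
    pol <- filter_policy("custom", tm_min = b, avg_cov_min = 0.3,
                         cluster_tm_min = 0.2)
    kept <- apply_policy(hits, pol, cluster_stats = stats)
    if (!is.null(prev)) {
      expect_true(all(do.call(paste, kept[, c("query", "target")]) %in%
                        do.call(paste, prev[, c("query", "target")])))
    }
    # idempotence against fixed cluster statistics
    expect_equal(apply_policy(kept, pol, cluster_stats = stats), kept)
    prev <- kept
  }
})

test_that("antidefense sources merge keeping the best TM per query", {
  adf <- mk_hits("q1", "AD1", tm = 0.7, source = "antidefensefinder")
  db <- mk_hits(c("q1", "q2"), c("AP1", "AP2"), tm = c(0.8, 0.6),
                source = "dbapis")
  merged <- merge_antidefense(adf, db)
  expect_equal(merged$target[merged$query == "q1"], "AP1")  # 0.8 wins
  expect_equal(merged$target[merged$query == "q2"], "AP2")  # only source
  # TM tie prefers the antidefense-library hit
  tie <- merge_antidefense(mk_hits("q", "AD1", tm = 0.7),
                           mk_hits("q", "AP1", tm = 0.7))
  expect_equal(tie$source, "antidefensefinder")
  expect_equal(nrow(merge_antidefense(adf[0, ], db)), 2)
})
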