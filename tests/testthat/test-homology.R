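test_that("best hit selection minimizes e-value with the documented ties", {
  h <- random_hits(2)[1:2, ]
  h$query_id <- "q1"
  h$subject_id <- c("s1", "s2")
  h$evalue <- c(1e-50, 1e-10)
  expect_identical(best_hits(h)$subject_id, "s1")

  h$evalue <- c(1e-50, 1e-50)
  h$pident <- c(90, 95)
  h$aln_len <- c(100L, 100L)
  expect_identical(best_hits(h)$subject_id, "s2")

  expect_identical(nrow(best_hits(h[0, ])), 0L)
})

test_that("best hits equal the exhaustive per-query oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    h <- random_hits(sample(20:100, 1))
    got <- best_hits(h)
    want <- oracle_best_hits(h)
    expect_identical(got[order(got$query_id), c("query_id", "subject_id")],
                     want[, c("query_id", "subject_id")])
  }
})

test_that("reciprocity keeps mutual best hits only", {
  f <- random_hits(1)
  f$query_id <- "q1"; f$subject_id <- "s1"
  r <- f
  r$query_genome <- "Y"; r$subject_genome <- "X"
  r$query_id <- "s1"; r$subject_id <- "q1"
  p <- bidirectional_best_hits(f, r)
  expect_identical(nrow(p), 1L)
  expect_identical(p$id_a, "q1")
  expect_identical(p$id_b, "s1")
  expect_equal(p$pident, f$pident)  # forward value is authoritative

  r$subject_id <- "q2"
  expect_identical(nrow(bidirectional_best_hits(f, r)), 0L)

  r$query_genome <- "Z"
  expect_error(bidirectional_best_hits(f, r), "not reciprocal")
})

test_that("reciprocity equals the O(n^2) cross-product oracle", {
  for (seed in 1:100) {
    set.seed(seed + 1000)
    n <- 50
    fwd <- data.frame(query_genome = "X", subject_genome = "Y",
                      query_id = paste0("x", sample.int(n)),
                      subject_id = paste0("y", sample.int(n, n, TRUE)),
                      evalue = 1e-30, pident = 95, pgaps = 0,
                      aln_len = 100L, score = 100,
                      stringsAsFactors = FALSE)
    rev <- data.frame(query_genome = "Y", subject_genome = "X",
                      query_id = paste0("y", sample.int(n)),
                      subject_id = paste0("x", sample.int(n, n, TRUE)),
                      evalue = 1e-30, pident = 95, pgaps = 0,
                      aln_len = 100L, score = 100,
                      stringsAsFactors = FALSE)
    got <- bidirectional_best_hits(fwd, rev)
    want <- oracle_bbh(fwd, rev)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_identical(got$id_a, unname(want[, 1]))
      expect_identical(got$id_b, unname(want[, 2]))
    }
  }
})

test_that("identity filter is strict and applied before reciprocity", {
  mk <- function(pident_fwd, pident_rev = pident_fwd) {
    f <- data.frame(query_genome = "H", subject_genome = "P",
                    query_id = "h1", subject_id = "p1", evalue = 1e-40,
                    pident = pident_fwd, pgaps = 0, aln_len = 300L,
                    score = 200, stringsAsFactors = FALSE)
    r <- f
    r$query_genome <- "P"; r$subject_genome <- "H"
    r$query_id <- "p1"; r$subject_id <- "h1"
    r$pident <- pident_rev
    list(f = f, r = r)
  }
  x <- mk(98)
  expect_identical(nrow(find_orthologs(x$f, x$r)$pairs), 1L)

  ## exactly 80.0 is rejected: the rule is *more than* 80% identity
  x <- mk(80.0)
  o <- find_orthologs(x$f, x$r)
  expect_identical(nrow(o$pairs), 0L)
  expect_identical(o$subthreshold_ids, "h1")

  expect_identical(nrow(find_orthologs(x$f, x$r, identity_min = 79)$pairs),
                   1L)

  ## a second-best hit above threshold must not be promoted when the best
  ## hit fails the filter
  f2 <- rbind(x$f, x$f)
  f2$subject_id <- c("p1", "p2")
  f2$evalue <- c(1e-60, 1e-40)   # best hit is p1 at 80.0 -> discarded
  f2$pident <- c(80, 95)
  r2 <- x$r
  r2$query_id <- "p2"            # p2 would reciprocate
  o <- find_orthologs(f2, r2)
  expect_identical(nrow(o$pairs), 0L)
  expect_identical(o$subthreshold_ids, "h1")

  expect_error(find_orthologs(x$f, x$r, identity_min = 0), "0, 100")
})

test_that("orthologs recover the simulator's truth for non-duplicated genes", {
  cfg <- sim_config(n_genes = 40, len_mean = 400, len_sd = 80,
                    div_parent = 0.10, dup_rate_parent = 0,
                    ploidy = c(parentA = 1L, parentB = 1L), loss_rate = 0,
                    div_posthyb = 0, dup_rate_hybrid = 0, seed = 3)
  sim <- simulate_hybrid_dataset(cfg)
  fwd <- run_backend(list(query_genome = "hybrid",
                          subject_genome = "parentA", purpose = "x"),
                     sim$hybrid, sim$parents$parentA)
  rev <- run_backend(list(query_genome = "parentA",
                          subject_genome = "hybrid", purpose = "x"),
                     sim$parents$parentA, sim$hybrid)
  pairs <- find_orthologs(fwd, rev)$pairs
  truthA <- sim$truth[sim$truth$source_parent == "parentA", ]
  got <- setNames(pairs$id_b, pairs$id_a)
  expect_identical(unname(got[truthA$hybrid_id]), truthA$source_gene)
})

test_that("self paralogs are mutual best non-self hits", {
  s <- random_dna(200)
  x <- orfs(c(g1 = s, g2 = s, g3 = random_dna(200)), "G")
  h <- run_backend(list(query_genome = "G", subject_genome = "G",
                        purpose = "self-paralog"), x, x)
  p <- find_self_paralogs(h)
  expect_identical(nrow(p), 1L)
  expect_identical(p$id_a, "g1")
  expect_identical(p$id_b, "g2")
  expect_true(all(p$id_a != p$id_b))

  ## unique singletons give no paralogs
  set.seed(8)
  y <- orfs(setNames(replicate(6, random_dna(250)), paste0("u", 1:6)), "U")
  hy <- run_backend(list(query_genome = "U", subject_genome = "U",
                         purpose = "self-paralog"), y, y)
  expect_identical(nrow(find_self_paralogs(hy)), 0L)

  bad <- h
  bad$subject_genome <- "other"
  expect_error(find_self_paralogs(bad), "genome-vs-itself")
})

test_that("simulated duplicate families are detected as self paralogs", {
  cfg <- sim_config(n_genes = 20, len_mean = 400, len_sd = 50,
                    dup_rate_parent = 1, seed = 12)
  sim <- simulate_hybrid_dataset(cfg)
  pa <- sim$parents$parentA
  h <- run_backend(list(query_genome = "parentA",
                        subject_genome = "parentA",
                        purpose = "self-paralog"), pa, pa)
  p <- find_self_paralogs(h)
  truth <- sim$parent_truth$parentA
  dups <- truth[truth$is_duplicate, ]
  want <- t(apply(cbind(dups$template_id, dups$gene_id), 1, sort))
  want <- want[order(want[, 1]), , drop = FALSE]
  expect_identical(p$id_a, unname(want[, 1]))
  expect_identical(p$id_b, unname(want[, 2]))
})

test_that("group merging follows shared members", {
  g <- merge_into_groups(pairs_df(c("a", "b"), c("b", "c")))
  expect_identical(length(g), 1L)
  expect_identical(g[[1]], c("a", "b", "c"))

  g <- merge_into_groups(pairs_df(c("a", "c"), c("b", "d")))
  expect_identical(length(g), 2L)

  expect_identical(length(merge_into_groups(pairs_df(character(0),
                                                     character(0)))), 0L)
})

test_that("group merging equals the transitive-closure oracle", {
  for (seed in 1:100) {
    set.seed(seed + 500)
    n_nodes <- sample(10:60, 1)
    n_pairs <- sample(5:80, 1)
    p <- pairs_df(paste0("n", sample.int(n_nodes, n_pairs, TRUE)),
                  paste0("n", sample.int(n_nodes, n_pairs, TRUE)))
    p <- p[p$id_a != p$id_b, ]
    if (!nrow(p)) next
    got <- merge_into_groups(p)
    want <- oracle_components(p)
    expect_identical(unname(lapply(got, identity)), want)
    ## partition property: groups cover exactly the ids in pairs, once
    ids <- unlist(got, use.names = FALSE)
    expect_false(anyDuplicated(ids) > 0)
    expect_setequal(ids, unique(c(p$id_a, p$id_b)))
  }
})

test_that("large random instance matches the oracle (1000 pairs)", {
  set.seed(4242)
  p <- pairs_df(paste0("v", sample.int(300, 1000, TRUE)),
                paste0("v", sample.int(300, 1000, TRUE)))
  p <- p[p$id_a != p$id_b, ]
  got <- merge_into_groups(p)
  want <- oracle_components(p)
  expect_identical(unname(lapply(got, identity)), want)
})

test_that("cross-parent orthologs behave like hybrid-parent orthologs", {
  set.seed(21)
  seqs <- setNames(replicate(8, random_dna(300)), paste0("g", 1:8))
  A <- orf_set(setNames(seqs, paste0("A_", names(seqs))), "A")
  B <- orf_set(setNames(seqs, paste0("B_", names(seqs))), "B")
  fwd <- run_backend(list(query_genome = "A", subject_genome = "B",
                          purpose = "x"), A, B)
  rev <- run_backend(list(query_genome = "B", subject_genome = "A",
                          purpose = "x"), B, A)
  p <- cross_parent_orthologs(fwd, rev)$pairs
  ## identical parents: every gene pairs with its counterpart at 100%
  expect_identical(nrow(p), 8L)
  expect_true(all(p$pident == 100))
  expect_identical(sub("^A_", "", p$id_a), sub("^B_", "", p$id_b))

  ## deleting one parent gene removes exactly that pair
  B2 <- orf_set(B$seqs[-1], "B")
  fwd2 <- run_backend(list(query_genome = "A", subject_genome = "B",
                           purpose = "x"), A, B2)
  rev2 <- run_backend(list(query_genome = "B", subject_genome = "A",
                           purpose = "x"), B2, A)
  p2 <- cross_parent_orthologs(fwd2, rev2)$pairs
  expect_false(orf_ids(B)[1] %in% p2$id_b)
  expect_identical(nrow(p2), 7L)
})

test_that("BBH pairs are 1:1 and subsets of both best-hit sets", {
  for (seed in 1:20) {
    set.seed(seed + 77)
    f <- best_hits(random_hits(60, 15, 15))
    r <- best_hits(random_hits(60, 15, 15, qg = "Y", sg = "X"))
    ## make ids compatible across directions
    r$query_id <- sub("^q", "t", r$query_id)
    r$subject_id <- sub("^t", "q", r$subject_id)
    p <- bidirectional_best_hits(f, r)
    expect_false(anyDuplicated(p$id_a) > 0)
    expect_false(anyDuplicated(p$id_b) > 0)
    expect_true(all(p$id_a %in% f$query_id))
    expect_true(all(p$id_b %in% r$query_id))
  }
})
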