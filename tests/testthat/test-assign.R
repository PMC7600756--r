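## convenience: build per-parent ortholog inputs from a compact spec
mk_inputs <- function(tbl, parents = c("A", "B")) {
  ## tbl: data.frame(hybrid_id, parent, gene, pident) -- one row per ortholog
  sets <- lapply(parents, function(p) {
    rows <- tbl[tbl$parent == p, , drop = FALSE]
    pairs_df(rows$hybrid_id, rows$gene, pident = rows$pident,
             ga = "hybrid", gb = p)
  })
  names(sets) <- parents
  sets
}

test_that("alleles go to the parent with strictly highest identity", {
  tbl <- data.frame(hybrid_id = c("h1", "h1"), parent = c("A", "B"),
                    gene = c("gA", "gB"), pident = c(98.2, 89.0),
                    stringsAsFactors = FALSE)
  a <- assign_parental_alleles(mk_inputs(tbl), list(), "h1")
  expect_identical(a$category, "ASSIGNED")
  expect_identical(a$parent_label, "A")
  expect_identical(a$parental_gene_id, "gA")
  expect_equal(a$pident, 98.2)
})

test_that("equal identities in several parents are declared ambiguous", {
  tbl <- data.frame(hybrid_id = c("h1", "h1"), parent = c("A", "B"),
                    gene = c("tRNA_A", "tRNA_B"), pident = c(100, 100),
                    stringsAsFactors = FALSE)
  a <- assign_parental_alleles(mk_inputs(tbl), list(), "h1")
  expect_identical(a$category, "AMBIGUOUS_EQUAL_IDENTITY")
  expect_identical(a$tied_parents, "A,B")
  expect_true(is.na(a$parent_label))

  ## ties are read at 2 decimals by default; a third decimal breaks one
  tbl$pident <- c(99.994, 99.987)
  a <- assign_parental_alleles(mk_inputs(tbl), list(), "h1")
  expect_identical(a$category, "AMBIGUOUS_EQUAL_IDENTITY")
  a <- assign_parental_alleles(mk_inputs(tbl), list(), "h1", digits = Inf)
  expect_identical(a$category, "ASSIGNED")
  expect_identical(a$parent_label, "A")
})

test_that("subthreshold and no-prediction are separated correctly", {
  sets <- mk_inputs(data.frame(hybrid_id = character(0),
                               parent = character(0), gene = character(0),
                               pident = numeric(0)))
  ## best hit at 72% identity, nothing else -> SUBTHRESHOLD_IDENTITY
  a <- assign_parental_alleles(sets, list(A = "h1"), c("h1", "h2"))
  expect_identical(a$category[a$hybrid_id == "h1"], "SUBTHRESHOLD_IDENTITY")
  expect_identical(a$category[a$hybrid_id == "h2"], "NO_PREDICTION")

  ## a non-reciprocal above-threshold best hit dominates: no prediction
  a <- assign_parental_alleles(sets, list(A = "h1"), c("h1", "h2"),
                               nonreciprocal_ids = list(B = "h1"))
  expect_identical(a$category[a$hybrid_id == "h1"], "NO_PREDICTION")
})

test_that("inconsistent inputs are refused", {
  tbl <- data.frame(hybrid_id = "h9", parent = "A", gene = "g",
                    pident = 95, stringsAsFactors = FALSE)
  expect_error(assign_parental_alleles(mk_inputs(tbl), list(), c("h1")),
               "absent from all_hybrid_ids")
  expect_error(assign_parental_alleles(mk_inputs(tbl)["A"], list(), "h9"),
               "2 to 4")
})

test_that("every ORF lands in exactly one category (partition invariant)", {
  for (seed in 1:25) {
    set.seed(seed + 9)
    n <- 60L
    ids <- sprintf("h%03d", 1:n)
    tbl <- do.call(rbind, lapply(c("A", "B", "C")[1:sample(2:3, 1)],
                                 function(p) {
      pick <- sample(ids, sample(10:40, 1))
      data.frame(hybrid_id = pick, parent = p,
                 gene = paste0(p, "_", pick),
                 pident = round(runif(length(pick), 81, 100), 2),
                 stringsAsFactors = FALSE)
    }))
    parents <- unique(tbl$parent)
    sub <- list(A = sample(ids, 5))
    a <- assign_parental_alleles(mk_inputs(tbl, parents), sub, ids)
    expect_identical(nrow(a), n)
    expect_false(anyDuplicated(a$hybrid_id) > 0)
    s <- classify_summary(a)
    parts <- s[grepl("^assigned:|ambiguous|subthreshold|no_prediction",
                     s$metric), 2]
    expect_identical(sum(parts), s[s$metric == "total_orfs", 2])
    ## ASSIGNED implies a strict winner above the threshold
    w <- a[a$category == "ASSIGNED", ]
    expect_true(all(w$pident > 80))
  }
})

test_that("removing a parent never promotes unpredicted ORFs", {
  for (seed in 1:15) {
    set.seed(seed + 321)
    ids <- sprintf("h%03d", 1:40)
    tbl <- do.call(rbind, lapply(c("A", "B", "C"), function(p) {
      pick <- sample(ids, 25)
      data.frame(hybrid_id = pick, parent = p, gene = paste0(p, "_", pick),
                 pident = round(runif(25, 81, 100), 2),
                 stringsAsFactors = FALSE)
    }))
    full <- assign_parental_alleles(mk_inputs(tbl, c("A", "B", "C")),
                                    list(), ids)
    drop <- assign_parental_alleles(mk_inputs(tbl, c("A", "B")),
                                    list(), ids)
    predicted <- function(a) {
      a$hybrid_id[a$category %in% c("ASSIGNED", "AMBIGUOUS_EQUAL_IDENTITY")]
    }
    expect_true(all(predicted(drop) %in% predicted(full)))
    ## ORFs assigned to a retained parent stay assigned to it
    keepA <- full[full$category == "ASSIGNED" & full$parent_label %in%
                    c("A", "B"), ]
    after <- drop[match(keepA$hybrid_id, drop$hybrid_id), ]
    expect_true(all(after$category == "ASSIGNED" &
                      after$parent_label == keepA$parent_label))
  }
})

test_that("summaries count categories and detect double assignment", {
  tbl <- data.frame(
    hybrid_id = paste0("h", 1:7), parent = c(rep("A", 4), rep("B", 3)),
    gene = paste0("g", 1:7), pident = 95, stringsAsFactors = FALSE)
  a <- assign_parental_alleles(mk_inputs(tbl), list(A = "h9"),
                               paste0("h", 1:10))
  tie <- data.frame(hybrid_id = "h8", parent = c("A", "B"),
                    gene = c("x", "y"), pident = 100,
                    stringsAsFactors = FALSE)
  a2 <- assign_parental_alleles(mk_inputs(rbind(tbl, tie)), list(A = "h9"),
                                paste0("h", 1:10))
  s <- classify_summary(a2, label = "toy")
  get <- function(m) s$toy[s$metric == m]
  expect_identical(get("total_orfs"), 10L)
  expect_identical(get("assigned:A"), 4L)
  expect_identical(get("assigned:B"), 3L)
  expect_identical(get("ambiguous_equal_identity"), 1L)
  expect_identical(get("subthreshold_identity"), 1L)
  expect_identical(get("no_prediction"), 1L)

  expect_error(classify_summary(rbind(a, a[1, ])), "more than once")

  ## degenerate: nothing assigned
  none <- assign_parental_alleles(mk_inputs(tbl[0, ]), list(),
                                  paste0("h", 1:5))
  s0 <- classify_summary(none)
  expect_identical(s0$run[s0$metric == "no_prediction"], 5L)
})

test_that("copy numbers count assigned ORFs per parental gene", {
  a <- data.frame(hybrid_id = c("h1", "h2", "h3"),
                  category = "ASSIGNED", parent_label = c("A", "A", "B"),
                  parental_gene_id = c("YBR218C", "YBR218C", "gB"),
                  pident = 99, origin = "ortholog",
                  tied_parents = NA_character_, stringsAsFactors = FALSE)
  cn <- copy_numbers(a)
  expect_identical(cn$copy_number[cn$parental_gene_id == "YBR218C"], 2L)
  expect_identical(cn$hybrid_ids[cn$parental_gene_id == "YBR218C"], "h1,h2")
  expect_identical(sum(cn$copy_number), 3L)

  a$parental_gene_id <- paste0("g", 1:3)
  expect_true(all(copy_numbers(a)$copy_number == 1L))
  expect_identical(nrow(copy_numbers(a[0, ])), 0L)

  ## conservation: sum of copy numbers == number of ASSIGNED ORFs
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    a <- data.frame(hybrid_id = paste0("h", 1:n),
                    category = sample(c("ASSIGNED", "NO_PREDICTION"), n,
                                      TRUE),
                    parent_label = sample(c("A", "B"), n, TRUE),
                    parental_gene_id = paste0("g", sample.int(15, n, TRUE)),
                    pident = 95, origin = "ortholog",
                    tied_parents = NA_character_, stringsAsFactors = FALSE)
    a$parental_gene_id[a$category != "ASSIGNED"] <- NA
    expect_identical(sum(copy_numbers(a)$copy_number),
                     sum(a$category == "ASSIGNED"))
  }
})

test_that("propagation hands alleles to unpredicted paralog partners", {
  a <- data.frame(
    hybrid_id = c("h1", "h2", "h3", "h4"),
    category = c("ASSIGNED", "NO_PREDICTION", "NO_PREDICTION",
                 "SUBTHRESHOLD_IDENTITY"),
    parent_label = c("B", NA, NA, NA),
    parental_gene_id = c("gB", NA, NA, NA),
    pident = c(99.5, NA, NA, NA),
    origin = c("ortholog", NA, NA, NA),
    tied_parents = NA_character_, stringsAsFactors = FALSE)
  ## chain h1 - h2 - h3; h4 in a pair but subthreshold, so untouched
  pairs <- pairs_df(c("h1", "h2", "h4"), c("h2", "h3", "h1"),
                    pident = c(99, 98, 97), ga = "hybrid", gb = "hybrid")
  out <- propagate_group_alleles(a, pairs)
  expect_identical(out$category[out$hybrid_id %in% c("h2", "h3")],
                   rep("ASSIGNED", 2))
  expect_identical(out$parental_gene_id[out$hybrid_id == "h3"], "gB")
  expect_identical(out$origin[out$hybrid_id == "h2"], "homolog-group")
  expect_identical(out$category[out$hybrid_id == "h4"],
                   "SUBTHRESHOLD_IDENTITY")
  ## copy number now includes the propagated members
  expect_identical(copy_numbers(out)$copy_number, 3L)
})

test_that("hybrid homolog groups join inherited paralogs across parents", {
  ## two parent-A paralogs (pyruvate-carboxylase style), each parent-A gene
  ## a cross-parent ortholog of a parent-B gene; hybrid carries all four
  a <- data.frame(
    hybrid_id = paste0("h", 1:4), category = "ASSIGNED",
    parent_label = c("A", "A", "B", "B"),
    parental_gene_id = c("YGL062W", "YBR218C", "XP_018222170.1",
                         "XP_018223247.1"),
    pident = 99, origin = "ortholog", tied_parents = NA_character_,
    stringsAsFactors = FALSE)
  parent_pairs <- list(A = pairs_df("YBR218C", "YGL062W", ga = "A",
                                    gb = "A"))
  cross <- pairs_df(c("YGL062W", "YBR218C"),
                    c("XP_018222170.1", "XP_018223247.1"),
                    ga = "A", gb = "B")
  g <- hybrid_homolog_groups(pairs_df(character(0), character(0)),
                             parent_pairs, cross, a)
  expect_identical(length(g), 1L)
  expect_identical(g[[1]], paste0("h", 1:4))
  ann <- attr(g, "annotation")
  expect_identical(sort(ann$parental_gene_id), sort(a$parental_gene_id))

  ## no edges -> no groups
  g0 <- hybrid_homolog_groups(pairs_df(character(0), character(0)),
                              NULL, NULL, a)
  expect_identical(length(g0), 0L)

  ## layers are configurable: self-only ignores the parental evidence
  g1 <- hybrid_homolog_groups(pairs_df(character(0), character(0)),
                              parent_pairs, cross, a, layers = "self")
  expect_identical(length(g1), 0L)
})

test_that("layered random graphs match the transitive-closure oracle", {
  for (seed in 1:10) {
    set.seed(seed + 31)
    ids <- sprintf("h%02d", 1:30)
    a <- data.frame(hybrid_id = ids, category = "ASSIGNED",
                    parent_label = sample(c("A", "B"), 30, TRUE),
                    parental_gene_id = paste0("g", sample.int(20, 30, TRUE)),
                    pident = 95, origin = "ortholog",
                    tied_parents = NA_character_, stringsAsFactors = FALSE)
    selfp <- pairs_df(sample(ids, 10, TRUE), sample(ids, 10, TRUE),
                      ga = "hybrid", gb = "hybrid")
    selfp <- selfp[selfp$id_a != selfp$id_b, ]
    genesA <- unique(a$parental_gene_id[a$parent_label == "A"])
    pp <- if (length(genesA) >= 4) {
      list(A = pairs_df(sample(genesA, 2), sample(genesA, 2), ga = "A",
                        gb = "A"))
    } else NULL
    g <- hybrid_homolog_groups(selfp, pp, NULL, a)
    ## oracle: expand the same two layers by hand, then close transitively
    edges <- selfp[, c("id_a", "id_b")]
    if (!is.null(pp)) {
      for (i in seq_len(nrow(pp$A))) {
        ha <- a$hybrid_id[a$parental_gene_id == pp$A$id_a[i]]
        hb <- a$hybrid_id[a$parental_gene_id == pp$A$id_b[i]]
        if (length(ha) && length(hb)) {
          edges <- rbind(edges, expand.grid(id_a = ha, id_b = hb,
                                            stringsAsFactors = FALSE))
        }
      }
    }
    edges <- edges[edges$id_a != edges$id_b, ]
    want <- oracle_components(edges)
    expect_identical(unname(lapply(g, identity)), want)
  }
})

test_that("shared-function report counts the Venn regions", {
  a <- data.frame(hybrid_id = c("h1", "h2", "h3"), category = "ASSIGNED",
                  parent_label = c("A", "B", "A"),
                  parental_gene_id = c("a1", "b1", "a2"),
                  pident = 95, origin = "ortholog",
                  tied_parents = NA_character_, stringsAsFactors = FALSE)
  cross <- pairs_df("a1", "b1", ga = "A", gb = "B")
  rep <- shared_function_report(a, cross)
  get <- function(m) rep$count[rep$metric == m]
  expect_identical(get("both_retained_pairs"), 1L)
  expect_identical(get("A_only"), 1L)   # a2
  expect_identical(get("B_only"), 0L)

  ## only one side retained
  a1 <- a[1, ]
  rep <- shared_function_report(a1, cross)
  expect_identical(rep$count[rep$metric == "A_only"], 1L)
  expect_identical(rep$count[rep$metric == "both_retained_pairs"], 0L)

  a$parent_label <- c("A", "B", "C")
  expect_error(shared_function_report(a, cross), "exactly 2 parents")
})
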