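# ortholog/WGD/tandem pair derivation, fractionation, array dating

test_that("orthologs_from_blocks labels anchors with their subgenome", {
  bl <- list(blocks = data.frame(
    block_id = c("blk0001", "blk0002", "blk0003"),
    ref_chrom = "R1", desc_chrom = c("D1", "D2", "D3"),
    orientation = "same", n_anchors = c(3L, 2L, 2L),
    score = c(30, 20, 10), bitscore = c(300, 200, 100),
    ref_rank_min = c(0, 0, 0), ref_rank_max = c(9, 9, 9),
    desc_rank_min = 0, desc_rank_max = 9,
    ref_span_bp = NA_real_, desc_span_bp = NA_real_,
    stringsAsFactors = FALSE),
    anchors = data.frame(
      ref_gene_id = c("r1", "r2", "r3", "r1", "r2", "r1", "r3"),
      desc_gene_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c3"),
      ref_chrom = "R1", desc_chrom = c("D1", "D1", "D1", "D2", "D2",
                                       "D3", "D3"),
      ref_rank = c(0, 4, 9, 0, 4, 0, 9), desc_rank = c(0, 1, 2, 0, 1, 0, 1),
      score = c(100, 90, 80, 70, 60, 50, 40),
      block_id = c("blk0001", "blk0001", "blk0001", "blk0002", "blk0002",
                   "blk0003", "blk0003"),
      stringsAsFactors = FALSE))
  class(bl) <- "synteny_blocks"
  asn <- partition_subgenomes(bl)
  o <- orthologs_from_blocks(asn, bl)
  # blk0003 is unassigned (third overlapping block): its anchors yield none
  expect_equal(nrow(o), 5)
  expect_false(any(o$desc_gene %in% c("c1", "c3")))
  expect_setequal(o$subgenome[o$ref_gene == "r1"],
                  c("subgenome1", "subgenome2"))  # one pair per subgenome
  # wgd pairs: r1 and r2 co-retained; r3 only in subgenome1
  w <- wgd_pairs(o)
  expect_equal(nrow(w), 2)
  expect_setequal(w$context, c("r1", "r2"))
  expect_equal(sort(unlist(w[w$context == "r1", c("gene_a", "gene_b")],
                           use.names = FALSE)), c("a1", "b1"))
})

test_that("wgd_pairs keeps the best-scoring anchor per ref gene and subgenome", {
  o <- ortho_pairs(ref_gene = c("r1", "r1", "r1"),
                   desc_gene = c("dA", "dB", "dC"),
                   subgenome = c("subgenome1", "subgenome1", "subgenome2"),
                   score = c(50, 90, 70))
  w <- wgd_pairs(o)
  expect_equal(nrow(w), 1)
  expect_setequal(unlist(w[, c("gene_a", "gene_b")], use.names = FALSE),
                  c("dB", "dC"))
  expect_equal(nrow(wgd_pairs(o[0, ])), 0)
  # one-sided retention produces no duplicate pair
  expect_equal(nrow(wgd_pairs(ortho_pairs("r1", "d1", "subgenome1"))), 0)
})

test_that("fractionation identities reproduce the published worked example", {
  fr <- fractionation_counts(3656, 3512, 1236)
  expect_equal(fr$fractionated, 4696)
  expect_equal(fr$distinct_ref_genes, 5932)
  expect_equal(round(fr$pct_fractionated, 2), 79.16)
})

test_that("fractionation identities hold for random ortholog tables", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:80, 1)
    refs <- sprintf("r%03d", seq_len(n))
    s1 <- refs[runif(n) < 0.6]
    s2 <- refs[runif(n) < 0.6]
    o <- ortho_pairs(c(s1, s2), paste0("d_", c(s1, s2)),
                     rep(c("subgenome1", "subgenome2"),
                         c(length(s1), length(s2))))
    fr <- fractionation_summary(o)
    expect_equal(fr$fractionated,
                 fr$retained_sub1 + fr$retained_sub2 - 2 * fr$co_retained)
    expect_equal(fr$distinct_ref_genes,
                 fr$retained_sub1 + fr$retained_sub2 - fr$co_retained)
    expect_equal(nrow(fr$status), fr$distinct_ref_genes)
    expect_equal(sum(fr$status$status == "co_retained"), fr$co_retained)
    # wgd pair count bounded by min per-subgenome retention
    expect_lte(nrow(wgd_pairs(o)), min(fr$retained_sub1, fr$retained_sub2))
  }
  empty <- fractionation_summary(ortho_pairs(character(0), character(0),
                                             character(0)))
  expect_equal(empty$distinct_ref_genes, 0)
  expect_equal(empty$pct_fractionated, 0)
  two <- fractionation_summary(ortho_pairs(
    c("r1", "r1", "r2", "r2"), c("a", "b", "c", "d"),
    rep(c("subgenome1", "subgenome2"), 2)))
  expect_equal(two$fractionated, 0)
  expect_equal(two$pct_fractionated, 0)
})

tandem_fixture <- function(gene_chrom_rank, edges) {
  genes <- data.frame(gene_id = names(gene_chrom_rank),
                      chromosome = vapply(gene_chrom_rank, `[[`, "", 1),
                      start = NA_integer_, end = NA_integer_, strand = "+",
                      stringsAsFactors = FALSE)
  ord <- as.integer(vapply(gene_chrom_rank, `[[`, "", 2))
  genes$start <- ord * 1000L
  genes$end <- ord * 1000L + 500L
  gi <- gene_index(genes, "desc")
  h <- make_hits(vapply(edges, `[[`, "", 1), vapply(edges, `[[`, "", 2))
  list(gi = gi, hits = h)
}

test_that("tandem arrays are homology connected components within rank reach", {
  fx <- tandem_fixture(
    list(g1 = c("c1", "1"), g2 = c("c1", "2"), g3 = c("c1", "3"),
         x1 = c("c1", "4"), x2 = c("c1", "5"), x3 = c("c1", "6"),
         x4 = c("c1", "7"), x5 = c("c1", "8"), x6 = c("c1", "9"),
         far = c("c1", "10")),
    list(c("g1", "g2"), c("g2", "g3"),      # chain, no g1-g3 edge
         c("x1", "far")))                   # 5 intervening genes
  arr <- detect_tandem_arrays(fx$gi, fx$hits, max_intervening = 1)
  expect_equal(nrow(arr$arrays), 1)
  expect_equal(arr$arrays$n_members, 3)     # transitive closure g1,g2,g3
  expect_equal(arr$arrays$members, "g1,g2,g3")
  # distant homologs never form an array at max_intervening = 1
  expect_false(any(grepl("far", arr$arrays$members)))
})

test_that("adjacent mutually homologous genes form one array", {
  fx <- tandem_fixture(
    list(a = c("c1", "1"), b = c("c1", "2"), c = c("c1", "3")),
    list(c("a", "b"), c("b", "c"), c("a", "c")))
  arr <- detect_tandem_arrays(fx$gi, fx$hits)
  expect_equal(arr$arrays$n_members, 3)
})

test_that("expand_array_pairs emits every member combination", {
  fx <- tandem_fixture(
    stats::setNames(lapply(1:19, function(i) c(if (i <= 3) "c1" else "c2",
                                               as.character(i))),
                    c(paste0("t", 1:3), paste0("u", 1:16))),
    c(list(c("t1", "t2"), c("t2", "t3")),
      lapply(1:15, function(i) c(paste0("u", i), paste0("u", i + 1)))))
  arr <- detect_tandem_arrays(fx$gi, fx$hits)
  expect_equal(sort(arr$arrays$n_members), c(3L, 16L))
  pairs <- expand_array_pairs(arr)
  # 3 -> 3 pairs; 16 -> C(16,2) = 120 pairs
  expect_equal(as.integer(table(pairs$context)[arr$arrays$array_id]),
               ifelse(arr$arrays$n_members == 3, 3L, 120L))
  expect_equal(nrow(pairs),
               sum(choose(arr$arrays$n_members, 2)))
  expect_true(all(pairs$gene_a < pairs$gene_b))
  expect_false(any(duplicated(pairs[, c("gene_a", "gene_b")])))
})

test_that("tandem pair count identity holds on the synthetic genome", {
  sim <- small_sim()
  arr <- detect_tandem_arrays(sim$desc_index, sim_hits(sim))
  pairs <- expand_array_pairs(arr)
  expect_equal(nrow(pairs), sum(choose(arr$arrays$n_members, 2)))
})

test_that("array dating follows the every-member-anchored rule", {
  fx <- tandem_fixture(
    list(a1 = c("c1", "1"), a2 = c("c1", "2"),
         b1 = c("c1", "5"), b2 = c("c1", "6")),
    list(c("a1", "a2"), c("b1", "b2")))
  arr <- detect_tandem_arrays(fx$gi, fx$hits)
  expect_equal(nrow(arr$arrays), 2)
  # a1+a2 anchored in subgenome1; only b1 anchored
  o <- ortho_pairs(c("r1", "r2", "r3"), c("a1", "a2", "b1"),
                   rep("subgenome1", 3))
  dat <- date_tandem_arrays(arr, o)
  d <- dat$dating
  expect_equal(d$dating[grepl("a1", arr$arrays$members[match(d$array_id,
               arr$arrays$array_id)])], "pre_wgd")
  expect_setequal(d$dating, c("pre_wgd", "post_wgd"))
  expect_equal(d$subgenome[d$dating == "pre_wgd"], "subgenome1")
  expect_equal(dat$counts$n_genes_pre, 2)
})

test_that("pre-WGD gene counts add up as in the published two-gene arrays", {
  # 36 two-gene arrays anchored in subgenome1 + 27 in subgenome2 -> 126 genes
  n1 <- 36
  n2 <- 27
  ranks <- list()
  edges <- list()
  genes <- character(0)
  for (i in seq_len(n1 + n2)) {
    g1 <- sprintf("t%03da", i)
    g2 <- sprintf("t%03db", i)
    ranks[[g1]] <- c("c1", as.character(10 * i))
    ranks[[g2]] <- c("c1", as.character(10 * i + 1))
    edges[[i]] <- c(g1, g2)
    genes <- c(genes, g1, g2)
  }
  fx <- tandem_fixture(ranks, edges)
  arr <- detect_tandem_arrays(fx$gi, fx$hits)
  expect_equal(nrow(arr$arrays), n1 + n2)
  sub <- rep(c("subgenome1", "subgenome2"), c(2 * n1, 2 * n2))
  o <- ortho_pairs(sprintf("r%03d", seq_along(genes)), genes, sub)
  dat <- date_tandem_arrays(arr, o)
  expect_equal(dat$counts$n_arrays_pre, 63)
  expect_equal(dat$counts$n_genes_pre, 126)
  expect_equal(dat$counts$pre_by_subgenome$subgenome1$n_arrays, n1)
  expect_equal(dat$counts$pre_by_subgenome$subgenome2$n_genes, 2 * n2)
})
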