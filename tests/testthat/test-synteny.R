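# anchors, chain DP (with brute-force oracle), subgenome partition, coverage

test_that("build_anchors keeps inter-genome hits only and inherits bitscore", {
  ref <- make_index("ref", "R1", 6, prefix = "r")
  desc <- make_index("desc", "D1", 6, prefix = "d")
  h <- make_hits(
    query = c("r_R1_01", "r_R1_02", "r_R1_03", "r_R1_04", "d_D1_05",
              "r_R1_01", "d_D1_01", "d_D1_03"),
    subject = c("d_D1_01", "d_D1_02", "d_D1_03", "d_D1_04", "r_R1_05",
                "r_R1_02", "d_D1_02", "d_D1_04"),
    bitscore = c(100, 110, 120, 130, 140, 150, 160, 170))
  a <- build_anchors(h, ref, desc)
  # 5 inter-genome hits (one given desc-first) survive; 3 intra-genome drop
  expect_equal(nrow(a), 5)
  expect_equal(a$score[a$ref_gene_id == "r_R1_01"], 100)
  expect_equal(a$score[a$ref_gene_id == "r_R1_05"], 140)
  expect_error(build_anchors(make_hits("r_R1_01", "nope"), ref, desc),
               "unknown gene id")
  empty <- build_anchors(make_hits(character(0), character(0)), ref, desc)
  expect_equal(nrow(empty), 0)
})

test_that("chain_blocks honors min_block_size on perfectly collinear runs", {
  p <- chain_params(min_block_size = 15)
  b15 <- chain_blocks(anchor_frame(0:14, 0:14), p)
  expect_equal(nrow(b15$blocks), 1)
  expect_equal(b15$blocks$n_anchors, 15)
  expect_equal(b15$blocks$orientation, "same")
  b14 <- chain_blocks(anchor_frame(0:13, 0:13), p)
  expect_equal(nrow(b14$blocks), 0)
  expect_equal(nrow(chain_blocks(anchor_frame(integer(0), integer(0)),
                                 p)$blocks), 0)
})

test_that("interleaved direct and inverted runs are resolved as two blocks", {
  # direct run at even ranks, inverted run at odd ranks
  p <- chain_params(min_block_size = 5, max_gap = 10)
  a <- anchor_frame(ref_rank = c(seq(0, 18, 2), seq(1, 19, 2)),
                    desc_rank = c(seq(0, 18, 2) + 30, seq(40, 22, -2)),
                    score = round(runif(20, 50, 150), 3))
  got <- chain_blocks(a, p)
  expect_equal(nrow(got$blocks), 2)
  expect_setequal(got$blocks$orientation, c("same", "inverted"))
  orc <- oracle_decompose(a, p)
  expect_equal(sort(got$blocks$score),
               sort(vapply(orc, function(b) b$sc, 1)))
  orc_sets <- lapply(orc, function(b) {
    sort(paste(a$ref_rank[b$idx], a$desc_rank[b$idx]))
  })
  got_sets <- lapply(split(got$anchors, got$anchors$block_id), function(x) {
    sort(paste(x$ref_rank, x$desc_rank))
  })
  expect_setequal(unname(got_sets), orc_sets)
})

test_that("chain decomposition equals exhaustive enumeration on random instances", {
  set.seed(902)
  p <- chain_params(min_block_size = 3, max_gap = 6)
  for (i in 1:60) {
    a <- random_anchor_frame(sample(4:12, 1))
    a <- a[!duplicated(a[, c("ref_rank", "desc_rank")]), , drop = FALSE]
    got <- chain_blocks(a, p)
    orc <- oracle_decompose(a, p)
    expect_equal(sort(got$blocks$score),
                 sort(vapply(orc, function(b) b$sc, 1)),
                 info = sprintf("instance %d", i))
  }
})

test_that("anchors are conserved and min_block_size is monotone", {
  set.seed(903)
  for (i in 1:10) {
    a <- random_anchor_frame(12, max_rank = 20)
    a <- a[!duplicated(a[, c("ref_rank", "desc_rank")]), , drop = FALSE]
    n_prev <- Inf
    for (mbs in c(2, 3, 5, 8)) {
      b <- chain_blocks(a, chain_params(min_block_size = mbs, max_gap = 8))
      expect_lte(nrow(b$blocks), n_prev)
      n_prev <- nrow(b$blocks)
      # each anchor in at most one block
      expect_false(any(duplicated(
        b$anchors[, c("ref_gene_id", "desc_gene_id")])))
    }
  }
})

test_that("chaining is invariant to anchor row order", {
  set.seed(904)
  a <- random_anchor_frame(12, max_rank = 18)
  a <- a[!duplicated(a[, c("ref_rank", "desc_rank")]), , drop = FALSE]
  p <- chain_params(min_block_size = 3, max_gap = 8)
  b1 <- chain_blocks(a, p)
  b2 <- chain_blocks(a[sample.int(nrow(a)), , drop = FALSE], p)
  expect_equal(b1$blocks, b2$blocks)
  expect_equal(b1$anchors[order(b1$anchors$ref_rank, b1$anchors$desc_rank), ],
               b2$anchors[order(b2$anchors$ref_rank, b2$anchors$desc_rank), ],
               ignore_attr = TRUE)
})

make_blocks <- function(spec) {
  # spec: list of c(ref_min, ref_max, score)
  blocks <- do.call(rbind, lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    data.frame(block_id = sprintf("blk%04d", i), ref_chrom = "R1",
               desc_chrom = sprintf("D%d", i), orientation = "same",
               n_anchors = s[3], score = s[3], bitscore = s[3] * 10,
               ref_rank_min = s[1], ref_rank_max = s[2],
               desc_rank_min = 0, desc_rank_max = s[2] - s[1],
               ref_span_bp = NA_real_, desc_span_bp = (s[2] - s[1] + 1) * 1e3,
               stringsAsFactors = FALSE)
  }))
  anchors <- do.call(rbind, lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    k <- s[3]
    data.frame(ref_gene_id = sprintf("r%d_%d", i, 1:k),
               desc_gene_id = sprintf("d%d_%d", i, 1:k),
               ref_chrom = "R1", desc_chrom = sprintf("D%d", i),
               ref_rank = seq(s[1], s[2], length.out = k),
               desc_rank = seq_len(k), score = 100,
               block_id = sprintf("blk%04d", i), stringsAsFactors = FALSE)
  }))
  structure(list(blocks = blocks, anchors = anchors,
                 params = chain_params(min_block_size = 2)),
            class = "synteny_blocks")
}

test_that("partition: overlapping blocks split across subgenomes by score", {
  # three mutually overlapping blocks, scores 30 > 20 > 10
  bl <- make_blocks(list(c(0, 50, 30), c(10, 60, 20), c(20, 70, 10)))
  asn <- partition_subgenomes(bl)
  expect_equal(asn$table$subgenome,
               c("subgenome1", "subgenome2", "unassigned"))
  expect_true(asn$table$curated_out[3])
  # two equal blocks on the same interval: one each
  bl2 <- make_blocks(list(c(0, 50, 20), c(0, 50, 20)))
  expect_setequal(partition_subgenomes(bl2)$table$subgenome,
                  c("subgenome1", "subgenome2"))
  # a lone block goes to subgenome1 after harmonization
  bl3 <- make_blocks(list(c(0, 50, 20)))
  expect_equal(partition_subgenomes(bl3)$table$subgenome, "subgenome1")
})

test_that("subgenome1 is harmonized to carry the larger anchor total", {
  # non-overlapping clusters; second cluster's lone block is bigger
  bl <- make_blocks(list(c(0, 10, 5), c(0, 10, 4), c(100, 160, 40)))
  asn <- partition_subgenomes(bl)
  big <- asn$table$subgenome[asn$table$block_id == "blk0003"]
  expect_equal(big, "subgenome1")
  tot <- asn$totals
  expect_gte(tot$n_anchors[tot$subgenome == "subgenome1"],
             tot$n_anchors[tot$subgenome == "subgenome2"])
})

test_that("synteny_coverage reproduces published-style percentages", {
  cov <- synteny_coverage(n_blocks = c(82, 87),
                          genomic_length_mb = c(57.22, 68.66),
                          n_genes = c(7450, 7958),
                          genome_mb = 274, genome_genes = 27148)
  tot <- cov[cov$category == "total", ]
  expect_equal(tot$n_blocks, 169)
  expect_equal(tot$genomic_length_mb, 125.88)
  expect_equal(round(tot$pct_genome_length, 2), 45.94)
  expect_equal(round(tot$pct_genome_genes, 2), 56.76)
  expect_error(synteny_coverage(1, 1, 1, 0, 10), "zero-length")
})

test_that("block_stats counts descendant genes inside block spans", {
  sim <- small_sim()
  hits <- sim_hits(sim)
  anchors <- build_anchors(hits, sim$ref_index, sim$desc_index)
  blocks <- chain_blocks(anchors, chain_params(), sim$ref_index,
                         sim$desc_index)
  asn <- partition_subgenomes(blocks)
  cov <- block_stats(asn, blocks, sim$desc_index)
  tot <- cov[cov$category == "total", ]
  expect_gt(tot$pct_genome_genes, 50)
  expect_lte(tot$pct_genome_genes, 100)
  expect_gte(tot$n_genes, tot$n_anchor_genes * 0)
  # empty assignment -> zero coverage
  empty <- chain_blocks(anchor_frame(integer(0), integer(0)), chain_params())
  asn0 <- partition_subgenomes(empty)
  cov0 <- block_stats(asn0, empty, sim$desc_index)
  expect_equal(cov0$n_blocks, c(0, 0, 0))
  expect_equal(cov0$pct_genome_genes[3], 0)
})
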