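# Small in-code fixtures shared across tests.

make_index <- function(label = "g", chroms = "c1", n_per_chrom = 5,
                       prefix = label, spacing = 1000, len = 300) {
  rows <- list()
  for (ch in chroms) {
    for (i in seq_len(n_per_chrom)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("%s_%s_%02d", prefix, ch, i), chromosome = ch,
        start = (i - 1) * spacing + 1, end = (i - 1) * spacing + len,
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  gene_index(do.call(rbind, rows), label)
}

make_hits <- function(query, subject, evalue = 1e-30, bitscore = 100) {
  n <- length(query)
  filter_hits(data.frame(query_id = query, subject_id = subject,
                         evalue = rep_len(evalue, n),
                         bitscore = rep_len(bitscore, n),
                         stringsAsFactors = FALSE))
}

anchor_frame <- function(ref_rank, desc_rank, score = 100,
                         ref_chrom = "R1", desc_chrom = "D1") {
  n <- length(ref_rank)
  structure(data.frame(
    ref_gene_id = sprintf("r%03d", seq_len(n)),
    desc_gene_id = sprintf("d%03d", seq_len(n)),
    ref_chrom = rep_len(ref_chrom, n), desc_chrom = rep_len(desc_chrom, n),
    ref_rank = ref_rank, desc_rank = desc_rank,
    score = rep_len(score, n), stringsAsFactors = FALSE),
    class = c("anchor_set", "data.frame"))
}

# gene_pairs row builder for ortholog tables
ortho_pairs <- function(ref_gene, desc_gene, subgenome, score = 100) {
  ga <- pmin(ref_gene, desc_gene)
  gb <- pmax(ref_gene, desc_gene)
  n <- length(ref_gene)
  structure(data.frame(gene_a = ga, gene_b = gb,
                       pair_type = rep("ortholog", n),
                       context = subgenome, ref_gene = ref_gene,
                       desc_gene = desc_gene, subgenome = subgenome,
                       score = rep_len(score, n),
                       block_id = rep("blk0001", n),
                       stringsAsFactors = FALSE),
            class = c("gene_pairs", "data.frame"))
}

# memoized small synthetic dataset used by several files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genomes(evolution_params(
        seed = 7, n_ref_genes = 250, n_chromosomes = 2,
        n_tandem_arrays = 15, gene_length_codons = 120))
    }
    cache
  }
})

sim_hits <- function(sim) {
  filter_hits(stats::setNames(sim$hits_raw[, c(1, 2, 11, 12)],
                              c("query_id", "subject_id", "evalue",
                                "bitscore")))
}
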