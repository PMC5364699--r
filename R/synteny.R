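# Collinear block detection by anchor chaining, subgenome partition and
# coverage statistics.
#
# Chain scoring: a chain of anchors (strictly increasing reference ranks;
# descendant ranks strictly increasing for "same" orientation, strictly
# decreasing for "inverted") scores
#   n_anchors * match_score + gap_penalty * sum((ref_gap - 1) + (desc_gap - 1))
# over consecutive anchor steps, where each rank gap must be <= max_gap in
# both genomes. Anchor bitscores only break ties between equal-score chains.

#' Chaining parameters
#'
#' @param max_evalue e-value threshold applied upstream to the hit table.
#' @param min_block_size minimum anchors per retained block.
#' @param max_gap maximum rank gap (in genes) allowed between consecutive
#'   anchors, in either genome.
#' @param gap_penalty score penalty per rank-gap unit beyond adjacency
#'   (negative; the "u = 1" unit penalty).
#' @param match_score score per anchor. The default 50 follows MCScanX's
#'   match score: with a unit gap penalty, a match score of 1 makes the
#'   expected chain score per anchor roughly zero at realistic fractionation
#'   levels (about half of all duplicate copies lost), shattering blocks.
#' @return list of class `chain_params`.
#' @export
chain_params <- function(max_evalue = 1e-20, min_block_size = 15,
                         max_gap = 25, gap_penalty = -1, match_score = 50) {
  stopifnot(min_block_size >= 2, max_gap >= 1)
  structure(list(max_evalue = max_evalue,
                 min_block_size = as.integer(min_block_size),
                 max_gap = as.integer(max_gap),
                 gap_penalty = gap_penalty, match_score = match_score),
            class = "chain_params")
}

#' Build synteny anchors from inter-genome hits
#'
#' One anchor per retained hit joining a reference gene to a descendant gene;
#' intra-genome hits are excluded here (they feed tandem-array detection
#' instead). The anchor inherits the hit bitscore as its score.
#'
#' @param hits a `homolog_hits` table (already e-value filtered).
#' @param ref,desc `gene_index` objects for the two genomes.
#' @return data.frame of class `anchor_set` with one row per anchor.
#' @export
build_anchors <- function(hits, ref, desc) {
  rg <- ref$genes
  dg <- desc$genes
  in_ref_q <- hits$query_id %in% rg$gene_id
  in_ref_s <- hits$subject_id %in% rg$gene_id
  in_desc_q <- hits$query_id %in% dg$gene_id
  in_desc_s <- hits$subject_id %in% dg$gene_id
  unknown <- !(in_ref_q | in_desc_q) | !(in_ref_s | in_desc_s)
  if (any(unknown)) {
    ids <- unique(c(hits$query_id[!(in_ref_q | in_desc_q)],
                    hits$subject_id[!(in_ref_s | in_desc_s)]))
    stop("hit(s) reference unknown gene id(s): ",
         paste(utils::head(ids, 10), collapse = ", "))
  }
  inter_qr <- in_ref_q & in_desc_s
  inter_qd <- in_desc_q & in_ref_s
  ref_id <- c(hits$query_id[inter_qr], hits$subject_id[inter_qd])
  desc_id <- c(hits$subject_id[inter_qr], hits$query_id[inter_qd])
  score <- c(hits$bitscore[inter_qr], hits$bitscore[inter_qd])
  ri <- match(ref_id, rg$gene_id)
  di <- match(desc_id, dg$gene_id)
  anchors <- data.frame(ref_gene_id = ref_id, desc_gene_id = desc_id,
                        ref_chrom = rg$chromosome[ri],
                        desc_chrom = dg$chromosome[di],
                        ref_rank = rg$rank[ri], desc_rank = dg$rank[di],
                        score = score, stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$ref_chrom, anchors$desc_chrom,
                           anchors$ref_rank, anchors$desc_rank), , drop = FALSE]
  rownames(anchors) <- NULL
  structure(anchors, class = c("anchor_set", "data.frame"))
}

# Best chain among `a` (rows of an anchor frame, one chromosome pair) for one
# orientation. Returns list(score, bitscore, idx) or NULL. `a` must be sorted
# by (ref_rank, desc_rank).
best_chain_dp <- function(a, params, orientation) {
  n <- nrow(a)
  if (n == 0) return(NULL)
  dr <- if (orientation == "same") a$desc_rank else -a$desc_rank
  match_score <- params$match_score
  gap_penalty <- params$gap_penalty
  max_gap <- params$max_gap
  score <- rep(match_score, n)
  bits <- a$score
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    gr <- a$ref_rank[i] - a$ref_rank[j]
    gd <- dr[i] - dr[j]
    ok <- gr >= 1L & gr <= max_gap & gd >= 1 & gd <= max_gap
    if (!any(ok)) next
    j <- j[ok]
    cand <- score[j] + match_score + gap_penalty * ((gr[ok] - 1) + (gd[ok] - 1))
    best <- max(cand)
    if (best < match_score) next                  # starting fresh is better
    tie <- j[cand == best]
    pick <- tie[which.max(bits[tie])]             # tie-break on chain bitscore
    score[i] <- best
    bits[i] <- bits[pick] + a$score[i]
    prev[i] <- pick
  }
  end_best <- max(score)
  ends <- which(score == end_best)
  end <- ends[which.max(bits[ends])]
  idx <- integer(0)
  k <- end
  while (k != 0L) {
    idx <- c(k, idx)
    k <- prev[k]
  }
  list(score = score[end], bitscore = bits[end], idx = idx,
       orientation = orientation)
}

# Best chain over both orientations; "same" preferred on exact ties.
best_chain <- function(a, params) {
  s <- best_chain_dp(a, params, "same")
  v <- best_chain_dp(a, params, "inverted")
  if (is.null(s)) return(v)
  if (is.null(v)) return(s)
  if (v$score > s$score ||
      (v$score == s$score && v$bitscore > s$bitscore)) v else s
}

#' Chain anchors into collinear blocks
#'
#' Per (reference chromosome, descendant chromosome) pair and orientation, a
#' maximal-score chain decomposition by dynamic programming: the highest
#' scoring chain is extracted, its anchors removed, and the process repeats
#' until no anchors remain. Extracted chains with fewer than
#' `min_block_size` anchors are discarded; every anchor therefore ends up in
#' at most one block.
#'
#' @param anchors an `anchor_set`.
#' @param params a [chain_params()].
#' @param ref,desc optional `gene_index` objects; when supplied, block spans
#'   in bp are computed from gene coordinates.
#' @return list of class `synteny_blocks` with elements `blocks` (one row per
#'   block) and `anchors` (anchors tagged with `block_id`).
#' @export
chain_blocks <- function(anchors, params = chain_params(),
                         ref = NULL, desc = NULL) {
  blocks <- list()
  kept_anchors <- list()
  nb <- 0L
  if (nrow(anchors) > 0) {
    groups <- split(seq_len(nrow(anchors)),
                    paste(anchors$ref_chrom, anchors$desc_chrom, sep = "\r"))
    for (g in groups[order(names(groups))]) {
      a <- anchors[g, , drop = FALSE]
      a <- a[order(a$ref_rank, a$desc_rank), , drop = FALSE]
      repeat {
        if (nrow(a) == 0) break
        ch <- best_chain(a, params)
        take <- a[ch$idx, , drop = FALSE]
        a <- a[-ch$idx, , drop = FALSE]
        if (length(ch$idx) >= params$min_block_size) {
          nb <- nb + 1L
          take$block_id <- sprintf("blk%04d", nb)
          kept_anchors[[nb]] <- take
          blocks[[nb]] <- data.frame(
            block_id = take$block_id[1],
            ref_chrom = take$ref_chrom[1], desc_chrom = take$desc_chrom[1],
            orientation = ch$orientation, n_anchors = nrow(take),
            score = ch$score, bitscore = ch$bitscore,
            ref_rank_min = min(take$ref_rank), ref_rank_max = max(take$ref_rank),
            desc_rank_min = min(take$desc_rank),
            desc_rank_max = max(take$desc_rank),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  blocks <- if (nb > 0) do.call(rbind, blocks) else
    data.frame(block_id = character(0), ref_chrom = character(0),
               desc_chrom = character(0), orientation = character(0),
               n_anchors = integer(0), score = numeric(0), bitscore = numeric(0),
               ref_rank_min = integer(0), ref_rank_max = integer(0),
               desc_rank_min = integer(0), desc_rank_max = integer(0),
               stringsAsFactors = FALSE)
  anchor_tab <- if (nb > 0) do.call(rbind, kept_anchors) else
    cbind(anchors[0, , drop = FALSE], block_id = character(0))
  rownames(blocks) <- rownames(anchor_tab) <- NULL
  blocks$ref_span_bp <- rep(NA_real_, nrow(blocks))
  blocks$desc_span_bp <- rep(NA_real_, nrow(blocks))
  if (!is.null(ref) && !is.null(desc) && nb > 0) {
    blocks$ref_span_bp <- rank_span_bp(ref, blocks$ref_chrom,
                                       blocks$ref_rank_min, blocks$ref_rank_max)
    blocks$desc_span_bp <- rank_span_bp(desc, blocks$desc_chrom,
                                        blocks$desc_rank_min,
                                        blocks$desc_rank_max)
  }
  # renumber blocks deterministically by genomic position
  ord <- order(blocks$ref_chrom, blocks$ref_rank_min, blocks$desc_chrom,
               blocks$desc_rank_min)
  old <- blocks$block_id[ord]
  new <- sprintf("blk%04d", seq_along(old))
  blocks <- blocks[ord, , drop = FALSE]
  blocks$block_id <- new
  anchor_tab$block_id <- new[match(anchor_tab$block_id, old)]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, anchors = anchor_tab, params = params),
            class = "synteny_blocks")
}

rank_span_bp <- function(index, chrom, rank_min, rank_max) {
  g <- index$genes
  key <- paste(g$chromosome, g$rank, sep = "\r")
  lo <- g$start[match(paste(chrom, rank_min, sep = "\r"), key)]
  hi <- g$end[match(paste(chrom, rank_max, sep = "\r"), key)]
  as.numeric(hi - lo + 1)
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("<synteny_blocks> ", nrow(x$blocks), " blocks, ",
      nrow(x$anchors), " anchors in blocks\n", sep = "")
  invisible(x)
}

#' Partition blocks into two non-overlapping subgenomes
#'
#' Blocks are clustered by reference-rank interval overlap (per reference
#' chromosome). Within each cluster, blocks are taken in order of descending
#' chain score (ties: total bitscore, then block id) and assigned to the
#' first subgenome whose already-assigned blocks they do not overlap on the
#' reference; blocks fitting neither subgenome stay `unassigned`. Labels are
#' harmonized genome-wide so that `subgenome1` carries the larger total
#' anchor count. Unassigned blocks whose reference span is >50% covered by a
#' higher-scoring assigned block are additionally flagged `curated_out` —
#' the automatic stand-in for manual curation.
#'
#' @param blocks a `synteny_blocks` object.
#' @param ref the reference `gene_index` (reserved; clustering is rank-based).
#' @return object of class `subgenome_assignment`: list with `table`
#'   (block_id, cluster, subgenome, curated_out), and per-subgenome totals.
#' @export
partition_subgenomes <- function(blocks, ref = NULL) {
  b <- blocks$blocks
  if (nrow(b) == 0) {
    tab <- data.frame(block_id = character(0), cluster = integer(0),
                      subgenome = character(0), curated_out = logical(0),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, totals = subgenome_totals(tab, blocks)),
                     class = "subgenome_assignment"))
  }
  b$cluster <- NA_integer_
  cl <- 0L
  for (chrom in unique(b$ref_chrom)) {
    i <- which(b$ref_chrom == chrom)
    i <- i[order(b$ref_rank_min[i], b$ref_rank_max[i])]
    cur_end <- -Inf
    for (k in i) {
      if (b$ref_rank_min[k] > cur_end) cl <- cl + 1L
      b$cluster[k] <- cl
      cur_end <- max(cur_end, b$ref_rank_max[k])
    }
  }
  b$subgenome <- "unassigned"
  for (c_id in unique(b$cluster)) {
    i <- which(b$cluster == c_id)
    i <- i[order(-b$score[i], -b$bitscore[i], b$block_id[i])]
    sub1 <- list()
    sub2 <- list()
    overlaps_any <- function(k, members) {
      any(vapply(members, function(m) {
        b$ref_rank_min[k] <= b$ref_rank_max[m] &&
          b$ref_rank_max[k] >= b$ref_rank_min[m]
      }, logical(1)))
    }
    for (k in i) {
      if (!overlaps_any(k, sub1)) {
        sub1 <- c(sub1, k); b$subgenome[k] <- "subgenome1"
      } else if (!overlaps_any(k, sub2)) {
        sub2 <- c(sub2, k); b$subgenome[k] <- "subgenome2"
      }
    }
  }
  # genome-wide harmonization: subgenome1 gets the larger anchor total
  n1 <- sum(b$n_anchors[b$subgenome == "subgenome1"])
  n2 <- sum(b$n_anchors[b$subgenome == "subgenome2"])
  if (n2 > n1) {
    s <- b$subgenome
    b$subgenome[s == "subgenome1"] <- "subgenome2"
    b$subgenome[s == "subgenome2"] <- "subgenome1"
  }
  # curation stand-in: unassigned blocks mostly covered by a better block
  b$curated_out <- FALSE
  for (k in which(b$subgenome == "unassigned")) {
    same <- which(b$ref_chrom == b$ref_chrom[k] & b$score > b$score[k] &
                    b$subgenome != "unassigned")
    if (length(same) == 0) next
    ov <- pmax(0, pmin(b$ref_rank_max[same], b$ref_rank_max[k]) -
                 pmax(b$ref_rank_min[same], b$ref_rank_min[k]) + 1)
    len <- b$ref_rank_max[k] - b$ref_rank_min[k] + 1
    if (any(ov / len > 0.5)) b$curated_out[k] <- TRUE
  }
  tab <- b[, c("block_id", "cluster", "subgenome", "curated_out")]
  rownames(tab) <- NULL
  structure(list(table = tab, totals = subgenome_totals(tab, blocks)),
            class = "subgenome_assignment")
}

subgenome_totals <- function(tab, blocks) {
  out <- lapply(c("subgenome1", "subgenome2"), function(sg) {
    ids <- tab$block_id[tab$subgenome == sg]
    bl <- blocks$blocks[blocks$blocks$block_id %in% ids, , drop = FALSE]
    an <- blocks$anchors[blocks$anchors$block_id %in% ids, , drop = FALSE]
    data.frame(subgenome = sg, n_blocks = nrow(bl),
               n_anchors = nrow(an),
               n_genes = length(unique(an$desc_gene_id)),
               genomic_length_bp = sum(bl$desc_span_bp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("<subgenome_assignment>\n")
  print(x$totals)
  invisible(x)
}

#' Coverage statistics for a subgenome partition
#'
#' The per-subgenome analogue of a "summary of syntenic regions" table:
#' number of blocks, summed descendant block span (Mb), descendant genes
#' inside block spans (plus anchor genes only, since either reading of a
#' "gene number" column is defensible), and percentages of the descendant
#' genome length and gene count.
#'
#' @param assignment a `subgenome_assignment`.
#' @param blocks the `synteny_blocks` the assignment was made from.
#' @param desc descendant `gene_index`.
#' @return data.frame of class `coverage_summary` with one row per subgenome
#'   plus a `total` row.
#' @export
block_stats <- function(assignment, blocks, desc) {
  if (desc$total_length_bp <= 0) stop("invalid input: zero-length genome")
  n_genome_genes <- nrow(desc$genes)
  dg <- desc$genes
  rows <- lapply(c("subgenome1", "subgenome2"), function(sg) {
    ids <- assignment$table$block_id[assignment$table$subgenome == sg]
    bl <- blocks$blocks[blocks$blocks$block_id %in% ids, , drop = FALSE]
    an <- blocks$anchors[blocks$anchors$block_id %in% ids, , drop = FALSE]
    in_span <- rep(FALSE, nrow(dg))
    for (i in seq_len(nrow(bl))) {
      in_span <- in_span | (dg$chromosome == bl$desc_chrom[i] &
                              dg$rank >= bl$desc_rank_min[i] &
                              dg$rank <= bl$desc_rank_max[i])
    }
    data.frame(category = sg, n_blocks = nrow(bl),
               genomic_length_mb = sum(bl$desc_span_bp) / 1e6,
               n_genes = sum(in_span),
               n_anchor_genes = length(unique(an$desc_gene_id)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  synteny_coverage(n_blocks = per$n_blocks,
                   genomic_length_mb = per$genomic_length_mb,
                   n_genes = per$n_genes,
                   genome_mb = desc$total_length_bp / 1e6,
                   genome_genes = n_genome_genes,
                   n_anchor_genes = per$n_anchor_genes)
}

#' Assemble a synteny coverage table from per-subgenome counts
#'
#' Pure arithmetic core of [block_stats()], usable directly on published
#' per-subgenome counts: appends a total row and the percentage of the
#' genome length and of the annotated gene count covered by blocks.
#'
#' @param n_blocks,genomic_length_mb,n_genes numeric vectors of length 2
#'   (subgenome1, subgenome2).
#' @param genome_mb assembled genome length in Mb.
#' @param genome_genes annotated gene count of the genome.
#' @param n_anchor_genes optional anchor-only gene counts.
#' @return `coverage_summary` data.frame; the total row carries
#'   `pct_genome_length` = 100 * total span / genome length and
#'   `pct_genome_genes` = 100 * total genes / genome genes.
#' @export
synteny_coverage <- function(n_blocks, genomic_length_mb, n_genes,
                             genome_mb, genome_genes, n_anchor_genes = NA) {
  if (genome_mb <= 0 || genome_genes <= 0) {
    stop("invalid input: zero-length genome")
  }
  per <- data.frame(category = c("subgenome1", "subgenome2"),
                    n_blocks = n_blocks,
                    genomic_length_mb = genomic_length_mb,
                    n_genes = n_genes,
                    n_anchor_genes = n_anchor_genes,
                    pct_genome_length = NA_real_, pct_genome_genes = NA_real_,
                    stringsAsFactors = FALSE)
  total <- data.frame(category = "total", n_blocks = sum(n_blocks),
                      genomic_length_mb = sum(genomic_length_mb),
                      n_genes = sum(n_genes),
                      n_anchor_genes = sum(n_anchor_genes),
                      pct_genome_length =
                        100 * sum(genomic_length_mb) / genome_mb,
                      pct_genome_genes = 100 * sum(n_genes) / genome_genes,
                      stringsAsFactors = FALSE)
  out <- rbind(per, total)
  attr(out, "genome_mb") <- genome_mb
  attr(out, "genome_genes") <- genome_genes
  class(out) <- c("coverage_summary", "data.frame")
  out
}
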