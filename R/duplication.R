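# Pair-class derivation: syntenic ortholog pairs, WGD duplicate pairs,
# tandem paralog pairs; fractionation accounting; pre-/post-WGD dating of
# tandem arrays.

canonical_pairs <- function(gene_a, gene_b) {
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  list(gene_a = gene_a, gene_b = gene_b)
}

#' Ortholog pairs from assigned synteny blocks
#'
#' One ortholog pair per anchor of every block assigned to a subgenome,
#' labeled with that subgenome; anchors of unassigned blocks yield no pairs.
#' A reference gene anchored in both subgenomes yields one pair per
#' subgenome.
#'
#' @param assignment a `subgenome_assignment`.
#' @param blocks the `synteny_blocks` it was computed from.
#' @return data.frame of class `gene_pairs` with columns `gene_a`, `gene_b`
#'   (canonical order), `pair_type = "ortholog"`, `context` (= subgenome),
#'   `ref_gene`, `desc_gene`, `subgenome`, `score`, `block_id`.
#' @export
orthologs_from_blocks <- function(assignment, blocks) {
  tab <- assignment$table
  assigned <- tab[tab$subgenome %in% c("subgenome1", "subgenome2"), ,
                  drop = FALSE]
  an <- blocks$anchors[blocks$anchors$block_id %in% assigned$block_id, ,
                       drop = FALSE]
  sg <- assigned$subgenome[match(an$block_id, assigned$block_id)]
  cp <- canonical_pairs(an$ref_gene_id, an$desc_gene_id)
  out <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                    pair_type = rep("ortholog", nrow(an)),
                    context = sg,
                    ref_gene = an$ref_gene_id, desc_gene = an$desc_gene_id,
                    subgenome = sg, score = an$score, block_id = an$block_id,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$gene_a, out$gene_b)), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gene_pairs", "data.frame"))
}

#' WGD duplicate pairs from co-retained orthologs
#'
#' For every reference gene with an ortholog in both subgenomes, emits the
#' descendant-descendant duplicate pair; when a reference gene has several
#' orthologs within one subgenome the best-scoring anchor defines the
#' ortholog (ties broken on lexicographic gene id).
#'
#' @param orthologs ortholog `gene_pairs` (from [orthologs_from_blocks()]).
#' @return `gene_pairs` with `pair_type = "wgd_duplicate"` and
#'   `context` = the shared reference gene id.
#' @export
wgd_pairs <- function(orthologs) {
  o <- as.data.frame(orthologs)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      pair_type = character(0), context = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(o) == 0) {
    return(structure(empty, class = c("gene_pairs", "data.frame")))
  }
  o <- o[order(-o$score, o$desc_gene), , drop = FALSE]
  best <- o[!duplicated(paste(o$ref_gene, o$subgenome)), , drop = FALSE]
  s1 <- best[best$subgenome == "subgenome1", , drop = FALSE]
  s2 <- best[best$subgenome == "subgenome2", , drop = FALSE]
  common <- intersect(s1$ref_gene, s2$ref_gene)
  if (length(common) == 0) {
    return(structure(empty, class = c("gene_pairs", "data.frame")))
  }
  d1 <- s1$desc_gene[match(common, s1$ref_gene)]
  d2 <- s2$desc_gene[match(common, s2$ref_gene)]
  cp <- canonical_pairs(d1, d2)
  out <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                    pair_type = "wgd_duplicate", context = common,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gene_pairs", "data.frame"))
}

#' Fractionation accounting over reference genes
#'
#' Per reference gene with at least one syntenic ortholog: co-retained if it
#' has orthologs in both subgenomes, otherwise retained only in one. The
#' count identities
#' `fractionated = retained_sub1 + retained_sub2 - 2 * co_retained` and
#' `distinct_ref_genes = retained_sub1 + retained_sub2 - co_retained`
#' hold by construction.
#'
#' @param orthologs ortholog `gene_pairs`.
#' @return object of class `fractionation_result` (see
#'   [fractionation_counts()]) plus a `status` data.frame
#'   (ref_gene, status in co_retained / only_sub1 / only_sub2).
#' @export
fractionation_summary <- function(orthologs) {
  o <- as.data.frame(orthologs)
  in1 <- unique(o$ref_gene[o$subgenome == "subgenome1"])
  in2 <- unique(o$ref_gene[o$subgenome == "subgenome2"])
  co <- intersect(in1, in2)
  status <- data.frame(
    ref_gene = c(co, setdiff(in1, co), setdiff(in2, co)),
    status = c(rep("co_retained", length(co)),
               rep("only_sub1", length(setdiff(in1, co))),
               rep("only_sub2", length(setdiff(in2, co)))),
    stringsAsFactors = FALSE)
  status <- status[order(status$ref_gene), , drop = FALSE]
  rownames(status) <- NULL
  res <- fractionation_counts(length(in1), length(in2), length(co))
  res$status <- status
  res
}

#' Fractionation count identities
#'
#' Arithmetic core of [fractionation_summary()], usable directly on
#' published counts: given the number of reference genes retained in each
#' subgenome and the co-retained count, derives the fractionated pair count,
#' the number of distinct reference genes, and the fractionation percentage
#' `100 * fractionated / distinct_ref_genes`.
#'
#' @param retained_sub1,retained_sub2 reference genes with an ortholog in
#'   subgenome 1 / 2 (co-retained genes count in both).
#' @param co_retained reference genes with orthologs in both subgenomes.
#' @return list of class `fractionation_result` with fields `retained_sub1`,
#'   `retained_sub2`, `co_retained`, `fractionated`, `distinct_ref_genes`,
#'   `pct_fractionated`.
#' @export
fractionation_counts <- function(retained_sub1, retained_sub2, co_retained) {
  stopifnot(co_retained <= retained_sub1, co_retained <= retained_sub2)
  fractionated <- retained_sub1 + retained_sub2 - 2L * co_retained
  distinct <- retained_sub1 + retained_sub2 - co_retained
  structure(list(retained_sub1 = retained_sub1,
                 retained_sub2 = retained_sub2,
                 co_retained = co_retained,
                 fractionated = fractionated,
                 distinct_ref_genes = distinct,
                 pct_fractionated =
                   if (distinct > 0) 100 * fractionated / distinct else 0),
            class = "fractionation_result")
}

#' @export
print.fractionation_result <- function(x, ...) {
  cat("<fractionation_result> distinct ref genes: ", x$distinct_ref_genes,
      "; co-retained: ", x$co_retained, "; fractionated: ", x$fractionated,
      " (", sprintf("%.2f", x$pct_fractionated), "%)\n", sep = "")
  invisible(x)
}

#' Detect tandem gene arrays
#'
#' Arrays are connected components of the graph joining homologous genes on
#' the same chromosome whose rank distance is at most `max_intervening + 1`
#' (i.e. at most `max_intervening` non-member genes between them).
#' Components are ordered by rank; singletons are discarded. An optional
#' curation list restricts members (the reproducible stand-in for manual
#' domain-based curation).
#'
#' @param desc descendant `gene_index`.
#' @param hits `homolog_hits` (intra-genome hits are used; inter-genome hits
#'   are ignored).
#' @param max_intervening maximum non-homologous genes allowed between
#'   consecutive array members.
#' @param include optional character vector: only these genes may be array
#'   members.
#' @return list of class `tandem_arrays`: `arrays` data.frame (array_id,
#'   chromosome, n_members, member ids comma-joined) and `members`
#'   data.frame (array_id, gene_id, rank).
#' @export
detect_tandem_arrays <- function(desc, hits, max_intervening = 1,
                                 include = NULL) {
  g <- desc$genes
  h <- hits[hits$query_id %in% g$gene_id & hits$subject_id %in% g$gene_id, ,
            drop = FALSE]
  if (!is.null(include)) {
    h <- h[h$query_id %in% include & h$subject_id %in% include, , drop = FALSE]
  }
  qi <- match(h$query_id, g$gene_id)
  si <- match(h$subject_id, g$gene_id)
  same_chrom <- g$chromosome[qi] == g$chromosome[si]
  near <- abs(g$rank[qi] - g$rank[si]) <= max_intervening + 1
  edge <- same_chrom & near
  parent <- seq_len(nrow(g))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in which(edge)) {
    a <- find(qi[k]); b <- find(si[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(nrow(g)), find, integer(1))
  groups <- split(seq_len(nrow(g)), comp)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (length(groups) == 0) {
    arrays <- data.frame(array_id = character(0), chromosome = character(0),
                         n_members = integer(0), members = character(0),
                         stringsAsFactors = FALSE)
    members <- data.frame(array_id = character(0), gene_id = character(0),
                          rank = integer(0), stringsAsFactors = FALSE)
    return(structure(list(arrays = arrays, members = members,
                          max_intervening = max_intervening),
                     class = "tandem_arrays"))
  }
  # order arrays by (chromosome, first member rank) for stable ids
  first <- vapply(groups, function(i) min(g$rank[i]), numeric(1))
  chrom <- vapply(groups, function(i) g$chromosome[i[1]], character(1))
  ord <- order(chrom, first)
  groups <- groups[ord]
  arrays <- vector("list", length(groups))
  members <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    i <- groups[[k]][order(g$rank[groups[[k]]])]
    id <- sprintf("TA%04d", k)
    arrays[[k]] <- data.frame(array_id = id, chromosome = g$chromosome[i[1]],
                              n_members = length(i),
                              members = paste(g$gene_id[i], collapse = ","),
                              stringsAsFactors = FALSE)
    members[[k]] <- data.frame(array_id = id, gene_id = g$gene_id[i],
                               rank = g$rank[i], stringsAsFactors = FALSE)
  }
  structure(list(arrays = do.call(rbind, arrays),
                 members = do.call(rbind, members),
                 max_intervening = max_intervening),
            class = "tandem_arrays")
}

#' @export
print.tandem_arrays <- function(x, ...) {
  cat("<tandem_arrays> ", nrow(x$arrays), " arrays, ",
      nrow(x$members), " member genes\n", sep = "")
  invisible(x)
}

#' Expand tandem arrays into paralogous gene pairs
#'
#' Every unordered combination of two members of an array constitutes a
#' tandem paralog pair: an array of n genes yields n(n-1)/2 pairs.
#'
#' @param arrays a `tandem_arrays` object (all arrays are expanded).
#' @return `gene_pairs` with `pair_type = "tandem_paralog"` and `context` =
#'   array id.
#' @export
expand_array_pairs <- function(arrays) {
  out <- list()
  n <- 0L
  for (id in arrays$arrays$array_id) {
    m <- arrays$members$gene_id[arrays$members$array_id == id]
    if (length(m) < 2) next
    cmb <- utils::combn(sort(m), 2)
    n <- n + 1L
    out[[n]] <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                           pair_type = "tandem_paralog", context = id,
                           stringsAsFactors = FALSE)
  }
  out <- if (n > 0) do.call(rbind, out) else
    data.frame(gene_a = character(0), gene_b = character(0),
               pair_type = character(0), context = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gene_pairs", "data.frame"))
}

#' Date tandem arrays relative to the WGD event
#'
#' An array predates the WGD if and only if every member gene appears as a
#' descendant anchor gene of some assigned syntenic block (i.e. follows the
#' ancestral gene order); otherwise it postdates the WGD. Pre-WGD arrays are
#' attributed to the subgenome of their members' ortholog pairs.
#'
#' @param arrays a `tandem_arrays` object.
#' @param orthologs ortholog `gene_pairs` from the same descendant genome.
#' @return list of class `tandem_dating`: `dating` data.frame (array_id,
#'   dating, subgenome, n_members) and `counts` (arrays and member genes per
#'   class, pre-WGD split by subgenome).
#' @export
date_tandem_arrays <- function(arrays, orthologs) {
  o <- as.data.frame(orthologs)
  anchor_genes <- unique(o$desc_gene)
  rows <- lapply(seq_len(nrow(arrays$arrays)), function(k) {
    id <- arrays$arrays$array_id[k]
    m <- arrays$members$gene_id[arrays$members$array_id == id]
    pre <- all(m %in% anchor_genes)
    sg <- NA_character_
    if (pre) {
      sgs <- unique(o$subgenome[o$desc_gene %in% m])
      sg <- if (length(sgs) == 1) sgs else "mixed"
    }
    data.frame(array_id = id, dating = if (pre) "pre_wgd" else "post_wgd",
               subgenome = sg, n_members = length(m),
               stringsAsFactors = FALSE)
  })
  dating <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(array_id = character(0), dating = character(0),
               subgenome = character(0), n_members = integer(0),
               stringsAsFactors = FALSE)
  pre <- dating[dating$dating == "pre_wgd", , drop = FALSE]
  post <- dating[dating$dating == "post_wgd", , drop = FALSE]
  counts <- list(
    n_arrays_pre = nrow(pre), n_genes_pre = sum(pre$n_members),
    n_arrays_post = nrow(post), n_genes_post = sum(post$n_members),
    pre_by_subgenome = stats::setNames(
      lapply(c("subgenome1", "subgenome2"), function(sg) {
        i <- pre$subgenome == sg
        list(n_arrays = sum(i), n_genes = sum(pre$n_members[i]))
      }), c("subgenome1", "subgenome2")))
  structure(list(dating = dating, counts = counts), class = "tandem_dating")
}

#' @export
print.tandem_dating <- function(x, ...) {
  cat("<tandem_dating> pre-WGD: ", x$counts$n_arrays_pre, " arrays / ",
      x$counts$n_genes_pre, " genes; post-WGD: ", x$counts$n_arrays_post,
      " arrays / ", x$counts$n_genes_post, " genes\n", sep = "")
  invisible(x)
}
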