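# Functional-divergence classification of gene pairs from annotation-term
# sets, per-class summaries, term-set overlap (Venn) and gene-family event
# attribution.

DIVERGENCE_CLASSES <- c("A_conserved", "B_subfunctionalized",
                        "C_neofunctionalized", "unannotated")

#' Classify one gene pair's functional divergence
#'
#' From the two members' annotation-term sets:
#' * `unannotated` if either set is empty (divergence is undefined with one
#'   empty set; this matches count identities where one-sided annotation
#'   falls in the "no annotation" column),
#' * `A_conserved` if the sets are identical,
#' * `B_subfunctionalized` if they share some but not all terms,
#' * `C_neofunctionalized` if both are non-empty and disjoint.
#'
#' The classification is symmetric in its arguments.
#'
#' @param terms_a,terms_b character vectors of term ids (duplicates ignored).
#' @return one of `r paste(DIVERGENCE_CLASSES, collapse = ", ")`.
#' @export
classify_pair <- function(terms_a, terms_b) {
  a <- unique(terms_a)
  b <- unique(terms_b)
  if (length(a) == 0 || length(b) == 0) return("unannotated")
  if (setequal(a, b)) return("A_conserved")
  if (length(intersect(a, b)) > 0) return("B_subfunctionalized")
  "C_neofunctionalized"
}

#' Classify a table of gene pairs
#'
#' @param pairs `gene_pairs` data.frame (columns `gene_a`, `gene_b`).
#' @param annotation a `term_annotation`.
#' @return the input with added columns `class`, `terms_a`, `terms_b`,
#'   `shared_terms` (comma-joined).
#' @export
classify_pairs <- function(pairs, annotation) {
  pairs <- as.data.frame(pairs)
  ta <- lapply(pairs$gene_a, function(g) gene_terms(annotation, g))
  tb <- lapply(pairs$gene_b, function(g) gene_terms(annotation, g))
  pairs$class <- mapply(classify_pair, ta, tb)
  pairs$terms_a <- vapply(ta, paste, "", collapse = ",")
  pairs$terms_b <- vapply(tb, paste, "", collapse = ",")
  pairs$shared_terms <- mapply(function(a, b) paste(intersect(a, b),
                                                    collapse = ","), ta, tb)
  if (nrow(pairs) == 0) {
    pairs$class <- character(0)
    pairs$terms_a <- pairs$terms_b <- pairs$shared_terms <- character(0)
  }
  structure(pairs, class = c("gene_pairs", "data.frame"))
}

#' Summarize divergence classes per pair class
#'
#' Counts A/B/C/unannotated pairs within each pair class and reports the
#' class percentages on both bases found in the literature: percent of all
#' pairs and percent of annotated pairs (both to one decimal).
#'
#' @param pairs `gene_pairs`; classified with [classify_pairs()] if the
#'   `class` column is absent.
#' @param annotation a `term_annotation` (used only if classification is
#'   still needed).
#' @param by column of `pairs` defining the grouping (default the pair type;
#'   for orthologs grouped per subgenome use `"context"`).
#' @return data.frame of class `divergence_summary`, one row per group.
#' @export
summarize_divergence <- function(pairs, annotation = NULL, by = "pair_type") {
  pairs <- as.data.frame(pairs)
  if (!"class" %in% names(pairs)) {
    if (is.null(annotation)) stop("pairs are unclassified and no annotation given")
    pairs <- classify_pairs(pairs, annotation)
  }
  if (nrow(pairs) == 0) {
    return(structure(divergence_summary_row("none", 0, 0, 0, 0)[0, ],
                     class = c("divergence_summary", "data.frame")))
  }
  groups <- split(pairs, pairs[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    cl <- groups[[g]]$class
    divergence_summary_row(g,
                           n_A = sum(cl == "A_conserved"),
                           n_B = sum(cl == "B_subfunctionalized"),
                           n_C = sum(cl == "C_neofunctionalized"),
                           n_unannotated = sum(cl == "unannotated"))
  }))
  structure(out, class = c("divergence_summary", "data.frame"))
}

#' One divergence-summary row from class counts
#'
#' Arithmetic core of [summarize_divergence()], usable directly on published
#' counts. Percentages use two explicit bases: `pct_*_of_total` divides by
#' all pairs, `pct_*_of_annotated` by annotated pairs only; both are rounded
#' to one decimal except `pct_A_of_total_2dp` (two decimals, the precision
#' used for WGD duplicate summaries).
#'
#' @param label group label.
#' @param n_A,n_B,n_C,n_unannotated class counts.
#' @return one-row data.frame.
#' @export
divergence_summary_row <- function(label, n_A, n_B, n_C, n_unannotated) {
  total <- n_A + n_B + n_C + n_unannotated
  annotated <- n_A + n_B + n_C
  pct <- function(x, base) if (base > 0) round(100 * x / base, 1) else 0
  data.frame(group = label, total_pairs = total, n_unannotated = n_unannotated,
             n_A = n_A, n_B = n_B, n_C = n_C,
             pct_A_of_total = pct(n_A, total),
             pct_B_of_total = pct(n_B, total),
             pct_C_of_total = pct(n_C, total),
             pct_A_of_annotated = pct(n_A, annotated),
             pct_B_of_annotated = pct(n_B, annotated),
             pct_C_of_annotated = pct(n_C, annotated),
             pct_A_of_total_2dp =
               if (total > 0) round(100 * n_A / total, 2) else 0,
             stringsAsFactors = FALSE)
}

#' Term-set overlap between two gene groups
#'
#' Aggregates the annotation terms of each gene group and partitions the
#' observed term universe into group-a-only / shared / group-b-only (the
#' Venn counts), plus the fraction of genes annotated in each group.
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @param annotation a `term_annotation`.
#' @return list of class `term_overlap` with `terms_only_a`, `terms_shared`,
#'   `terms_only_b` (character vectors), `genes_annotated_a/b`,
#'   `prop_annotated_a/b`.
#' @export
term_overlap <- function(genes_a, genes_b, annotation) {
  ta <- terms_of_genes(annotation, genes_a)
  tb <- terms_of_genes(annotation, genes_b)
  shared <- intersect(ta, tb)
  ann_a <- sum(genes_a %in% names(annotation))
  ann_b <- sum(genes_b %in% names(annotation))
  structure(list(terms_only_a = setdiff(ta, shared),
                 terms_shared = shared,
                 terms_only_b = setdiff(tb, shared),
                 genes_annotated_a = ann_a, genes_annotated_b = ann_b,
                 prop_annotated_a =
                   if (length(genes_a) > 0) ann_a / length(genes_a) else 0,
                 prop_annotated_b =
                   if (length(genes_b) > 0) ann_b / length(genes_b) else 0),
            class = "term_overlap")
}

#' @export
print.term_overlap <- function(x, ...) {
  cat("<term_overlap> only-a: ", length(x$terms_only_a), "; shared: ",
      length(x$terms_shared), "; only-b: ", length(x$terms_only_b), "\n",
      sep = "")
  invisible(x)
}

#' Attribute a gene family to duplication events
#'
#' A family is defined by one or more annotation terms; its members are all
#' genes whose term set intersects the family terms. Members are then
#' attributed to the WGD event (members of WGD duplicate pairs) and to
#' tandem duplication (members of tandem arrays).
#'
#' @param family_terms character vector of term ids defining the family.
#' @param annotation a `term_annotation`.
#' @param wgd_genes gene ids that are members of WGD duplicate pairs.
#' @param td_genes gene ids that are members of tandem arrays.
#' @param all_genes a `gene_index` or character vector restricting the gene
#'   universe (optional).
#' @param family_label label for the output row.
#' @return one-row data.frame of class `family_attribution` with `n_total`,
#'   `n_from_wgd`, `n_from_td` and the two event percentages (1 decimal).
#' @export
attribute_family <- function(family_terms, annotation, wgd_genes, td_genes,
                             all_genes = NULL, family_label = family_terms[1]) {
  if (length(family_terms) == 0) stop("invalid input: empty family_terms")
  members <- names(annotation)[vapply(unclass(annotation), function(t) {
    length(intersect(t, family_terms)) > 0
  }, logical(1))]
  if (!is.null(all_genes)) {
    universe <- if (inherits(all_genes, "gene_index")) {
      all_genes$genes$gene_id
    } else {
      as.character(all_genes)
    }
    members <- intersect(members, universe)
  }
  n_total <- length(members)
  n_wgd <- length(intersect(members, wgd_genes))
  n_td <- length(intersect(members, td_genes))
  pct <- function(x) if (n_total > 0) round(100 * x / n_total, 1) else 0
  structure(data.frame(family = family_label,
                       defining_terms = paste(family_terms, collapse = ","),
                       n_total = n_total, n_from_wgd = n_wgd,
                       n_from_td = n_td,
                       pct_from_wgd = pct(n_wgd), pct_from_td = pct(n_td),
                       stringsAsFactors = FALSE),
            class = c("family_attribution", "data.frame"))
}
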