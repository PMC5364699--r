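# Protein-guided codon alignment, per-pair Ka/Ks, similarity filtering and
# class-wise rate comparisons.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scores and affine gaps
#' (open 10, extend 0.5), computed by `Biostrings::pairwiseAlignment`.
#' `protein_identity` is the fraction of identical residues among columns
#' where both sequences have a residue; `coverage` is the fraction of the
#' shorter sequence present in such columns.
#'
#' @param a,b amino-acid sequences (character scalars, 20-letter alphabet; a
#'   terminal `*` is tolerated and trimmed).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return list of class `protein_alignment`: `aligned_a`, `aligned_b`
#'   (gapped strings), `score`, `protein_identity`, `coverage`.
#' @export
align_protein_pair <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  res <- align_protein_pairs(a, b, gap_opening, gap_extension)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score,
                 protein_identity = res$protein_identity,
                 coverage = res$coverage),
            class = "protein_alignment")
}

#' Vectorized pairwise protein alignments
#'
#' @param a,b character vectors of equal length; element i of `a` is aligned
#'   with element i of `b`.
#' @inheritParams align_protein_pair
#' @return data.frame with `aligned_a`, `aligned_b`, `score`,
#'   `protein_identity`, `coverage`.
#' @export
align_protein_pairs <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  stopifnot(length(a) == length(b))
  a <- sub("\\*$", "", toupper(a))
  b <- sub("\\*$", "", toupper(b))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), c(a, b)) |
    nchar(c(a, b)) == 0
  if (any(bad)) stop("invalid residue or empty protein sequence")
  blosum62 <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
    substitutionMatrix = blosum62, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  stats <- mapply(function(x, y, la, lb) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    both <- cx != "-" & cy != "-"
    id <- if (any(both)) sum(cx[both] == cy[both]) / sum(both) else 0
    c(id = id, cov = sum(both) / min(la, lb))
  }, pa, pb, nchar(a), nchar(b))
  data.frame(aligned_a = unname(pa), aligned_b = unname(pb),
             score = Biostrings::score(aln),
             protein_identity = unname(stats["id", ]),
             coverage = unname(stats["cov", ]),
             stringsAsFactors = FALSE)
}

.blosum <- new.env(parent = emptyenv())
get_blosum62 <- function() {
  if (is.null(.blosum$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum$m <- e$BLOSUM62
  }
  .blosum$m
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue column expands to its source codon; protein gap
#' columns expand to `---` codon gaps. The coding sequence must translate to
#' the protein (one terminal stop is tolerated and trimmed); coding
#' sequences with internal stops, frame problems or translation mismatches
#' exclude the pair with a recorded reason instead of a hard failure.
#'
#' @param alignment a `protein_alignment` (or list with `aligned_a`,
#'   `aligned_b`).
#' @param cds_a,cds_b in-frame coding sequences for the two proteins.
#' @param gene_a,gene_b gene ids carried into the result.
#' @return a `codon_alignment` (fields `codons_a`, `codons_b`,
#'   `n_codon_columns`, `protein_identity`, `coverage`), or an object of
#'   class `pair_exclusion` with a `reason` field (`internal_stop`, `frame`,
#'   `translation_mismatch`).
#' @export
backtranslate <- function(alignment, cds_a, cds_b,
                          gene_a = "a", gene_b = "b") {
  expand <- function(aligned, cds) {
    cds <- toupper(cds)
    if (nchar(cds) >= 3 &&
        substr(cds, nchar(cds) - 2, nchar(cds)) %in% STOP_CODONS) {
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    if (nchar(cds) %% 3 != 0) return(list(reason = "frame"))
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- translate_codons(codons)
    if (any(aa == "*")) return(list(reason = "internal_stop"))
    res <- strsplit(aligned, "")[[1]]
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(codons) ||
        any(ungapped != aa & aa != "X")) {
      return(list(reason = "translation_mismatch"))
    }
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    list(codons = out)
  }
  ea <- expand(alignment$aligned_a, cds_a)
  if (!is.null(ea$reason)) {
    return(structure(list(gene_a = gene_a, gene_b = gene_b,
                          reason = ea$reason), class = "pair_exclusion"))
  }
  eb <- expand(alignment$aligned_b, cds_b)
  if (!is.null(eb$reason)) {
    return(structure(list(gene_a = gene_a, gene_b = gene_b,
                          reason = eb$reason), class = "pair_exclusion"))
  }
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = ea$codons, codons_b = eb$codons,
                 n_codon_columns = length(ea$codons),
                 protein_identity = alignment$protein_identity,
                 coverage = alignment$coverage),
            class = "codon_alignment")
}

translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"   # ambiguous bases
  aa
}

#' Ka/Ks for a table of gene pairs
#'
#' Convenience wrapper running [align_protein_pairs()], [backtranslate()]
#' and [kaks_ng86()] over a `gene_pairs` table. Pairs excluded at
#' back-translation or lacking sequences are reported in the exclusion log.
#'
#' @param pairs `gene_pairs` data.frame.
#' @param cds a cds `sequence_set`.
#' @param proteins a protein `sequence_set` (if `NULL`, proteins are
#'   translated from the cds).
#' @return list with `results` (one Ka/Ks row per computed pair, carrying
#'   the pair columns) and `excluded` (gene_a, gene_b, reason).
#' @export
kaks_pairs <- function(pairs, cds, proteins = NULL) {
  pairs <- as.data.frame(pairs)
  excl <- list()
  seqs <- cds$sequences
  has <- pairs$gene_a %in% names(seqs) & pairs$gene_b %in% names(seqs)
  if (any(!has)) {
    excl[[length(excl) + 1]] <- data.frame(
      gene_a = pairs$gene_a[!has], gene_b = pairs$gene_b[!has],
      reason = "missing_sequence", stringsAsFactors = FALSE)
  }
  p <- pairs[has, , drop = FALSE]
  if (nrow(p) == 0) {
    return(list(results = cbind(pairs[0, , drop = FALSE],
                                as_kaks_row(empty_kaks())[0, -(1:2)]),
                excluded = rbindlist0(excl)))
  }
  prot <- function(id) {
    if (!is.null(proteins) && id %in% names(proteins$sequences)) {
      return(proteins$sequences[[id]])
    }
    cd <- seqs[[id]]
    codons <- substring(cd, seq(1, nchar(cd), 3), seq(3, nchar(cd), 3))
    paste(translate_codons(codons), collapse = "")
  }
  pa <- vapply(p$gene_a, prot, "")
  pb <- vapply(p$gene_b, prot, "")
  internal_stop <- grepl("\\*", pa) | grepl("\\*", pb)
  if (any(internal_stop)) {
    excl[[length(excl) + 1]] <- data.frame(
      gene_a = p$gene_a[internal_stop], gene_b = p$gene_b[internal_stop],
      reason = "internal_stop", stringsAsFactors = FALSE)
    p <- p[!internal_stop, , drop = FALSE]
    pa <- pa[!internal_stop]
    pb <- pb[!internal_stop]
  }
  if (nrow(p) == 0) {
    return(list(results = cbind(pairs[0, , drop = FALSE],
                                as_kaks_row(empty_kaks())[0, -(1:2)]),
                excluded = rbindlist0(excl)))
  }
  aln <- align_protein_pairs(pa, pb)
  rows <- vector("list", nrow(p))
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    ca <- backtranslate(list(aligned_a = aln$aligned_a[i],
                             aligned_b = aln$aligned_b[i],
                             protein_identity = aln$protein_identity[i],
                             coverage = aln$coverage[i]),
                        seqs[[p$gene_a[i]]], seqs[[p$gene_b[i]]],
                        p$gene_a[i], p$gene_b[i])
    if (inherits(ca, "pair_exclusion")) {
      excl[[length(excl) + 1]] <- data.frame(gene_a = ca$gene_a,
                                             gene_b = ca$gene_b,
                                             reason = ca$reason,
                                             stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- as_kaks_row(kaks_ng86(ca))
    keep[i] <- TRUE
  }
  res <- if (any(keep)) {
    cbind(p[keep, , drop = FALSE],
          do.call(rbind, rows[keep])[, -(1:2), drop = FALSE])
  } else {
    cbind(pairs[0, , drop = FALSE], as_kaks_row(empty_kaks())[0, -(1:2)])
  }
  rownames(res) <- NULL
  list(results = res, excluded = rbindlist0(excl))
}

empty_kaks <- function() {
  structure(list(gene_a = "a", gene_b = "b", n_codon_columns = 0L,
                 S_sites = 0, N_sites = 0, Sd = 0, Nd = 0, pS = 0, pN = 0,
                 Ks = NA_real_, Ka = NA_real_, omega = NA_real_,
                 saturated = FALSE, protein_identity = NA_real_,
                 coverage = NA_real_), class = "kaks_result")
}

rbindlist0 <- function(lst) {
  if (length(lst) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Filter Ka/Ks results on sequence similarity
#'
#' Removes pairs below the identity or coverage thresholds and saturated
#' pairs; every exclusion is logged with its reason (`low_identity`,
#' `low_coverage`, `saturated`). Exclusions recorded earlier (e.g. at
#' back-translation) can be passed through.
#'
#' @param results Ka/Ks results data.frame (from [kaks_pairs()]).
#' @param min_identity minimum protein identity (fraction).
#' @param min_coverage minimum aligned coverage of the shorter sequence.
#' @param prior_exclusions optional data.frame (gene_a, gene_b, reason)
#'   appended to the log.
#' @return list with `retained` (data.frame) and `excluded` (the log).
#' @export
filter_pairs <- function(results, min_identity = 0.3, min_coverage = 0.5,
                         prior_exclusions = NULL) {
  reason <- rep(NA_character_, nrow(results))
  reason[results$saturated] <- "saturated"
  reason[is.na(reason) & results$coverage < min_coverage] <- "low_coverage"
  reason[is.na(reason) & results$protein_identity < min_identity] <-
    "low_identity"
  keep <- is.na(reason)
  excluded <- data.frame(gene_a = results$gene_a[!keep],
                         gene_b = results$gene_b[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (!is.null(prior_exclusions) && nrow(prior_exclusions) > 0) {
    excluded <- rbind(prior_exclusions[, c("gene_a", "gene_b", "reason")],
                      excluded)
  }
  rownames(excluded) <- NULL
  retained <- results[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided test on two samples. When both groups have at most
#' `exact_max` observations the p-value is computed by complete enumeration
#' of all rank assignments (ties handled through midranks); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric samples.
#' @param exact_max exact-enumeration threshold per group.
#' @return list with `U` (statistic of `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sel <- utils::combn(n1 + n2, n1)
    base <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(r[sel], nrow = n1)) - base
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal_approx")
}

#' Compare substitution rates between divergence classes
#'
#' Per-class mean and median of Ka, Ks and omega (= Ka/Ks), and a two-sided
#' Mann-Whitney U p-value on omega for every pair of classes.
#'
#' @param results Ka/Ks results data.frame containing a `class` column (or
#'   supply `classes`).
#' @param classes optional character vector of class labels, one per row of
#'   `results`.
#' @param value column compared between classes (default `"omega"`).
#' @return list of class `class_comparison`: `stats` data.frame and `tests`
#'   data.frame (class_a, class_b, U, p_value, method).
#' @export
compare_classes <- function(results, classes = NULL, value = "omega") {
  if (is.null(classes)) {
    if (!"class" %in% names(results)) stop("no class labels available")
    classes <- results$class
  }
  groups <- split(results, classes)
  usable <- vapply(groups, function(g) sum(!is.na(g[[value]])) >= 1, logical(1))
  if (any(!usable)) {
    warning("class(es) without usable values omitted: ",
            paste(names(groups)[!usable], collapse = ", "))
    groups <- groups[usable]
  }
  if (length(groups) < 2) stop("need >= 2 classes with >= 1 pair each")
  stats_tab <- do.call(rbind, lapply(names(groups), function(cl) {
    g <- groups[[cl]]
    data.frame(class = cl, n = nrow(g),
               mean_Ka = mean(g$Ka, na.rm = TRUE),
               median_Ka = stats::median(g$Ka, na.rm = TRUE),
               mean_Ks = mean(g$Ks, na.rm = TRUE),
               median_Ks = stats::median(g$Ks, na.rm = TRUE),
               mean_omega = mean(g$omega, na.rm = TRUE),
               median_omega = stats::median(g$omega, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  cls <- names(groups)
  tests <- list()
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (j <= i) next
      mw <- mann_whitney_u(groups[[cls[i]]][[value]],
                           groups[[cls[j]]][[value]])
      tests[[length(tests) + 1]] <- data.frame(
        class_a = cls[i], class_b = cls[j], U = mw$U, p_value = mw$p_value,
        method = mw$method, stringsAsFactors = FALSE)
    }
  }
  structure(list(stats = stats_tab, tests = do.call(rbind, tests),
                 value = value),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("<class_comparison> on", x$value, "\n")
  print(x$stats)
  print(x$tests)
  invisible(x)
}
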