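# Nei-Gojobori (1986) counting machinery: synonymous/nonsynonymous site
# fractions per codon from the standard genetic code, pathway-averaged
# difference counts per codon pair, and the Jukes-Cantor correction.
#
# Conventions (NG86):
#  - each codon position contributes the fraction of its possible
#    single-nucleotide changes that are synonymous; changes to stop codons
#    are excluded from the possible-change count;
#  - for codon pairs differing at k positions, observed synonymous and
#    nonsynonymous differences are averaged over all k! mutational pathways,
#    pathways passing through a stop codon being discarded (if every pathway
#    hits a stop, differences are split half/half);
#  - multiple-hit correction d = -(3/4) * log(1 - (4/3) * p).

NUCS <- c("A", "C", "G", "T")

.ng86 <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86$tables)) return(.ng86$tables)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  is_stop <- aa == "*"
  n <- length(codons)
  idx <- stats::setNames(seq_len(n), codons)

  # per-codon synonymous site counts
  syn_sites <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    s <- 0
    cod <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      syn <- 0L
      valid <- 0L
      for (nt in setdiff(NUCS, cod[pos])) {
        alt <- cod
        alt[pos] <- nt
        alt_aa <- code[[paste(alt, collapse = "")]]
        if (alt_aa == "*") next
        valid <- valid + 1L
        if (alt_aa == aa[i]) syn <- syn + 1L
      }
      if (valid > 0) s <- s + syn / valid
    }
    syn_sites[i] <- s
  }

  # pathway-averaged difference counts per codon pair
  Sd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  Nd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (is_stop[j]) next
      cj <- strsplit(codons[j], "")[[1]]
      d <- which(ci != cj)
      k <- length(d)
      if (k == 0) {
        Sd[i, j] <- Nd[i, j] <- 0
        next
      }
      pp <- perms[[as.character(k)]]
      s_tot <- 0
      n_tot <- 0
      n_valid <- 0L
      for (p in seq_len(nrow(pp))) {
        cur <- ci
        s <- 0L
        ns <- 0L
        ok <- TRUE
        for (step in pp[p, ]) {
          nxt <- cur
          nxt[d[step]] <- cj[d[step]]
          aa_cur <- code[[paste(cur, collapse = "")]]
          aa_nxt <- code[[paste(nxt, collapse = "")]]
          if (aa_nxt == "*") {
            ok <- FALSE
            break
          }
          if (aa_cur == aa_nxt) s <- s + 1L else ns <- ns + 1L
          cur <- nxt
        }
        if (ok) {
          n_valid <- n_valid + 1L
          s_tot <- s_tot + s
          n_tot <- n_tot + ns
        }
      }
      if (n_valid > 0) {
        Sd[i, j] <- s_tot / n_valid
        Nd[i, j] <- n_tot / n_valid
      } else {
        Sd[i, j] <- k / 2
        Nd[i, j] <- k / 2
      }
    }
  }
  .ng86$tables <- list(codons = codons, idx = idx, aa = aa, is_stop = is_stop,
                       syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  .ng86$tables
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p proportion of observed differences per site; values at or above
#'   3/4 are saturated and return `NA`.
#' @return corrected substitutions per site.
#' @export
jukes_cantor <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Ka and Ks for one codon alignment (NG86)
#'
#' Nei-Gojobori counting with Jukes-Cantor correction. Gap columns and
#' columns containing ambiguous bases are skipped; stop codons in aligned
#' columns are an error (pairs with internal stops are excluded upstream at
#' back-translation).
#'
#' @param aln a `codon_alignment` (from [backtranslate()]).
#' @return object of class `kaks_result`: list with `gene_a`, `gene_b`,
#'   `n_codon_columns`, `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `omega`, `saturated`, plus the alignment's `protein_identity` and
#'   `coverage`.
#' @export
kaks_ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tb <- ng86_tables()
  ca <- aln$codons_a
  cb <- aln$codons_b
  keep <- ca != "---" & cb != "---" &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]
  cb <- cb[keep]
  if (length(ca) == 0) stop("invalid input: no usable codon columns")
  ia <- tb$idx[ca]
  ib <- tb$idx[cb]
  if (any(tb$is_stop[ia]) || any(tb$is_stop[ib])) {
    stop("stop codon in aligned non-gap column")
  }
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tb$Sd[cbind(ia, ib)])
  Nd <- sum(tb$Nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  saturated <- pS >= 0.75 || pN >= 0.75
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  omega <- if (!saturated && !is.na(Ks) && !is.na(Ka) && Ks > 0) {
    Ka / Ks
  } else {
    NA_real_
  }
  structure(list(gene_a = aln$gene_a, gene_b = aln$gene_b,
                 n_codon_columns = length(ca),
                 S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka, omega = omega,
                 saturated = saturated,
                 protein_identity = aln$protein_identity,
                 coverage = aln$coverage),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("<kaks_result> ", x$gene_a, " vs ", x$gene_b,
      sprintf(": Ka=%.4f Ks=%.4f omega=%s%s\n", x$Ka, x$Ks,
              ifelse(is.na(x$omega), "NA", sprintf("%.4f", x$omega)),
              if (x$saturated) " [saturated]" else ""), sep = "")
  invisible(x)
}

as_kaks_row <- function(x) {
  data.frame(gene_a = x$gene_a, gene_b = x$gene_b,
             n_codon_columns = x$n_codon_columns,
             S_sites = x$S_sites, N_sites = x$N_sites,
             Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
             Ks = x$Ks, Ka = x$Ka, omega = x$omega,
             saturated = x$saturated,
             protein_identity = x$protein_identity,
             coverage = x$coverage, stringsAsFactors = FALSE)
}
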