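# Independent oracles used across the suite. Each is implemented on a
# different representation / algorithm than the package path it checks.

# ---- chain oracle: exhaustive monotone-chain enumeration -------------------

# Enumerate every valid chain (DAG path) over an anchor frame for one
# orientation; returns list of index vectors (into rows of `a`).
oracle_all_chains <- function(a, params, orientation) {
  n <- nrow(a)
  if (n == 0) return(list())
  ord <- order(a$ref_rank, a$desc_rank)
  a <- a[ord, , drop = FALSE]
  dr <- if (orientation == "same") a$desc_rank else -a$desc_rank
  can_follow <- function(i, j) {  # j after i
    gr <- a$ref_rank[j] - a$ref_rank[i]
    gd <- dr[j] - dr[i]
    gr >= 1 && gr <= params$max_gap && gd >= 1 && gd <= params$max_gap
  }
  chains <- list()
  grow <- function(path) {
    chains[[length(chains) + 1]] <<- ord[path]
    last <- path[length(path)]
    for (j in seq_len(n)) {
      if (j > last && can_follow(last, j)) grow(c(path, j))
    }
  }
  for (s in seq_len(n)) grow(s)
  chains
}

oracle_chain_score <- function(a_full, idx, params, orientation) {
  a <- a_full[idx, , drop = FALSE]
  o <- order(a$ref_rank)
  a <- a[o, , drop = FALSE]
  gaps <- 0
  if (nrow(a) > 1) {
    gr <- diff(a$ref_rank)
    gd <- abs(diff(a$desc_rank))
    gaps <- sum((gr - 1) + (gd - 1))
  }
  nrow(a) * params$match_score + params$gap_penalty * gaps
}

# Greedy maximum-score chain decomposition by full enumeration; mirrors the
# package contract (chains < min_block_size discarded) but shares no code.
oracle_decompose <- function(a, params) {
  blocks <- list()
  rows <- seq_len(nrow(a))
  while (length(rows) > 0) {
    sub <- a[rows, , drop = FALSE]
    best <- NULL
    for (orient in c("same", "inverted")) {
      for (ch in oracle_all_chains(sub, params, orient)) {
        sc <- oracle_chain_score(sub, ch, params, orient)
        bits <- sum(sub$score[ch])
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && bits > best$bits)) {
          best <- list(idx = rows[ch], sc = sc, bits = bits)
        }
      }
    }
    if (is.null(best)) break
    if (length(best$idx) >= params$min_block_size) {
      blocks[[length(blocks) + 1]] <- best
    }
    rows <- setdiff(rows, best$idx)
  }
  blocks
}

random_anchor_frame <- function(n, max_rank = 15) {
  data.frame(
    ref_gene_id = sprintf("r%02d", seq_len(n)),
    desc_gene_id = sprintf("d%02d", seq_len(n)),
    ref_chrom = "R1", desc_chrom = "D1",
    ref_rank = sample.int(max_rank, n),
    desc_rank = sample.int(max_rank, n),
    score = round(stats::runif(n, 50, 150), 3),
    stringsAsFactors = FALSE)
}

# ---- NG86 oracle: string-based site counting + recursive path averaging ----

oracle_syn_sites <- function(codon) {
  GC <- Biostrings::GENETIC_CODE
  aa <- GC[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == nt) next
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (GC[[alt]] == "*") next
      valid <- valid + 1
      if (GC[[alt]] == aa) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

oracle_path_diffs <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0) return(c(s = 0, n = 0))
  acc <- list()
  rec <- function(cur, left, s, n) {
    if (length(left) == 0) {
      acc[[length(acc) + 1]] <<- c(s = s, n = n)
      return()
    }
    for (k in seq_along(left)) {
      pos <- left[k]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (GC[[nxt]] == "*") next
      if (GC[[nxt]] == GC[[cur]]) {
        rec(nxt, left[-k], s + 1, n)
      } else {
        rec(nxt, left[-k], s, n + 1)
      }
    }
  }
  rec(c1, d, 0, 0)
  if (length(acc) == 0) {
    return(c(s = length(d) / 2, n = length(d) / 2))
  }
  m <- do.call(rbind, acc)
  c(s = mean(m[, "s"]), n = mean(m[, "n"]))
}

oracle_kaks <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, 1)) +
          sum(vapply(codons_b, oracle_syn_sites, 1))) / 2
  N <- 3 * length(codons_a) - S
  diffs <- mapply(function(x, y) oracle_path_diffs(x, y),
                  codons_a, codons_b)
  Sd <- sum(diffs["s", ])
  Nd <- sum(diffs["n", ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(pS), Ka = jc(pN))
}

random_sense_codons <- function(n) {
  GC <- Biostrings::GENETIC_CODE
  sense <- names(GC)[GC != "*"]
  sample(sense, n, replace = TRUE)
}

codon_aln <- function(codons_a, codons_b, identity = 1, coverage = 1) {
  structure(list(gene_a = "a", gene_b = "b",
                 codons_a = codons_a, codons_b = codons_b,
                 n_codon_columns = length(codons_a),
                 protein_identity = identity, coverage = coverage),
            class = "codon_alignment")
}

# ---- affine-gap alignment score oracle (Gotoh, plain matrices) -------------

oracle_align_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  sub <- get("get_blosum62", asNamespace("paleodup"))()
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  # gap of length L costs gap_open + L * gap_ext (Biostrings convention)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - i * gap_ext
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - j * gap_ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# ---- Mann-Whitney oracle: pair counting over explicit group assignments ---

oracle_mw_exact <- function(x, y) {
  u_stat <- function(xx, yy) {
    sum(outer(xx, yy, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  U <- u_stat(x, y)
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  sel <- utils::combn(length(pool), n1)
  Us <- apply(sel, 2, function(s) u_stat(pool[s], pool[-s]))
  mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
}
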