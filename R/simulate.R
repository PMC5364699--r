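# Genome-evolution simulator: a paleodiploid reference genome and a
# descendant shaped by speciation, one WGD with fractionation, and tandem
# duplications -- with sequences, annotation terms, a hit table and
# ground-truth labels for every pipeline stage.
#
# Ks is planted per pair relationship (branch construction: ancestor
# --(ks_speciation - ks_wgd/2)--> WGD node --(ks_wgd/2)--> each subgenome
# copy), not via a global clock, so every measured pair hits its planted
# value in expectation. Substitution events are Poisson draws: synonymous
# count ~ Poisson(ks * S_sites), nonsynonymous ~ Poisson(omega * ks *
# N_sites), each event a uniform draw over the currently possible
# single-nucleotide changes of that type (changes creating stop codons are
# never available).

#' Simulation parameters
#'
#' Defaults state the emulated history: ortholog divergence centered at
#' Ks = 1.5 (speciation), one WGD at Ks = 0.7 with per-copy retention 0.5
#' (joint co-retention target 0.25), tandem duplications centered at
#' Ks = 0.3 with a 5% minority of arrays predating the WGD.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_ref_genes ancestral (= reference) gene count.
#' @param n_chromosomes reference chromosomes; the descendant has twice as
#'   many (one set per subgenome).
#' @param gene_length_codons codons per gene (one model per locus).
#' @param ks_speciation planted Ks between reference and descendant copies.
#' @param ks_wgd planted Ks between the two subgenome copies of a gene.
#' @param ks_tandem_mean planted Ks between members of a post-WGD tandem
#'   array.
#' @param ks_tandem_pre planted Ks between the two ancestral copies of a
#'   pre-WGD tandem array (older than the WGD; the descendant members'
#'   pairwise Ks is uncontrolled and typically saturated).
#' @param frac_tandem_pre_wgd fraction of tandem arrays planted before the
#'   WGD (as ancestral adjacent duplicates).
#' @param retention_prob per-copy survival probability of a WGD duplicate.
#' @param rescue_fraction fraction of doubly-lost reference genes whose
#'   descendant lineage keeps one random copy anyway.
#' @param n_tandem_arrays total planted tandem arrays.
#' @param array_size_weights sampling weights for array sizes 2..16.
#' @param omega_by_class Ka/Ks used on branches, by intended divergence
#'   class (unannotated branches use the A value).
#' @param class_proportions intended divergence-class proportions
#'   (A, B, C, unannotated); must sum to 1.
#' @param term_vocab_size annotation-term vocabulary size.
#' @param terms_per_gene integer range (min, max) of terms per ancestral
#'   gene.
#' @param n_inversions random segmental inversions applied to descendant
#'   chromosomes (stress knob for the chain DP; 0 = clean collinearity).
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(seed = 7,
                             n_ref_genes = 2000,
                             n_chromosomes = 5,
                             gene_length_codons = 200,
                             ks_speciation = 1.5,
                             ks_wgd = 0.7,
                             ks_tandem_mean = 0.3,
                             ks_tandem_pre = 1.0,
                             frac_tandem_pre_wgd = 0.05,
                             retention_prob = 0.5,
                             rescue_fraction = 0.5,
                             n_tandem_arrays = 100,
                             array_size_weights = 0.45^(0:14),
                             omega_by_class = c(A = 0.15, B = 0.21, C = 0.35),
                             class_proportions = c(A = 0.74, B = 0.11,
                                                   C = 0.06,
                                                   unannotated = 0.09),
                             term_vocab_size = 1500,
                             terms_per_gene = c(1L, 4L),
                             n_inversions = 0) {
  p <- list(seed = as.integer(seed), n_ref_genes = as.integer(n_ref_genes),
            n_chromosomes = as.integer(n_chromosomes),
            gene_length_codons = as.integer(gene_length_codons),
            ks_speciation = ks_speciation, ks_wgd = ks_wgd,
            ks_tandem_mean = ks_tandem_mean, ks_tandem_pre = ks_tandem_pre,
            frac_tandem_pre_wgd = frac_tandem_pre_wgd,
            retention_prob = retention_prob,
            rescue_fraction = rescue_fraction,
            n_tandem_arrays = as.integer(n_tandem_arrays),
            array_size_weights = array_size_weights,
            omega_by_class = omega_by_class,
            class_proportions = class_proportions,
            term_vocab_size = as.integer(term_vocab_size),
            terms_per_gene = as.integer(terms_per_gene),
            n_inversions = as.integer(n_inversions))
  rates <- c(p$ks_speciation, p$ks_wgd, p$ks_tandem_mean, p$ks_tandem_pre,
             p$omega_by_class)
  if (any(rates < 0)) stop("invalid params: negative rate")
  if (abs(sum(p$class_proportions) - 1) > 1e-8) {
    stop("invalid params: class_proportions must sum to 1")
  }
  if (!setequal(names(p$class_proportions),
                c("A", "B", "C", "unannotated"))) {
    stop("invalid params: class_proportions needs A, B, C, unannotated")
  }
  if (p$ks_wgd / 2 >= p$ks_speciation) {
    stop("invalid params: ks_wgd/2 must be below ks_speciation")
  }
  if (length(p$array_size_weights) != 15) {
    stop("invalid params: array_size_weights must cover sizes 2..16")
  }
  structure(p, class = "evolution_params")
}

# ---- codon evolution machinery ---------------------------------------------

.sim <- new.env(parent = emptyenv())

evolve_tables <- function() {
  if (!is.null(.sim$tables)) return(.sim$tables)
  tb <- ng86_tables()
  n <- length(tb$codons)
  syn_opts <- vector("list", n)
  non_opts <- vector("list", n)
  for (i in seq_len(n)) {
    if (tb$is_stop[i]) {
      syn_opts[[i]] <- integer(0)
      non_opts[[i]] <- integer(0)
      next
    }
    cod <- strsplit(tb$codons[i], "")[[1]]
    so <- integer(0)
    no <- integer(0)
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, cod[pos])) {
        alt <- cod
        alt[pos] <- nt
        j <- tb$idx[[paste(alt, collapse = "")]]
        if (tb$is_stop[j]) next
        if (tb$aa[j] == tb$aa[i]) so <- c(so, j) else no <- c(no, j)
      }
    }
    syn_opts[[i]] <- so
    non_opts[[i]] <- no
  }
  .sim$tables <- list(
    codons = tb$codons, idx = tb$idx, aa = tb$aa, is_stop = tb$is_stop,
    sense = which(!tb$is_stop),
    syn_sites = tb$syn_sites,
    syn_opts = syn_opts, non_opts = non_opts,
    n_syn_opts = vapply(syn_opts, length, 1L),
    n_non_opts = vapply(non_opts, length, 1L))
  .sim$tables
}

random_codons <- function(n, ev) {
  sample(ev$sense, n, replace = TRUE)
}

# Apply the Poisson substitution scheme to an integer codon vector.
evolve_codons <- function(codons, ks, omega, ev) {
  L <- length(codons)
  S <- sum(ev$syn_sites[codons])
  N <- 3 * L - S
  n_syn <- stats::rpois(1, ks * S)
  n_non <- stats::rpois(1, omega * ks * N)
  events <- rep(c(1L, 2L), c(n_syn, n_non))
  if (length(events) > 1) events <- sample(events)
  for (type in events) {
    w <- if (type == 1L) ev$n_syn_opts[codons] else ev$n_non_opts[codons]
    tot <- sum(w)
    if (tot == 0) next
    j <- sample.int(L, 1L, prob = w)
    opts <- if (type == 1L) ev$syn_opts[[codons[j]]] else
      ev$non_opts[[codons[j]]]
    codons[j] <- opts[sample.int(length(opts), 1L)]
  }
  list(codons = codons, n_syn = n_syn, n_non = n_non)
}

#' Diverge a coding sequence to a planted Ks
#'
#' Applies the simulator's Poisson substitution scheme to one sequence:
#' synonymous events ~ Poisson(`ks_target` * S_sites), nonsynonymous events
#' ~ Poisson(`omega` * `ks_target` * N_sites); every event is a uniform draw
#' over the currently possible single-nucleotide changes of its type, and
#' changes creating stop codons are never drawn.
#'
#' @param cds in-frame, stop-free coding sequence (a terminal stop codon is
#'   tolerated and trimmed).
#' @param ks_target planted synonymous substitutions per synonymous site.
#' @param omega planted Ka/Ks.
#' @param seed optional integer; when given the RNG is seeded locally.
#' @return list with `cds` (diverged sequence), `n_syn`, `n_nonsyn`
#'   (realized event counts).
#' @export
evolve_pair <- function(cds, ks_target, omega, seed = NULL) {
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, evolve_pair(cds, ks_target, omega)))
  }
  expected_pS <- 0.75 * (1 - exp(-4 / 3 * ks_target))
  if (expected_pS > 0.74) stop("unreachable target: pS would exceed 0.74")
  ev <- evolve_tables()
  cds <- toupper(cds)
  if (nchar(cds) >= 3 &&
      substr(cds, nchar(cds) - 2, nchar(cds)) %in% STOP_CODONS) {
    cds <- substr(cds, 1, nchar(cds) - 3)
  }
  if (nchar(cds) %% 3 != 0) stop("cds length not a multiple of 3")
  codons <- ev$idx[substring(cds, seq(1, nchar(cds), 3),
                             seq(3, nchar(cds), 3))]
  if (anyNA(codons)) stop("cds contains ambiguous bases")
  if (any(ev$is_stop[codons])) stop("cds contains internal stop codons")
  res <- evolve_codons(unname(codons), ks_target, omega, ev)
  list(cds = paste(ev$codons[res$codons], collapse = ""),
       n_syn = res$n_syn, n_nonsyn = res$n_non)
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# generator-side divergence labeling (kept independent of classify_pair)
label_rule <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return("unannotated")
  if (length(a) == length(b) && all(sort(a) == sort(b))) return("A_conserved")
  if (any(a %in% b)) return("B_subfunctionalized")
  "C_neofunctionalized"
}

mutate_terms <- function(terms, class, vocab) {
  fresh <- function(k, avoid) {
    pool <- setdiff(vocab, avoid)
    sample(pool, min(k, length(pool)))
  }
  switch(class,
         A = terms,
         B = if (length(terms) >= 2) {
           out <- terms[-sample.int(length(terms), 1)]
           if (stats::runif(1) < 0.5) out <- c(out, fresh(1, terms))
           out
         } else {
           c(terms, fresh(1, terms))
         },
         C = fresh(max(1, length(terms)), terms),
         unannotated = character(0))
}

# ---- the simulator ----------------------------------------------------------

#' Simulate a reference genome and a WGD-shaped descendant
#'
#' Generates the full input set the pipeline consumes -- gene models (GFF3),
#' coding and protein sequences (FASTA), gene-to-term tables (TSV) for both
#' genomes, an all-vs-all protein hit table -- plus ground truth (planted
#' ortholog map, retention status, tandem arrays with pre-/post-WGD flags,
#' per-pair intended divergence class and planted Ks/omega).
#'
#' @param params an [evolution_params()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   there (`ref.gff3`, `desc.gff3`, `ref_cds.fasta`, `desc_cds.fasta`,
#'   `ref_protein.fasta`, `desc_protein.fasta`, `ref_terms.tsv`,
#'   `desc_terms.tsv`, `hits.tsv`, `ground_truth.json`).
#' @return object of class `synthetic_dataset`: the parsed in-memory
#'   equivalents (`gene_index`, `sequence_set`, `term_annotation`, raw hit
#'   data.frame) plus `truth`.
#' @export
simulate_genomes <- function(params = evolution_params(), out_dir = NULL) {
  stopifnot(inherits(params, "evolution_params"))
  with_preserved_seed(params$seed, simulate_genomes_impl(params, out_dir))
}

simulate_genomes_impl <- function(params, out_dir) {
  ev <- evolve_tables()
  vocab <- sprintf("IPR%06d", seq_len(params$term_vocab_size))
  n_chrom <- params$n_chromosomes
  L <- params$gene_length_codons
  cls_names <- c("A", "B", "C", "unannotated")
  cls_prob <- params$class_proportions[cls_names]
  omega_of <- function(cl) {
    if (cl == "unannotated") params$omega_by_class[["A"]] else
      params$omega_by_class[[cl]]
  }

  # ---- ancestral loci -------------------------------------------------------
  n_base <- params$n_ref_genes
  per_chrom <- diff(round(seq(0, n_base, length.out = n_chrom + 1)))
  base_chrom <- rep(seq_len(n_chrom), per_chrom)
  n_pre <- round(params$frac_tandem_pre_wgd * params$n_tandem_arrays)

  # hosts for pre-WGD arrays: spaced, not at chromosome edges
  host_ok <- rep(TRUE, n_base)
  host_ok[c(1, n_base)] <- FALSE
  host_ok[cumsum(per_chrom)] <- FALSE
  host_ok[c(1, utils::head(cumsum(per_chrom), -1) + 1)] <- FALSE
  pre_hosts <- integer(0)
  if (n_pre > 0) {
    cand <- sample(which(host_ok))
    for (h in cand) {
      if (length(pre_hosts) == n_pre) break
      if (all(abs(h - pre_hosts) > 3)) pre_hosts <- c(pre_hosts, h)
    }
    pre_hosts <- sort(pre_hosts)
  }
  # ancestral loci; a pre-WGD array adds a sibling locus right after its
  # host, the two forming one superfamily
  loci <- build_ancestral_loci(params, ev, vocab, base_chrom, pre_hosts,
                               cls_names, cls_prob, omega_of, L)

  n_loci <- length(loci)
  chrom_of <- vapply(loci, `[[`, 1L, "chrom")

  # ---- per-locus lineage decisions -----------------------------------------
  for (i in seq_len(n_loci)) {
    cl <- sample(cls_names, 1, prob = cls_prob)
    loci[[i]]$class <- cl
    loci[[i]]$omega <- omega_of(cl)
    s1 <- stats::runif(1) < params$retention_prob
    s2 <- stats::runif(1) < params$retention_prob
    if (!s1 && !s2 && stats::runif(1) < params$rescue_fraction) {
      if (stats::runif(1) < 0.5) s1 <- TRUE else s2 <- TRUE
    }
    loci[[i]]$s <- c(s1, s2)
  }
  # pre-WGD arrays: force joint retention of both members in one subgenome
  pre_sub <- integer(0)
  if (n_pre > 0) {
    pre_sub <- sample(1:2, n_pre, replace = TRUE)
    for (k in seq_len(n_pre)) {
      mem <- which(vapply(loci, function(l) identical(l$pre_array, k),
                          logical(1)))
      for (m in mem) loci[[m]]$s[pre_sub[k]] <- TRUE
    }
  }

  # ---- sequences & terms of descendant copies ------------------------------
  for (i in seq_len(n_loci)) {
    l <- loci[[i]]
    if (!any(l$s)) next
    d0 <- evolve_codons(l$seq, params$ks_speciation - params$ks_wgd / 2,
                        l$omega, ev)$codons
    for (sub in 1:2) {
      if (!l$s[sub]) next
      loci[[i]][[paste0("seq", sub)]] <-
        evolve_codons(d0, params$ks_wgd / 2, l$omega, ev)$codons
      loci[[i]][[paste0("terms", sub)]] <-
        mutate_terms(l$terms, l$class, vocab)
    }
  }

  # ---- descendant layout: retained copies per subgenome chromosome --------
  # descendant chromosomes: LG01..LG(n) for subgenome1, then subgenome2
  desc_rows <- list()   # one element per descendant gene, in genomic order
  copy_gene <- matrix(NA_character_, n_loci, 2)  # locus x sub -> gene id
  gid <- 0L
  next_id <- function() {
    gid <<- gid + 1L
    sprintf("SIN_g%05d", gid)
  }
  arrays_truth <- list()
  post_left <- params$n_tandem_arrays - n_pre
  # pre-select post-WGD hosts: (locus, sub) of retained, non-pre-array copies
  cand <- list()
  for (i in seq_len(n_loci)) {
    if (!is.na(loci[[i]]$pre_array)) next
    for (sub in 1:2) if (loci[[i]]$s[sub]) cand[[length(cand) + 1]] <-
        c(i, sub)
  }
  cand <- cand[sample.int(length(cand))]
  post_hosts <- matrix(0L, 0, 2)
  for (c2 in cand) {
    if (nrow(post_hosts) == post_left) break
    same <- post_hosts[post_hosts[, 2] == c2[2], 1]
    if (all(abs(same - c2[1]) > 20)) {
      post_hosts <- rbind(post_hosts, c2)
    }
  }
  post_size <- sample(2:16, nrow(post_hosts), replace = TRUE,
                      prob = params$array_size_weights)
  host_key <- paste(post_hosts[, 1], post_hosts[, 2])

  truth_pairs <- list()
  tp <- function(...) truth_pairs[[length(truth_pairs) + 1]] <<- list(...)
  lineage <- list()

  array_n <- 0L
  for (sub in 1:2) {
    for (ch in seq_len(n_chrom)) {
      chrom_name <- sprintf("LG%02d", (sub - 1) * n_chrom + ch)
      idx <- which(chrom_of == ch &
                     vapply(loci, function(l) l$s[sub], logical(1)))
      if (params$n_inversions > 0 && length(idx) > 3) {
        for (v in seq_len(params$n_inversions)) {
          ab <- sort(sample.int(length(idx), 2))
          idx[ab[1]:ab[2]] <- rev(idx[ab[1]:ab[2]])
        }
      }
      for (i in idx) {
        l <- loci[[i]]
        hk <- match(paste(i, sub), host_key)
        if (!is.na(hk)) {
          # post-WGD tandem array: replace the copy by `size` members
          size <- post_size[hk]
          center <- l[[paste0("seq", sub)]]
          base_terms <- l[[paste0("terms", sub)]]
          array_n <- array_n + 1L
          a_id <- sprintf("PA%04d", array_n)
          member_ids <- character(size)
          member_terms <- vector("list", size)
          extra_ks <- numeric(size)
          for (m in seq_len(size)) {
            mcl <- if (m == 1) "A" else sample(cls_names, 1, prob = cls_prob)
            mseq <- evolve_codons(center, params$ks_tandem_mean / 2,
                                  omega_of(mcl), ev)$codons
            mterms <- if (m == 1) base_terms else
              mutate_terms(base_terms, mcl, vocab)
            id <- next_id()
            member_ids[m] <- id
            member_terms[[m]] <- mterms
            extra_ks[m] <- params$ks_tandem_mean / 2
            desc_rows[[length(desc_rows) + 1]] <-
              list(gene_id = id, chrom = chrom_name, locus = i, sub = sub,
                   seq = mseq, terms = mterms,
                   role = if (m == 1) "wgd_copy" else "tandem_member")
            lineage[[id]] <- list(locus = i, subgenome = sub,
                                  role = if (m == 1) "copy" else
                                    "tandem_member", array = a_id)
          }
          copy_gene[i, sub] <- member_ids[1]
          loci[[i]][[paste0("extra_ks", sub)]] <- extra_ks[1]
          loci[[i]][[paste0("terms", sub)]] <- member_terms[[1]]
          arrays_truth[[length(arrays_truth) + 1]] <-
            list(array_id = a_id, chromosome = chrom_name,
                 members = member_ids, timing = "post_wgd",
                 subgenome = paste0("subgenome", sub))
          for (m1 in seq_len(size - 1)) {
            for (m2 in (m1 + 1):size) {
              tp(pair_type = "tandem_paralog",
                 gene_a = min(member_ids[m1], member_ids[m2]),
                 gene_b = max(member_ids[m1], member_ids[m2]),
                 class = label_rule(member_terms[[m1]], member_terms[[m2]]),
                 ks_planted = params$ks_tandem_mean,
                 omega = NA, array = a_id)
            }
          }
        } else {
          id <- next_id()
          copy_gene[i, sub] <- id
          desc_rows[[length(desc_rows) + 1]] <-
            list(gene_id = id, chrom = chrom_name, locus = i, sub = sub,
                 seq = l[[paste0("seq", sub)]],
                 terms = l[[paste0("terms", sub)]], role = "wgd_copy")
          lineage[[id]] <- list(locus = i, subgenome = sub, role = "copy",
                                array = NA)
        }
      }
    }
  }

  # ---- reference genome -----------------------------------------------------
  ref_ids <- sprintf("VVI_g%05d", seq_len(n_loci))
  ref_rows <- lapply(seq_len(n_loci), function(i) {
    list(gene_id = ref_ids[i], chrom = sprintf("chr%02d", chrom_of[i]),
         seq = loci[[i]]$seq, terms = loci[[i]]$terms)
  })

  # ---- ground truth: orthologs, WGD pairs, pre-WGD array instances ---------
  retention <- list()
  for (i in seq_len(n_loci)) {
    l <- loci[[i]]
    status <- if (all(l$s)) "co_retained" else if (l$s[1]) "only_sub1" else
      if (l$s[2]) "only_sub2" else "lost"
    retention[[ref_ids[i]]] <- status
    for (sub in 1:2) {
      if (!l$s[sub]) next
      extra <- l[[paste0("extra_ks", sub)]]
      if (is.null(extra)) extra <- 0
      d <- copy_gene[i, sub]
      tp(pair_type = "ortholog", gene_a = min(ref_ids[i], d),
         gene_b = max(ref_ids[i], d),
         ref_gene = ref_ids[i], desc_gene = d,
         subgenome = paste0("subgenome", sub),
         class = label_rule(l$terms, l[[paste0("terms", sub)]]),
         ks_planted = params$ks_speciation + extra, omega = l$omega)
    }
    if (all(l$s)) {
      e1 <- l$extra_ks1
      e2 <- l$extra_ks2
      d1 <- copy_gene[i, 1]
      d2 <- copy_gene[i, 2]
      tp(pair_type = "wgd_duplicate", gene_a = min(d1, d2),
         gene_b = max(d1, d2), ref_gene = ref_ids[i],
         class = label_rule(l$terms1, l$terms2),
         ks_planted = params$ks_wgd + (if (is.null(e1)) 0 else e1) +
           (if (is.null(e2)) 0 else e2),
         omega = l$omega)
    }
  }
  if (n_pre > 0) {
    for (k in seq_len(n_pre)) {
      mem <- which(vapply(loci, function(l) identical(l$pre_array, k),
                          logical(1)))
      for (sub in 1:2) {
        ids <- copy_gene[mem, sub]
        if (any(is.na(ids))) next   # array not jointly retained here
        array_n <- array_n + 1L
        a_id <- sprintf("PA%04d", array_n)
        ch <- sprintf("LG%02d", (sub - 1) * n_chrom + loci[[mem[1]]]$chrom)
        arrays_truth[[length(arrays_truth) + 1]] <-
          list(array_id = a_id, chromosome = ch, members = ids,
               timing = "pre_wgd", subgenome = paste0("subgenome", sub))
        tp(pair_type = "tandem_paralog", gene_a = min(ids), gene_b = max(ids),
           class = label_rule(loci[[mem[1]]][[paste0("terms", sub)]],
                              loci[[mem[2]]][[paste0("terms", sub)]]),
           ks_planted = NA, omega = NA, array = a_id)
      }
    }
  }

  # ---- assemble genomes -----------------------------------------------------
  ref_index <- assemble_index(ref_rows, "reference", L)
  desc_index <- assemble_index(desc_rows, "descendant", L)

  aa_string <- function(seq) paste(ev$aa[seq], collapse = "")
  cds_string <- function(seq) paste0(paste(ev$codons[seq], collapse = ""),
                                     "TAA")
  ref_cds <- vapply(ref_rows, function(r) cds_string(r$seq), "")
  names(ref_cds) <- vapply(ref_rows, `[[`, "", "gene_id")
  desc_cds <- vapply(desc_rows, function(r) cds_string(r$seq), "")
  names(desc_cds) <- vapply(desc_rows, `[[`, "", "gene_id")
  ref_aa <- vapply(ref_rows, function(r) aa_string(r$seq), "")
  names(ref_aa) <- names(ref_cds)
  desc_aa <- vapply(desc_rows, function(r) aa_string(r$seq), "")
  names(desc_aa) <- names(desc_cds)

  ref_terms <- lapply(ref_rows, `[[`, "terms")
  names(ref_terms) <- names(ref_cds)
  desc_terms <- lapply(desc_rows, `[[`, "terms")
  names(desc_terms) <- names(desc_cds)

  # ---- hit table ------------------------------------------------------------
  sf_members <- list()
  add_member <- function(sf, id, aa) {
    key <- as.character(sf)
    sf_members[[key]] <<- c(sf_members[[key]], stats::setNames(list(aa), id))
  }
  for (i in seq_len(n_loci)) {
    add_member(loci[[i]]$superfamily, ref_ids[i], ev$aa[loci[[i]]$seq])
  }
  for (r in desc_rows) {
    add_member(loci[[r$locus]]$superfamily, r$gene_id, ev$aa[r$seq])
  }
  hit_rows <- make_hit_rows(sf_members)

  truth <- list(
    params = unclass(params),
    retention = retention,
    arrays = arrays_truth,
    pairs = truth_pairs,
    lineage = lineage,
    copy_gene = stats::setNames(
      lapply(seq_len(n_loci), function(i) as.list(copy_gene[i, ])), ref_ids))

  out <- structure(list(
    params = params,
    ref_index = ref_index, desc_index = desc_index,
    ref_cds = sequence_set(ref_cds, "cds"),
    desc_cds = sequence_set(desc_cds, "cds"),
    ref_protein = sequence_set(ref_aa, "protein"),
    desc_protein = sequence_set(desc_aa, "protein"),
    ref_terms = term_annotation(ref_terms),
    desc_terms = term_annotation(desc_terms),
    hits_raw = hit_rows,
    truth = truth), class = "synthetic_dataset")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(out_dir, x)
    write_gff3(ref_index, f("ref.gff3"))
    write_gff3(desc_index, f("desc.gff3"))
    writeLines(fasta_lines(ref_cds), f("ref_cds.fasta"))
    writeLines(fasta_lines(desc_cds), f("desc_cds.fasta"))
    writeLines(fasta_lines(ref_aa), f("ref_protein.fasta"))
    writeLines(fasta_lines(desc_aa), f("desc_protein.fasta"))
    write_term_table(out$ref_terms, f("ref_terms.tsv"))
    write_term_table(out$desc_terms, f("desc_terms.tsv"))
    utils::write.table(hit_rows, f("hits.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(truth, f("ground_truth.json"), auto_unbox = TRUE,
                         null = "null", digits = NA)
    out$files <- vapply(c("ref.gff3", "desc.gff3", "ref_cds.fasta",
                          "desc_cds.fasta", "ref_protein.fasta",
                          "desc_protein.fasta", "ref_terms.tsv",
                          "desc_terms.tsv", "hits.tsv",
                          "ground_truth.json"), f, "")
  }
  out
}

build_ancestral_loci <- function(params, ev, vocab, base_chrom, pre_hosts,
                                 cls_names, cls_prob, omega_of, L) {
  n_base <- params$n_ref_genes
  loci <- vector("list", 0)
  for (i in seq_len(n_base)) {
    nt <- sample(seq(params$terms_per_gene[1], params$terms_per_gene[2]), 1)
    base <- list(chrom = base_chrom[i], seq = random_codons(L, ev),
                 terms = sample(vocab, nt), superfamily = i,
                 pre_array = NA_integer_)
    k <- match(i, pre_hosts)
    if (!is.na(k)) base$pre_array <- k
    loci[[length(loci) + 1]] <- base
    if (!is.na(k)) {
      cl <- sample(cls_names, 1, prob = cls_prob)
      sib <- list(chrom = base$chrom,
                  seq = evolve_codons(base$seq, params$ks_tandem_pre,
                                      omega_of(cl), ev)$codons,
                  terms = mutate_terms(base$terms, cl, vocab),
                  superfamily = i, pre_array = k)
      loci[[length(loci) + 1]] <- sib
    }
  }
  loci
}

assemble_index <- function(rows, label, gene_length_codons) {
  chrom <- vapply(rows, `[[`, "", "chrom")
  pos <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  start <- (pos - 1L) * 3000L + 501L
  glen <- 3L * gene_length_codons + 3L   # including the terminal stop
  genes <- data.frame(gene_id = vapply(rows, `[[`, "", "gene_id"),
                      chromosome = chrom,
                      start = start, end = start + glen - 1L,
                      strand = sample(c("+", "-"), length(rows),
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  total <- sum(vapply(split(pos, chrom), max, 1L) * 3000 + 1000)
  gene_index(genes, label, total_length_bp = total)
}

fasta_lines <- function(seqs) {
  out <- character(2 * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  out
}

make_hit_rows <- function(sf_members) {
  q <- s <- character(0)
  ident <- numeric(0)
  len <- integer(0)
  for (key in names(sf_members)) {
    mem <- sf_members[[key]]
    ids <- names(mem)
    n <- length(ids)
    if (n < 2) next
    cmb <- utils::combn(n, 2)
    pid <- vapply(seq_len(ncol(cmb)), function(k) {
      mean(mem[[cmb[1, k]]] == mem[[cmb[2, k]]])
    }, numeric(1))
    l <- length(mem[[1]])
    # both directions, to exercise reciprocal-duplicate collapsing
    q <- c(q, ids[cmb[1, ]], ids[cmb[2, ]])
    s <- c(s, ids[cmb[2, ]], ids[cmb[1, ]])
    ident <- c(ident, pid, pid)
    len <- c(len, rep(l, 2 * ncol(cmb)))
  }
  out <- data.frame(q = q, s = s, pident = round(100 * ident, 2), len = len,
                    mismatch = as.integer(round(len * (1 - ident))),
                    gapopen = 0L, qstart = 1L, qend = len, sstart = 1L,
                    send = len, evalue = 1e-50,
                    bitscore = round(2 * len * pmax(ident, 0.05), 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> seed ", x$params$seed, ": ",
      nrow(x$ref_index$genes), " reference genes, ",
      nrow(x$desc_index$genes), " descendant genes, ",
      nrow(x$hits_raw), " hit rows\n", sep = "")
  invisible(x)
}
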