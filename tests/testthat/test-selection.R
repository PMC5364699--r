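# protein alignment, back-translation, NG86 Ka/Ks, filtering, class tests

test_that("alignment of identical and near-identical peptides", {
  a <- align_protein_pair("MKV", "MKV")
  expect_equal(a$protein_identity, 1)
  expect_equal(a$coverage, 1)
  expect_equal(a$aligned_a, "MKV")
  g <- align_protein_pair("MKV", "MV")
  expect_equal(nchar(g$aligned_a), 3)
  expect_equal(sum(strsplit(g$aligned_b, "")[[1]] == "-"), 1)
  expect_equal(g$protein_identity, 1)      # both aligned columns identical
  expect_equal(g$coverage, 1)              # 2 aligned of shorter length 2
  expect_error(align_protein_pair("MKB!", "MKV"), "invalid residue")
})

test_that("alignment scores match an independent affine DP on short peptides", {
  set.seed(81)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:40) {
    a <- paste(sample(aa, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:12, 1), TRUE), collapse = "")
    expect_equal(align_protein_pair(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("backtranslate expands residues to codons and gaps to ---", {
  aln <- list(aligned_a = "MK", aligned_b = "MK",
              protein_identity = 1, coverage = 1)
  ca <- backtranslate(aln, "ATGAAA", "ATGAAG")
  expect_s3_class(ca, "codon_alignment")
  expect_equal(ca$codons_a, c("ATG", "AAA"))
  expect_equal(ca$codons_b, c("ATG", "AAG"))   # third-position difference
  gap <- backtranslate(list(aligned_a = "MKV", aligned_b = "M-V",
                            protein_identity = 2 / 3, coverage = 1),
                       "ATGAAAGTT", "ATGGTA")
  expect_equal(gap$codons_b[2], "---")
  # internal stop excludes the pair with a reason (a lone terminal stop
  # would be trimmed, so the stop sits mid-sequence here)
  aln3 <- list(aligned_a = "MKV", aligned_b = "MKV",
               protein_identity = 1, coverage = 1)
  ex <- backtranslate(aln3, "ATGTAAGTT", "ATGAAAGTT")
  expect_s3_class(ex, "pair_exclusion")
  expect_equal(ex$reason, "internal_stop")
  mm <- backtranslate(aln, "ATGGGG", "ATGAAA")
  expect_equal(mm$reason, "translation_mismatch")
  # terminal stop on the cds is tolerated
  ok <- backtranslate(aln, "ATGAAATAA", "ATGAAG")
  expect_s3_class(ok, "codon_alignment")
})

test_that("NG86 on hand-checkable pairs", {
  # identical sequences: no differences, omega undefined
  cods <- random_sense_codons(100)
  r <- kaks_ng86(codon_aln(cods, cods))
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$S_sites + r$N_sites, 300)
  # one synonymous third-position change (CCT -> CCC)
  a <- c("CCT", rep("AAA", 9))
  b <- c("CCC", rep("AAA", 9))
  r <- kaks_ng86(codon_aln(a, b))
  o <- oracle_kaks(a, b)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$Ks, o$Ks)
  expect_equal(r$S_sites, o$S)
  # one nonsynonymous change (AAA -> GAA): Ks = 0, omega undefined
  b2 <- c("CCT", "GAA", rep("AAA", 8))
  a2 <- c("CCT", rep("AAA", 9))
  r2 <- kaks_ng86(codon_aln(a2, b2))
  o2 <- oracle_kaks(a2, b2)
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  expect_equal(r2$Ks, 0)
  expect_gt(r2$Ka, 0)
  expect_equal(r2$Ka, o2$Ka)
  expect_true(is.na(r2$omega))
})

test_that("NG86 agrees with the site/pathway oracle on random codon pairs", {
  set.seed(82)
  for (i in 1:40) {
    a <- random_sense_codons(10)
    b <- random_sense_codons(10)
    r <- kaks_ng86(codon_aln(a, b))
    o <- oracle_kaks(a, b)
    expect_equal(r$S_sites, o$S, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
    if (!r$saturated) {
      expect_equal(r$Ks, o$Ks, tolerance = 1e-12)
      expect_equal(r$Ka, o$Ka, tolerance = 1e-12)
    }
    # symmetry
    r2 <- kaks_ng86(codon_aln(b, a))
    expect_equal(r2$Ks, r$Ks)
    expect_equal(r2$Ka, r$Ka)
    # site identity
    expect_equal(r$S_sites + r$N_sites, 30)
  }
})

test_that("adding a synonymous difference never decreases Ks", {
  set.seed(83)
  ev <- asNamespace("paleodup")$evolve_tables()
  for (rep in 1:15) {
    a <- random_sense_codons(30)
    b <- a
    # each step creates one NEW synonymous difference at a so-far identical
    # codon (a mutation at an already-diverged codon could revert it)
    prev <- kaks_ng86(codon_aln(a, b))$Ks
    for (step in 1:6) {
      cand <- which(b == a &
                      ev$n_syn_opts[ev$idx[b]] > 0)
      if (length(cand) == 0) break
      j <- cand[sample.int(length(cand), 1)]
      opts <- ev$syn_opts[[ev$idx[[b[j]]]]]
      b[j] <- ev$codons[opts[sample.int(length(opts), 1)]]
      r <- kaks_ng86(codon_aln(a, b))
      if (r$saturated) break
      expect_gte(r$Ks + 1e-12, prev)
      prev <- r$Ks
    }
  }
})

test_that("gap and ambiguous columns are skipped; stops are an error", {
  r <- kaks_ng86(codon_aln(c("AAA", "---", "ANA", "CCT"),
                           c("AAA", "CCC", "AAA", "CCC")))
  expect_equal(r$n_codon_columns, 2)
  expect_error(kaks_ng86(codon_aln("TAA", "AAA")), "stop codon")
  expect_error(kaks_ng86(codon_aln("---", "AAA")), "no usable codon")
})

test_that("filter_pairs excludes by identity, coverage and saturation", {
  res <- data.frame(gene_a = sprintf("a%d", 1:4),
                    gene_b = sprintf("b%d", 1:4),
                    protein_identity = c(0.25, 0.9, 0.9, 0.9),
                    coverage = c(0.9, 0.4, 0.9, 0.9),
                    saturated = c(FALSE, FALSE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  f <- filter_pairs(res, min_identity = 0.3, min_coverage = 0.5)
  expect_equal(nrow(f$retained), 1)
  expect_setequal(f$excluded$reason,
                  c("low_identity", "low_coverage", "saturated"))
  prior <- data.frame(gene_a = "x", gene_b = "y", reason = "internal_stop")
  f2 <- filter_pairs(res, prior_exclusions = prior)
  expect_equal(nrow(f2$excluded), 4)
})

test_that("exact Mann-Whitney matches complete enumeration", {
  # {1,2,3} vs {4,5,6}: most extreme ranking, two-sided p = 2/20
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$p_value, oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)))
  # identical samples: midpoint U, p = 1
  mw2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p_value, 1)
  set.seed(84)
  for (i in 1:25) {
    x <- sample(1:10, sample(2:6, 1), TRUE)
    y <- sample(1:10, sample(2:6, 1), TRUE)
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p_value, oracle_mw_exact(x, y), info = i)
  }
  # tie-free cases also agree with stats::wilcox.test exact p
  for (i in 1:10) {
    x <- sample(seq(0, 1, by = 0.001), 6)
    y <- sample(seq(2, 3, by = 0.001), 5)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(85)
  x <- rnorm(30)
  y <- rnorm(40, 0.8)
  mine <- mann_whitney_u(x, y)
  expect_equal(mine$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("compare_classes recovers the planted selection-pressure ordering", {
  set.seed(86)
  ev <- asNamespace("paleodup")$evolve_tables()
  ta <- asNamespace("paleodup")$ng86_tables()
  rows <- list()
  for (cl in c("A_conserved", "C_neofunctionalized")) {
    om <- if (cl == "A_conserved") 0.15 else 0.4
    for (i in 1:25) {
      cod <- asNamespace("paleodup")$random_codons(150, ev)
      d <- asNamespace("paleodup")$evolve_codons(cod, 0.7, om, ev)$codons
      r <- kaks_ng86(codon_aln(ta$codons[cod], ta$codons[d]))
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = "x", gene_b = "y", class = cl, Ka = r$Ka, Ks = r$Ks,
        omega = r$omega, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  cmp <- compare_classes(res)
  st <- cmp$stats
  expect_lt(st$mean_omega[st$class == "A_conserved"],
            st$mean_omega[st$class == "C_neofunctionalized"])
  expect_lt(cmp$tests$p_value, 0.05)
  expect_error(compare_classes(res[res$class == "A_conserved", ]),
               ">= 2 classes")
})

test_that("kaks_pairs runs a pair table end to end with an exclusion log", {
  pairs <- structure(data.frame(
    gene_a = c("g1", "g3", "g5"), gene_b = c("g2", "g4", "g6"),
    pair_type = "wgd_duplicate", context = "x", stringsAsFactors = FALSE),
    class = c("gene_pairs", "data.frame"))
  cds <- sequence_set(c(
    g1 = "ATGAAACCTGGG", g2 = "ATGAAGCCAGGG",
    g3 = "ATGAAACCTGGG", g4 = "ATGTAACCTGGG",   # internal stop
    g5 = "ATGAAACCTGGG"), "cds")                # g6 missing
  out <- kaks_pairs(pairs, cds)
  expect_equal(nrow(out$results), 1)
  expect_equal(out$results$gene_a, "g1")
  expect_setequal(out$excluded$reason, c("internal_stop", "missing_sequence"))
})
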