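# End-to-end orchestration: inputs (or simulation) -> synteny -> pair
# classes -> divergence -> selection -> dating, with paper-shaped summary
# tables and a self-describing run report.

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to the real input artifacts) or
#' `simulate` (an [evolution_params()] or a list of its arguments) must be
#' given. Every stage parameter has an explicit default and is echoed into
#' the run report.
#'
#' @param inputs named list of paths: `ref_gff`, `desc_gff`, `ref_cds`,
#'   `desc_cds`, `ref_terms`, `desc_terms`, `hits` (optionally
#'   `ref_protein`, `desc_protein`).
#' @param simulate an [evolution_params()] (or argument list) for a
#'   synthetic run.
#' @param chain a [chain_params()].
#' @param max_intervening tandem-array spacing parameter.
#' @param min_identity,min_coverage Ka/Ks similarity filter thresholds.
#' @param ks_max,bandwidth Ks-density grid end and bandwidth rule.
#' @param families optional named list of term-id vectors defining gene
#'   families for event attribution.
#' @param out_dir optional output directory for all tables.
#' @param seed seed for a simulated run (ignored when `simulate` carries its
#'   own).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            chain = chain_params(), max_intervening = 1,
                            min_identity = 0.3, min_coverage = 0.5,
                            ks_max = 3.0, bandwidth = "silverman",
                            families = NULL, out_dir = NULL, seed = 1) {
  if (is.null(inputs) == is.null(simulate)) {
    stop("config error: exactly one of 'inputs' and 'simulate' must be set")
  }
  if (!is.null(simulate) && !inherits(simulate, "evolution_params")) {
    if (is.null(simulate$seed)) simulate$seed <- seed
    simulate <- do.call(evolution_params, simulate)
  }
  if (!is.null(inputs)) {
    need <- c("ref_gff", "desc_gff", "ref_cds", "desc_cds", "ref_terms",
              "desc_terms", "hits")
    missing_in <- setdiff(need, names(inputs))
    if (length(missing_in) > 0) {
      stop("config error: missing input path(s): ",
           paste(missing_in, collapse = ", "))
    }
    absent <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(absent) > 0) {
      stop("missing file(s): ", paste(absent, collapse = ", "))
    }
  }
  structure(list(inputs = inputs, simulate = simulate, chain = chain,
                 max_intervening = max_intervening,
                 min_identity = min_identity, min_coverage = min_coverage,
                 ks_max = ks_max, bandwidth = bandwidth, families = families,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file mirroring the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("inputs", "max_intervening", "min_identity", "min_coverage",
               "ks_max", "bandwidth", "out_dir", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$simulate)) args$simulate <- as.list(raw$simulate)
  if (!is.null(raw$chain)) args$chain <- do.call(chain_params,
                                                 as.list(raw$chain))
  if (!is.null(raw$families)) args$families <- lapply(raw$families, unlist)
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes input loading (or simulation), synteny-block chaining and
#' subgenome partition, pair-class derivation (orthologs, WGD duplicates,
#' tandem paralogs), fractionation accounting, divergence classification,
#' Ka/Ks estimation with filtering, class comparisons, Ks-density peak
#' dating and event ordering. All stage outputs and paper-shaped summary
#' tables are collected in the returned report (and written to
#' `config$out_dir` when set).
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  counts <- list()

  # ---- stage: inputs --------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_genomes(config$simulate)
    ref <- sim$ref_index
    desc <- sim$desc_index
    hits <- filter_hits(sim$hits_raw[, c(1, 2, 11, 12)] |>
                          stats::setNames(c("query_id", "subject_id",
                                            "evalue", "bitscore")),
                        config$chain$max_evalue)
    ref_terms <- sim$ref_terms
    desc_terms <- sim$desc_terms
    cds <- sequence_set(c(sim$ref_cds$sequences, sim$desc_cds$sequences),
                        "cds")
    proteins <- sequence_set(c(sim$ref_protein$sequences,
                               sim$desc_protein$sequences), "protein")
    truth <- sim$truth
  } else {
    inp <- config$inputs
    ref <- read_gff3(inp$ref_gff, "reference")
    desc <- read_gff3(inp$desc_gff, "descendant")
    hits <- read_hit_table(inp$hits, config$chain$max_evalue)
    ref_terms <- read_term_table(inp$ref_terms)
    desc_terms <- read_term_table(inp$desc_terms)
    ref_cds <- read_fasta(inp$ref_cds, "cds")
    desc_cds <- read_fasta(inp$desc_cds, "cds")
    cds <- sequence_set(c(ref_cds$sequences, desc_cds$sequences), "cds")
    proteins <- NULL
    if (!is.null(inp$ref_protein) && !is.null(inp$desc_protein)) {
      proteins <- sequence_set(
        c(read_fasta(inp$ref_protein, "protein")$sequences,
          read_fasta(inp$desc_protein, "protein")$sequences), "protein")
    }
    truth <- NULL
  }
  annotation <- term_annotation(c(unclass(ref_terms), unclass(desc_terms)))
  counts$genes_ref <- nrow(ref$genes)
  counts$genes_desc <- nrow(desc$genes)
  counts$hits <- nrow(hits)

  # ---- stage: synteny -------------------------------------------------------
  anchors <- build_anchors(hits, ref, desc)
  counts$anchors <- nrow(anchors)
  blocks <- chain_blocks(anchors, config$chain, ref, desc)
  counts$blocks <- nrow(blocks$blocks)
  assignment <- partition_subgenomes(blocks, ref)
  table1 <- block_stats(assignment, blocks, desc)

  # ---- stage: pair classes --------------------------------------------------
  orthologs <- orthologs_from_blocks(assignment, blocks)
  counts$ortholog_pairs <- nrow(orthologs)
  wgd <- wgd_pairs(orthologs)
  counts$wgd_pairs <- nrow(wgd)
  fract <- fractionation_summary(orthologs)
  arrays <- detect_tandem_arrays(desc, hits,
                                 max_intervening = config$max_intervening)
  counts$tandem_arrays <- nrow(arrays$arrays)
  tandem <- expand_array_pairs(arrays)
  counts$tandem_pairs <- nrow(tandem)
  array_dating <- date_tandem_arrays(arrays, orthologs)

  shared_cols <- c("gene_a", "gene_b", "pair_type", "context")
  all_pairs <- rbind(as.data.frame(orthologs)[, shared_cols],
                     as.data.frame(wgd)[, shared_cols],
                     as.data.frame(tandem)[, shared_cols])
  all_pairs$group <- ifelse(all_pairs$pair_type == "ortholog",
                            paste0("ortholog_", all_pairs$context),
                            all_pairs$pair_type)

  # ---- stage: divergence ----------------------------------------------------
  classified <- classify_pairs(all_pairs, annotation)
  table2 <- summarize_divergence(classified, by = "group")
  # Venn analogues: single-copy genes of the two subgenomes; WGD vs TD genes
  o <- as.data.frame(orthologs)
  co_ref <- fract$status$ref_gene[fract$status$status == "co_retained"]
  single1 <- o$desc_gene[o$subgenome == "subgenome1" & !(o$ref_gene %in% co_ref)]
  single2 <- o$desc_gene[o$subgenome == "subgenome2" & !(o$ref_gene %in% co_ref)]
  venn_single_copy <- term_overlap(unique(single1), unique(single2),
                                   annotation)
  wgd_genes <- unique(c(wgd$gene_a, wgd$gene_b))
  td_genes <- unique(arrays$members$gene_id)
  venn_wgd_td <- term_overlap(wgd_genes, td_genes, annotation)
  table4 <- NULL
  if (!is.null(config$families)) {
    table4 <- do.call(rbind, lapply(names(config$families), function(fam) {
      attribute_family(config$families[[fam]], annotation, wgd_genes,
                       td_genes, desc, family_label = fam)
    }))
  }

  # ---- stage: selection -----------------------------------------------------
  kk <- kaks_pairs(classified, cds, proteins)
  filt <- filter_pairs(kk$results, config$min_identity, config$min_coverage,
                       prior_exclusions = kk$excluded)
  counts$kaks_pairs <- nrow(kk$results)
  counts$kaks_retained <- nrow(filt$retained)
  comparisons <- list()
  for (grp in unique(filt$retained$group)) {
    g <- filt$retained[filt$retained$group == grp &
                         filt$retained$class != "unannotated", , drop = FALSE]
    cmp <- tryCatch(compare_classes(g), error = function(e) {
      note("class comparison skipped for ", grp, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(cmp)) comparisons[[grp]] <- cmp
  }

  # ---- stage: dating --------------------------------------------------------
  densities <- list()
  peaks <- list()
  for (grp in unique(filt$retained$group)) {
    ks <- filt$retained$Ks[filt$retained$group == grp]
    d <- tryCatch(ks_density(ks, pair_class = grp, ks_max = config$ks_max,
                             bandwidth = config$bandwidth),
                  error = function(e) {
                    note("Ks density skipped for ", grp, ": ",
                         conditionMessage(e))
                    NULL
                  })
    if (is.null(d)) next
    densities[[grp]] <- d
    peaks[[grp]] <- find_peaks(d)
  }
  ordering <- if (length(peaks) >= 2) order_events(peaks) else NULL

  # ---- table 3 analogue -----------------------------------------------------
  table3 <- data.frame(
    category = c("subgenome1", "subgenome2"),
    total_gene_pairs = c(fract$distinct_ref_genes, NA),
    retained = c(fract$retained_sub1, fract$retained_sub2),
    co_retained = c(fract$co_retained, NA),
    fractionated_or_specific = c(fract$retained_sub1 - fract$co_retained,
                                 fract$retained_sub2 - fract$co_retained),
    stringsAsFactors = FALSE)

  report <- structure(list(
    config = config, counts = counts, warnings = warnings_log,
    blocks = blocks, assignment = assignment,
    orthologs = orthologs, wgd = wgd, tandem = tandem,
    arrays = arrays, array_dating = array_dating,
    fractionation = fract, classified = classified,
    kaks = filt$retained, kaks_excluded = filt$excluded,
    comparisons = comparisons, densities = densities, peaks = peaks,
    ordering = ordering,
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    venn_single_copy = venn_single_copy, venn_wgd_td = venn_wgd_td,
    truth = truth), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  utils::str(x$counts, give.head = FALSE)
  if (!is.null(x$ordering)) cat(x$ordering$statement, "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  write_tsv(report$blocks$blocks, f("blocks.tsv"))
  write_tsv(report$blocks$anchors, f("anchors.tsv"))
  write_tsv(report$assignment$table, f("subgenomes.tsv"))
  write_tsv(report$classified, f("pairs.tsv"))
  write_tsv(report$arrays$arrays, f("tandem_arrays.tsv"))
  write_tsv(report$array_dating$dating, f("tandem_dating.tsv"))
  write_tsv(report$kaks, f("kaks.tsv"))
  write_tsv(report$kaks_excluded, f("kaks_excluded.tsv"))
  write_tsv(as.data.frame(report$table1), f("table1_synteny.tsv"))
  write_tsv(as.data.frame(report$table2), f("table2_divergence.tsv"))
  write_tsv(report$table3, f("table3_fractionation.tsv"))
  if (!is.null(report$table4)) {
    write_tsv(as.data.frame(report$table4), f("table4_families.tsv"))
  }
  venn <- list(
    single_copy_subgenomes = venn_counts(report$venn_single_copy),
    wgd_vs_tandem = venn_counts(report$venn_wgd_td))
  jsonlite::write_json(venn, f("venn.json"), auto_unbox = TRUE)
  pk <- lapply(report$peaks, function(p) {
    list(primary_mode = p$primary_mode, flat = p$flat,
         modes = p$modes)
  })
  jsonlite::write_json(list(peaks = pk,
                            ordering = if (!is.null(report$ordering))
                              report$ordering$table else NULL),
                       f("ks_peaks.json"), auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  jsonlite::write_json(list(counts = report$counts,
                            warnings = report$warnings,
                            config = cfg[setdiff(names(cfg), "families")]),
                       f("report.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(out_dir)
}

venn_counts <- function(v) {
  list(only_a = length(v$terms_only_a), shared = length(v$terms_shared),
       only_b = length(v$terms_only_b),
       prop_annotated_a = v$prop_annotated_a,
       prop_annotated_b = v$prop_annotated_b)
}
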