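# ---- gene index -------------------------------------------------------------

#' Build a gene index from a gene table
#'
#' A gene index is the coordinate backbone of every downstream analysis: a
#' table of positioned gene models with, per chromosome, a 0-based rank order
#' by ascending start coordinate (ties broken on end, then gene id).
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`. Coordinates are 1-based inclusive.
#' @param genome_label character scalar naming the genome.
#' @param total_length_bp assembled genome length in bp; if `NULL`, the sum
#'   over chromosomes of the maximum gene end is used.
#' @return An object of class `gene_index`: a list with elements
#'   `genome_label`, `genes` (the table plus a `rank` column) and
#'   `total_length_bp`.
#' @export
gene_index <- function(genes, genome_label, total_length_bp = NULL) {
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene IDs in '", genome_label, "': ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end]
    stop("start > end for gene(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  ord <- order(genes$chromosome, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- as.integer(stats::ave(genes$start, genes$chromosome,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  if (is.null(total_length_bp)) {
    total_length_bp <- sum(vapply(split(genes$end, genes$chromosome),
                                  max, numeric(1)))
  }
  structure(list(genome_label = genome_label,
                 genes = genes,
                 total_length_bp = as.numeric(total_length_bp)),
            class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat("<gene_index> ", x$genome_label, ": ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chromosome)), " chromosomes, ",
      format(x$total_length_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Rank-ordered genes of one chromosome
#' @param index a `gene_index`
#' @param chromosome chromosome name
#' @return data.frame ordered by rank
#' @export
genes_on <- function(index, chromosome) {
  g <- index$genes[index$genes$chromosome == chromosome, , drop = FALSE]
  g[order(g$rank), , drop = FALSE]
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` features are used; one gene model per locus is assumed
#' (splice variants must be pre-collapsed). Ranks are assigned per chromosome
#' by ascending start with a deterministic tie-break on (start, end, gene_id).
#' `##sequence-region` pragmas, when present, supply the assembled length.
#'
#' @param path GFF3 file.
#' @param genome_label label for the resulting index.
#' @return a [gene_index()].
#' @export
read_gff3 <- function(path, genome_label) {
  lines <- readLines(path)
  seqlen <- 0
  has_region <- FALSE
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "#")) {
      if (startsWith(line, "##sequence-region")) {
        f <- strsplit(trimws(line), "[ \t]+")[[1]]
        if (length(f) >= 4 && !is.na(suppressWarnings(as.numeric(f[4])))) {
          seqlen <- seqlen + as.numeric(f[4])
          has_region <- TRUE
        }
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop("malformed GFF3 line ", i, " in '", path, "': expected 9 fields, got ",
           length(f))
    }
    if (tolower(f[3]) != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    }
    id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", f[9], perl = TRUE)
    if (identical(id, f[9]) && !grepl("ID=", f[9], fixed = TRUE)) {
      stop("malformed GFF3 line ", i, ": gene feature without ID attribute")
    }
    n <- n + 1L
    rows[[n]] <- data.frame(gene_id = id, chromosome = f[1],
                            start = start, end = end,
                            strand = if (f[7] %in% c("+", "-")) f[7] else "+",
                            stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows[seq_len(n)])
  if (is.null(genes)) stop("no gene features found in '", path, "'")
  gene_index(genes, genome_label,
             total_length_bp = if (has_region) seqlen else NULL)
}

#' Write a gene index back to GFF3
#' @param index a `gene_index`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(index, path) {
  g <- index$genes[order(index$genes$chromosome, index$genes$rank), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chrom in unique(g$chromosome)) {
    len <- max(g$end[g$chromosome == chrom])
    writeLines(sprintf("##sequence-region %s 1 %d", chrom, len), con)
  }
  writeLines(sprintf("%s\tpaleodup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chromosome, g$start, g$end, g$strand, g$gene_id), con)
  invisible(path)
}

# ---- homology hits ----------------------------------------------------------

#' Read an all-vs-all protein hit table
#'
#' Expects the standard tabular 12-column hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bitscore). Rows above the e-value threshold and
#' self hits are removed, and reciprocal duplicates are collapsed to one
#' undirected edge keeping the best bitscore (and the smallest e-value).
#'
#' @param path hit table file (TSV, no header).
#' @param max_evalue e-value threshold; rows with larger e-values are dropped.
#' @return data.frame of class `homolog_hits` with columns `query_id`,
#'   `subject_id` (canonical: query < subject), `evalue`, `bitscore`, and a
#'   `filter_counts` attribute recording how many rows each filter removed.
#' @export
read_hit_table <- function(path, max_evalue = 1e-20) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12) {
    stop("hit table must have 12 columns, found ", ncol(raw))
  }
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  if (anyNA(ev)) {
    stop("non-numeric e-value at row(s): ",
         paste(utils::head(which(is.na(ev)), 5), collapse = ", "))
  }
  bs <- suppressWarnings(as.numeric(raw[[12]]))
  hits <- data.frame(query_id = as.character(raw[[1]]),
                     subject_id = as.character(raw[[2]]),
                     evalue = ev, bitscore = bs,
                     stringsAsFactors = FALSE)
  filter_hits(hits, max_evalue)
}

#' Filter and canonicalize homology hits
#'
#' Applies the e-value filter, removes self hits and collapses reciprocal
#' duplicates. Idempotent: re-filtering at the same threshold is a no-op.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `evalue`, `bitscore`.
#' @inheritParams read_hit_table
#' @return canonical `homolog_hits` data.frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-20) {
  n_in <- nrow(hits)
  if (any(hits$evalue < 0)) stop("negative e-value in hit table")
  keep <- hits$evalue <= max_evalue
  n_evalue <- sum(!keep)
  hits <- hits[keep, , drop = FALSE]
  self <- hits$query_id == hits$subject_id
  n_self <- sum(self)
  hits <- hits[!self, , drop = FALSE]
  swap <- hits$query_id > hits$subject_id
  tmp <- hits$query_id[swap]
  hits$query_id[swap] <- hits$subject_id[swap]
  hits$subject_id[swap] <- tmp
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  ord <- order(-hits$bitscore, hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  dup <- duplicated(key[ord])
  n_collapsed <- sum(dup)
  hits <- hits[!dup, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, class = c("homolog_hits", "data.frame"),
            filter_counts = c(input = n_in, evalue_filtered = n_evalue,
                              self = n_self, collapsed = n_collapsed,
                              retained = nrow(hits)))
}

# ---- annotation terms -------------------------------------------------------

#' Read a gene-to-annotation-term table
#'
#' TSV with columns `gene_id`, `term_id` (one row per gene/term, header
#' optional). Terms are de-duplicated into proper sets. Genes absent from the
#' table are "unannotated".
#'
#' @param path TSV file.
#' @return object of class `term_annotation`: a named list mapping gene id to
#'   a character vector of term ids.
#' @export
read_term_table <- function(path) {
  raw <- tryCatch(utils::read.delim(path, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    warning("empty term table: '", path, "'")
    return(term_annotation(list()))
  }
  if (ncol(raw) < 2) stop("term table must have two columns")
  if (tolower(raw[1, 1]) %in% c("gene_id", "gene") &&
      tolower(raw[1, 2]) %in% c("term_id", "term", "interpro")) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    warning("term table has a header but no rows: '", path, "'")
    return(term_annotation(list()))
  }
  term_annotation(split(as.character(raw[[2]]), as.character(raw[[1]])))
}

#' Construct a term annotation from a gene -> terms list
#' @param terms named list of character vectors (term ids per gene).
#' @return a `term_annotation`.
#' @export
term_annotation <- function(terms) {
  terms <- lapply(terms, function(x) sort(unique(as.character(x))))
  terms <- terms[vapply(terms, length, 1L) > 0]
  structure(terms, class = "term_annotation")
}

#' Terms annotated to one gene
#' @param annotation a `term_annotation`
#' @param gene_id gene identifier
#' @return character vector of term ids (empty if unannotated).
#' @export
gene_terms <- function(annotation, gene_id) {
  t <- annotation[[gene_id]]
  if (is.null(t)) character(0) else t
}

#' Union of terms over a set of genes
#' @inheritParams gene_terms
#' @param gene_ids character vector of gene ids
#' @return sorted character vector of term ids.
#' @export
terms_of_genes <- function(annotation, gene_ids) {
  sort(unique(unlist(unclass(annotation)[intersect(gene_ids, names(annotation))],
                     use.names = FALSE)))
}

#' Write a term annotation to TSV
#' @param annotation a `term_annotation`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_term_table <- function(annotation, path) {
  genes <- rep(names(annotation), vapply(annotation, length, 1L))
  utils::write.table(data.frame(gene_id = genes,
                                term_id = unlist(annotation, use.names = FALSE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sequences --------------------------------------------------------------

CDS_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read gene sequences from FASTA
#'
#' Coding sequences are validated for alphabet (ACGTN) and frame: one
#' terminal stop codon is trimmed; sequences whose remaining length is not a
#' multiple of 3 are excluded (with a warning) and recorded as excluded — they
#' stay out of selection analyses only. Proteins have a terminal `*` trimmed
#' and are checked against the 20-letter amino-acid alphabet.
#'
#' @param path FASTA file; record ids must match gene ids.
#' @param kind `"cds"` or `"protein"`.
#' @return object of class `sequence_set`: list with `sequences` (named
#'   character vector), `kind`, and `excluded` (data.frame gene_id, reason).
#' @export
read_fasta <- function(path, kind = c("cds", "protein")) {
  kind <- match.arg(kind)
  set <- if (kind == "cds") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sequence_set(seqs, kind)
}

#' Construct a validated sequence set
#' @param sequences named character vector of sequences.
#' @param kind `"cds"` or `"protein"`.
#' @return a `sequence_set`; invalid records are moved to `excluded`.
#' @export
sequence_set <- function(sequences, kind = c("cds", "protein")) {
  kind <- match.arg(kind)
  excluded <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  terminal_stop <- logical(length(sequences))
  if (kind == "cds") {
    has_stop <- nchar(sequences) >= 3 &
      substr(sequences, nchar(sequences) - 2, nchar(sequences)) %in% STOP_CODONS
    sequences[has_stop] <- substr(sequences[has_stop], 1,
                                  nchar(sequences[has_stop]) - 3)
    terminal_stop <- has_stop
    bad_frame <- nchar(sequences) %% 3 != 0 | nchar(sequences) == 0
    bad_alpha <- grepl(paste0("[^", paste(CDS_ALPHABET, collapse = ""), "]"),
                       sequences)
    bad <- bad_frame | bad_alpha
    if (any(bad)) {
      warning(sum(bad), " cds record(s) excluded (frame or alphabet): ",
              paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
      excluded <- data.frame(
        gene_id = names(sequences)[bad],
        reason = ifelse(bad_alpha[bad], "invalid_alphabet", "frame"),
        stringsAsFactors = FALSE)
      terminal_stop <- terminal_stop[!bad]
      sequences <- sequences[!bad]
    }
  } else {
    ends_star <- endsWith(sequences, "*")
    sequences[ends_star] <- substr(sequences[ends_star], 1,
                                   nchar(sequences[ends_star]) - 1)
    bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                 sequences)
    if (any(bad)) {
      warning(sum(bad), " protein record(s) excluded (alphabet): ",
              paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
      excluded <- data.frame(gene_id = names(sequences)[bad],
                             reason = "invalid_alphabet",
                             stringsAsFactors = FALSE)
      sequences <- sequences[!bad]
    }
    terminal_stop <- ends_star[!bad]
  }
  structure(list(sequences = sequences, kind = kind,
                 terminal_stop = stats::setNames(terminal_stop, names(sequences)),
                 excluded = excluded),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", length(x$sequences), " ", x$kind, " sequences (",
      nrow(x$excluded), " excluded)\n", sep = "")
  invisible(x)
}

#' Write a sequence set to FASTA
#' @param set a `sequence_set`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  x <- Biostrings::BStringSet(set$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a data.frame as TSV with header
#' @param x data.frame
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
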