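#' Read DNA sequences from a FASTA file
#'
#' Parsing is delegated to Biostrings; records are then validated against the
#' contig contract: unique ids, non-empty sequences, alphabet restricted to
#' A/C/G/T/N (lowercase accepted and upper-cased).
#'
#' @param path FASTA file.
#' @return a [contig_set()] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record '", ids[empty][1], "' in ", path)
  contig_set(seqs, ids)
}

#' Write sequences to FASTA
#'
#' One sequence line per record (no wrapping), so write/read round-trips are
#' byte-stable.
#'
#' @param x named character vector of sequences (e.g. a [contig_set()]).
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(x), "\n", as.character(x)), con, sep = "\n")
  invisible(path)
}

#' Read sequencing reads from a FASTQ file
#'
#' Base qualities are parsed (the record structure is validated) but ignored;
#' quality trimming is assumed to have happened upstream.
#'
#' @param path FASTQ file.
#' @return a [read_set()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fastq"),
                error = function(e) stop("malformed FASTQ in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  read_set(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ (constant dummy quality "I")
#'
#' @param x a [read_set()] or named character vector.
#' @param path output file.
#' @export
write_fastq <- function(x, path) {
  qual <- vapply(nchar(x), function(n) strrep("I", n), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("@", names(x), "\n", as.character(x), "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Only rows with type `gene` are kept; the gene id is taken from the `ID`
#' attribute. Coordinates stay 1-based inclusive (GFF convention).
#'
#' @param path GFF3 file.
#' @return a [gene_annotation()].
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop("no gene features in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("gene feature without ID attribute in ", path)
  gene_annotation(ids, as.character(GenomicRanges::seqnames(gr)),
                  BiocGenerics::start(gr), BiocGenerics::end(gr),
                  as.character(BiocGenerics::strand(gr)))
}

#' Write gene features as GFF3
#'
#' @param ann a [gene_annotation()].
#' @param path output file.
#' @export
write_gff_genes <- function(ann, path) {
  rows <- sprintf("%s\tbchrom\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  ann$contig_id, ann$start, ann$end, ann$strand, ann$gene_id)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3", rows), con, sep = "\n")
  invisible(path)
}

#' Read a gene count matrix with sample metadata
#'
#' The count table is a TSV with gene ids in the first column and one column
#' per sample; the metadata TSV has columns `sample_id`, `stage`, `b_status`,
#' `replicate`. Columns are aligned to the metadata order, so the two files
#' may list samples in different orders.
#'
#' @param path counts TSV.
#' @param metadata_path sample metadata TSV.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, metadata_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  rownames(m) <- genes
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  cm <- count_matrix(m, meta)
  # canonical sample order: metadata file order restricted to matrix columns
  ord <- meta$sample_id[meta$sample_id %in% colnames(m)]
  cm$counts <- cm$counts[, ord, drop = FALSE]
  cm$samples <- cm$samples[match(ord, cm$samples$sample_id), , drop = FALSE]
  rownames(cm$samples) <- NULL
  cm
}

#' Write a count matrix and its metadata as TSVs
#'
#' @param cm a [count_matrix()].
#' @param path counts TSV path.
#' @param metadata_path metadata TSV path.
#' @export
write_counts_tsv <- function(cm, path, metadata_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, path)
  write_tsv(cm$samples, metadata_path)
  invisible(path)
}

#' Read an ontology edge list (child TAB parent)
#'
#' @param path TSV with columns `child`, `parent` (header optional if the
#'   first row parses as two term ids named `child`/`parent`).
#' @return an [ontology_dag()].
#' @export
read_ontology_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(tab)))
    stop("ontology edge file needs 'child' and 'parent' columns")
  ontology_dag(tab$child, tab$parent)
}

#' Read a gene-to-term map (long TSV: gene_id TAB term_id)
#'
#' @param path TSV with columns `gene_id`, `term_id`.
#' @param dag the [ontology_dag()] the terms must belong to.
#' @return a [gene_term_map()].
#' @export
read_gene_term_tsv <- function(path, dag) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tab)))
    stop("gene-term file needs 'gene_id' and 'term_id' columns")
  gene_term_map(split(tab$term_id, tab$gene_id), dag)
}

# Deterministic TSV writer used for every result table.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

# Long-format writer for a gene_term_map.
write_gene_term_tsv <- function(map, path) {
  genes <- rep(names(map), lengths(map))
  write_tsv(data.frame(gene_id = genes, term_id = unlist(map, use.names = FALSE),
                       stringsAsFactors = FALSE), path)
}

write_ontology_tsv <- function(dag, path) {
  write_tsv(dag$edges[, c("child", "parent")], path)
}
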