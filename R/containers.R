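#' Contig set
#'
#' An ordered set of named DNA sequences (assembly contigs, repeat monomers).
#' Stored as a named character vector with class `contig_set`; ids must be
#' unique, sequences non-empty and restricted to A/C/G/T/N.
#'
#' @param sequences character vector of DNA sequences.
#' @param ids character vector of unique contig ids.
#' @return a `contig_set`.
#' @export
contig_set <- function(sequences, ids = names(sequences)) {
  if (is.null(ids)) stop("contig ids are required")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate contig id: ", ids[duplicated(ids)][1])
  if (any(!nzchar(sequences))) stop("empty sequence for contig ", ids[!nzchar(sequences)][1])
  sequences <- toupper(as.character(sequences))
  assert_dna(sequences, "contig")
  structure(setNames(sequences, ids), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d sequence(s), total %d bp\n",
              length(x), sum(nchar(x))))
  invisible(x)
}

#' @export
`[.contig_set` <- function(x, i) {
  out <- unclass(x)[i]
  structure(out, class = "contig_set")
}

#' Read set
#'
#' Sequencing reads as a named character vector with class `read_set`.
#'
#' @param sequences character vector of read sequences.
#' @param ids read ids (unique).
#' @return a `read_set`.
#' @export
read_set <- function(sequences, ids = names(sequences)) {
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(sequences))
  sequences <- toupper(as.character(sequences))
  assert_dna(sequences, "read")
  structure(setNames(sequences, ids), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d read(s), total %d bp\n", length(x), sum(nchar(x))))
  invisible(x)
}

#' Total k-mer mass of a read set
#'
#' The number of length-`k` windows over all reads,
#' `sum(max(0, len - k + 1))`. Used to depth-normalize summed k-mer counts.
#'
#' @param reads a `read_set` (or character vector of sequences).
#' @param k window size.
#' @return a single number.
#' @export
total_kmer_mass <- function(reads, k) {
  sum(pmax(0L, nchar(reads) - as.integer(k) + 1L))
}

#' Gene annotation table
#'
#' @param gene_id,contig_id,start,end,strand parallel vectors; coordinates are
#'   1-based inclusive, strand is "+" or "-".
#' @return a `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, contig_id, start, end, strand = "+") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1])
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(start > end))
    stop("gene coordinates must satisfy 1 <= start <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = gene_id, contig_id = as.character(contig_id),
                   start = start, end = end,
                   strand = rep_len(strand, length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Count matrix with sample metadata
#'
#' Genes x samples non-negative integer counts plus a metadata table with one
#' row per sample: `sample_id`, `stage` (early/mid/late/lcm), `b_status`
#' (0B/+B) and `replicate`.
#'
#' @param counts integer matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data.frame of sample metadata.
#' @return a `count_matrix` (list with elements `counts`, `samples`).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("negative count found")
  if (any(counts != round(counts))) stop("non-integer count found")
  storage.mode(counts) <- "integer"
  req <- c("sample_id", "stage", "b_status", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample metadata must contain columns: ", paste(req, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(samples$stage %in% c("early", "mid", "late", "lcm")))
    stop("stage must be one of early, mid, late, lcm")
  if (!all(samples$b_status %in% c("0B", "+B")))
    stop("b_status must be '0B' or '+B'")
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing))
    stop("sample(s) in count matrix missing from metadata: ",
         paste(missing, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(stage = x$samples$stage, b_status = x$samples$b_status))
  invisible(x)
}

#' Ontology DAG
#'
#' Directed acyclic graph of ontology terms given as a child -> parent edge
#' list. Acyclicity is verified at construction.
#'
#' @param child,parent character vectors of term ids (edges child -> parent).
#' @param terms optional character vector of all term ids (defaults to the ids
#'   appearing in the edges).
#' @return an `ontology_dag` (list with `edges` data.frame and `terms`).
#' @export
ontology_dag <- function(child, parent, terms = NULL) {
  edges <- data.frame(child = as.character(child), parent = as.character(parent),
                      stringsAsFactors = FALSE)
  terms <- sort(unique(c(terms, edges$child, edges$parent)))
  dag <- structure(list(edges = edges, terms = terms), class = "ontology_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc))
    stop("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "))
  dag
}

# Kahn topological sort; returns one cycle (as a term path) or NULL.
find_cycle <- function(dag) {
  terms <- dag$terms
  parents <- split(dag$edges$parent, factor(dag$edges$child, levels = terms))
  indeg <- table(factor(dag$edges$parent, levels = terms))
  active <- setNames(rep(TRUE, length(terms)), terms)
  queue <- terms[indeg == 0]
  n_removed <- 0L
  indeg <- setNames(as.integer(indeg), terms)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    active[t] <- FALSE; n_removed <- n_removed + 1L
    for (p in parents[[t]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (n_removed == length(terms)) return(NULL)
  # walk within the residual subgraph to exhibit one cycle
  rem <- names(active)[active]
  nxt <- vapply(rem, function(t) {
    ps <- parents[[t]]
    ps[ps %in% rem][1]
  }, character(1))
  path <- rem[1]
  repeat {
    nx <- nxt[[path[length(path)]]]
    if (nx %in% path) return(c(path[which(path == nx):length(path)], nx))
    path <- c(path, nx)
  }
}

# child -> parents adjacency list over all dag terms
dag_parents <- function(dag) {
  split(dag$edges$parent, factor(dag$edges$child, levels = dag$terms))
}

# child lists (term -> direct children)
dag_children <- function(dag) {
  split(dag$edges$child, factor(dag$edges$parent, levels = dag$terms))
}

#' Gene-to-term annotation map
#'
#' @param map named list: gene id -> character vector of term ids.
#' @param dag an [ontology_dag()]; all terms must be present in it.
#' @return a `gene_term_map` (named list).
#' @export
gene_term_map <- function(map, dag) {
  bad <- setdiff(unique(unlist(map)), dag$terms)
  if (length(bad))
    stop("annotation uses term(s) absent from the ontology: ",
         paste(utils::head(bad, 5), collapse = ", "))
  structure(lapply(map, unique), class = "gene_term_map")
}
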