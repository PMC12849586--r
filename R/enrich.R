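#' Propagate gene annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. The closure is idempotent; ancestors reached along multiple
#' paths (diamonds) are counted once.
#'
#' @param map a [gene_term_map()] (direct annotations).
#' @param dag an [ontology_dag()].
#' @return a closed `gene_term_map`.
#' @export
propagate_annotations <- function(map, dag) {
  parents <- dag_parents(dag)
  anc_cache <- new.env(parent = emptyenv())
  ancestors_of <- function(t) {
    if (exists(t, envir = anc_cache, inherits = FALSE))
      return(get(t, envir = anc_cache))
    out <- character(0)
    frontier <- parents[[t]]
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier],
                                        use.names = FALSE)), out)
    }
    assign(t, out, envir = anc_cache)
    out
  }
  closed <- lapply(map, function(terms) {
    sort(unique(c(terms, unlist(lapply(terms, ancestors_of),
                                use.names = FALSE))))
  })
  gene_term_map(closed, dag)
}

#' Hypergeometric term enrichment against a restricted universe
#'
#' For each term annotated to at least one universe gene, computes the
#' upper-tail hypergeometric probability of drawing at least `k` annotated
#' genes in a study sample of size `n` from a universe of size `N` containing
#' `K` annotated genes:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The universe is deliberately restricted (here: the B-located gene set) so
#' terms that are merely over-represented on the whole B chromosome do not
#' masquerade as stage-specific signal.
#'
#' @param study_genes character vector (must be a subset of the universe).
#' @param universe_genes character vector (the reference gene set).
#' @param closed_map a closed [gene_term_map()] (see
#'   [propagate_annotations()]).
#' @param enrich_alpha significance threshold (`p <= enrich_alpha`, ties
#'   significant).
#' @return data.frame: `term_id`, `k`, `K`, `n`, `N`, `p`, `significant`,
#'   sorted by `term_id`.
#' @export
hypergeom_enrich <- function(study_genes, universe_genes, closed_map,
                             enrich_alpha = 0.05) {
  study_genes <- unique(study_genes)
  universe_genes <- unique(universe_genes)
  outside <- setdiff(study_genes, universe_genes)
  if (length(outside))
    stop("study gene(s) outside the universe: ", paste(outside, collapse = ", "))
  uni_map <- closed_map[intersect(names(closed_map), universe_genes)]
  terms <- sort(unique(unlist(uni_map, use.names = FALSE)))
  N <- length(universe_genes)
  n <- length(study_genes)
  rows <- lapply(terms, function(t) {
    annotated <- names(uni_map)[vapply(uni_map, function(x) t %in% x, logical(1))]
    K <- length(annotated)
    k <- length(intersect(annotated, study_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, p = p,
               significant = p <= enrich_alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame(term_id = character(0), k = integer(0),
                                       K = integer(0), n = integer(0),
                                       N = integer(0), p = numeric(0),
                                       significant = logical(0))
}

#' Keep terminal significant terms
#'
#' A term is terminal-significant when it is significant and none of its
#' descendants (within the DAG, among the tested terms) is significant. This
#' operationalizes reporting "terminal nodes" of an enrichment graph.
#'
#' @param results data.frame from [hypergeom_enrich()].
#' @param dag an [ontology_dag()].
#' @param enrich_alpha significance threshold (recomputed from `p` so the
#'   function is self-contained).
#' @return `results` with a logical `terminal_significant` column.
#' @export
select_terminal_significant <- function(results, dag, enrich_alpha = 0.05) {
  results <- results[order(results$term_id), , drop = FALSE]
  sig <- results$term_id[results$p <= enrich_alpha]
  children <- dag_children(dag)
  descendants_of <- function(t) {
    out <- character(0)
    frontier <- children[[t]] %||% character(0)
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- setdiff(unique(unlist(children[frontier],
                                        use.names = FALSE)), out)
    }
    out
  }
  results$significant <- results$p <= enrich_alpha
  results$terminal_significant <- vapply(seq_len(nrow(results)), function(i) {
    t <- results$term_id[i]
    if (!results$significant[i]) return(FALSE)
    desc <- descendants_of(t)
    !any(desc %in% sig)
  }, logical(1))
  rownames(results) <- NULL
  results
}

#' Venn-region tallies of per-stage gene sets
#'
#' Counts every non-empty intersection pattern of the given sets; the region
#' counts sum to the size of the union.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return data.frame with one row per pattern: logical membership columns,
#'   `count`, and a `pattern` label like `"mid&late"`.
#' @export
stage_overlaps <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 stage sets")
  nm <- names(sets)
  genes <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, nm))
  pat <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  for (s in nm) out[[s]] <- vapply(strsplit(out$pattern, "&", fixed = TRUE),
                                   function(x) s %in% x, logical(1))
  out[order(out$pattern), c("pattern", nm, "count")]
}

#' Assemble the candidate-gene table
#'
#' A candidate is a B-located up-regulated gene (in the mid, late or LCM
#' analysis) annotated -- through the closed map -- to at least one term that
#' is terminal-significant in the corresponding analysis *and* listed in the
#' user-curated `relevant_terms`. One row per gene records which analyses
#' detected it and which terms support it.
#'
#' @param enrich_by_stage named list (`mid`, `late`) of
#'   [select_terminal_significant()] outputs for the whole-embryo analyses.
#' @param up_by_stage named list (`mid`, `late`) of B-located up-gene sets.
#' @param lcm_enrich [select_terminal_significant()] output for the LCM
#'   analysis (or `NULL`).
#' @param lcm_up B-located up-genes of the LCM analysis.
#' @param relevant_terms non-empty character vector of curated term ids.
#' @param closed_map closed [gene_term_map()].
#' @return data.frame: `gene_id`, `stages_detected`, `lcm_detected`,
#'   `supporting_terms` (both list columns flattened to `;`-joined strings),
#'   sorted by gene id.
#' @export
build_candidate_table <- function(enrich_by_stage, up_by_stage,
                                  lcm_enrich = NULL, lcm_up = character(0),
                                  relevant_terms, closed_map) {
  if (length(relevant_terms) == 0)
    stop("relevant_terms must be an explicit, non-empty configuration")
  analyses <- names(up_by_stage)
  hits <- list()
  add_hits <- function(up, enr, label) {
    if (is.null(enr) || !nrow(enr)) return()
    ok_terms <- intersect(enr$term_id[enr$terminal_significant],
                          relevant_terms)
    if (!length(ok_terms)) return()
    for (g in up) {
      gt <- intersect(closed_map[[g]] %||% character(0), ok_terms)
      if (length(gt))
        hits[[length(hits) + 1L]] <<- data.frame(
          gene_id = g, analysis = label,
          term = paste(sort(gt), collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  for (st in analyses) add_hits(up_by_stage[[st]], enrich_by_stage[[st]], st)
  add_hits(lcm_up, lcm_enrich, "lcm")
  if (!length(hits))
    return(data.frame(gene_id = character(0), stages_detected = character(0),
                      lcm_detected = logical(0),
                      supporting_terms = character(0),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  out <- do.call(rbind, lapply(split(h, h$gene_id), function(d) {
    stages <- setdiff(unique(d$analysis), "lcm")
    data.frame(gene_id = d$gene_id[1],
               stages_detected = paste(sort(stages), collapse = ";"),
               lcm_detected = "lcm" %in% d$analysis,
               supporting_terms = paste(sort(unique(unlist(
                 strsplit(d$term, ";", fixed = TRUE)))), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curated default of highlighted ontology terms
#'
#' The mitosis/kinetochore/cohesion-flavoured term list used as the default
#' `relevant_terms` configuration; always explicit, never inferred.
#'
#' @return character vector of term ids.
#' @export
default_relevant_terms <- function() {
  c("GO:0000070", "GO:0065004", "GO:0016926", "GO:0016747", "GO:0016929",
    "GO:0005634", "GO:0000776", "GO:0003690", "GO:0008094", "GO:0000226",
    "GO:0015630")
}
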