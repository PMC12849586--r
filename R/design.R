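#' Plant an ontology with enriched terms for given candidate sets
#'
#' Builds a small GO-style DAG (a root, three namespace nodes, one parent per
#' relevant leaf term, plus noise terms) and a gene-to-term map in which each
#' planted candidate set is annotated to its own relevant leaf term at high
#' odds, while non-candidate genes receive noise-term annotations. With the
#' B-located genes as universe this makes each relevant term significantly
#' enriched in the analysis whose up-set contains its candidates, and
#' terminal (the leaves have no descendants).
#'
#' @param universe_genes B-located gene ids (the enrichment universe).
#' @param candidate_sets named list of candidate gene vectors; names are used
#'   to pick a relevant term per set (`mid`, `late`, `both`, `lcm`).
#' @param background_per_term universe genes (non-candidates) co-annotated to
#'   each relevant term, so K > k.
#' @param n_noise_terms number of noise leaf terms.
#' @param exclude genes that must never receive a relevant-term annotation
#'   (e.g. planted up-genes meant to be filtered out by the enrichment step).
#' @param seed integer seed.
#' @return list: `dag` ([ontology_dag()]), `map` ([gene_term_map()]),
#'   `relevant_terms`, `enriched_terms_truth`.
#' @export
simulate_go_annotation <- function(universe_genes, candidate_sets,
                                   background_per_term = 5L,
                                   n_noise_terms = 12L,
                                   exclude = character(0), seed = 1L) {
  term_for <- c(mid = "GO:0000070", late = "GO:0000776", both = "GO:0065004",
                lcm = "GO:0000226")
  parent_for <- c(mid = "GO:0007059", late = "GO:0000775",
                  both = "GO:0071824", lcm = "GO:0007010")
  ns_for <- c(mid = "GO:BP", late = "GO:CC", both = "GO:BP", lcm = "GO:BP")
  used <- names(candidate_sets)
  if (!all(used %in% names(term_for)))
    stop("candidate_sets names must be among: ",
         paste(names(term_for), collapse = ", "))
  with_seed(derive_seed(seed, "go"), {
    noise_terms <- sprintf("GO:n%04d", seq_len(n_noise_terms))
    child <- c("GO:BP", "GO:MF", "GO:CC",
               parent_for[used], term_for[used], noise_terms)
    parent <- c("GO:ROOT", "GO:ROOT", "GO:ROOT",
                ns_for[used], parent_for[used],
                sample(c("GO:BP", "GO:MF", "GO:CC"), n_noise_terms,
                       replace = TRUE))
    dag <- ontology_dag(child, parent)

    map <- setNames(vector("list", length(universe_genes)), universe_genes)
    for (g in universe_genes)
      map[[g]] <- sample(noise_terms, sample(0:2, 1))
    for (nm in used) {
      annotated <- candidate_sets[[nm]]
      bg_pool <- setdiff(universe_genes, c(unlist(candidate_sets), exclude))
      bg <- sample(bg_pool, min(background_per_term, length(bg_pool)))
      for (g in c(annotated, bg))
        map[[g]] <- unique(c(map[[g]], term_for[[nm]]))
    }
    map <- map[lengths(map) > 0]
    list(dag = dag, map = gene_term_map(map, dag),
         relevant_terms = unname(term_for[used]),
         enriched_terms_truth = unname(term_for[used]))
  })
}

#' Design-level simulation of the candidate-screen world
#'
#' Generates a virtual annotation (no sequences), planted per-stage
#' up-regulated B gene sets with the mid/late/both/LCM-only structure of a
#' whole-embryo + microdissection screen, extra up-regulated B genes that are
#' *not* annotated to any relevant term (they must be filtered out by the
#' enrichment step), and the planted ontology from
#' [simulate_go_annotation()].
#'
#' @param n_a_genes,n_b_genes numbers of A- and B-located genes.
#' @param n_mid_only,n_late_only,n_both whole-embryo candidate counts
#'   (defaults 8/6/7, i.e. 21 candidates).
#' @param n_lcm_only candidates detected only in the LCM analysis (7).
#' @param n_extra_per_stage planted up-genes per analysis without relevant
#'   annotation.
#' @param seed integer seed.
#' @return list: `annotation`, `truth` (with `b_contigs`, `b_genes`,
#'   `candidates_truth`), `planted_up`, `dag`, `map`, `relevant_terms`.
#' @export
simulate_candidate_design <- function(n_a_genes = 350L, n_b_genes = 150L,
                                      n_mid_only = 8L, n_late_only = 6L,
                                      n_both = 7L, n_lcm_only = 7L,
                                      n_extra_per_stage = 5L, seed = 1L) {
  need <- n_mid_only + n_late_only + n_both + n_lcm_only +
    3L * n_extra_per_stage
  if (need > n_b_genes)
    stop("n_b_genes too small for the requested planted sets")
  with_seed(derive_seed(seed, "design"), {
    n <- n_a_genes + n_b_genes
    ids <- sprintf("g%05d", seq_len(n))
    a_genes <- ids[seq_len(n_a_genes)]
    b_genes <- ids[(n_a_genes + 1L):n]
    contig <- c(sprintf("A_%02d", 1L + (seq_len(n_a_genes) %% 10L)),
                sprintf("B_%02d", 1L + (seq_along(b_genes) %% 6L)))
    start <- 1000L * seq_len(n)
    ann <- gene_annotation(ids, contig, start, start + 299L)

    pool <- sample(b_genes)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    mid_only <- take(n_mid_only); late_only <- take(n_late_only)
    both <- take(n_both); lcm_only <- take(n_lcm_only)
    extra <- list(mid = take(n_extra_per_stage),
                  late = take(n_extra_per_stage),
                  lcm = take(n_extra_per_stage))
    planted_up <- list(mid = c(mid_only, both, extra$mid),
                      late = c(late_only, both, extra$late),
                      lcm = c(lcm_only, extra$lcm))
    go <- simulate_go_annotation(
      b_genes, list(mid = mid_only, late = late_only, both = both,
                    lcm = lcm_only), exclude = unlist(extra),
      seed = derive_seed(seed, "design-go"))
    truth <- list(b_contigs = sprintf("B_%02d", 1:6), b_genes = b_genes,
                  candidates_truth = sort(c(mid_only, late_only, both,
                                            lcm_only)),
                  de_truth = planted_up)
    list(annotation = ann, truth = truth, planted_up = planted_up,
         dag = go$dag, map = go$map, relevant_terms = go$relevant_terms)
  })
}

#' Run the candidate-gene screen from counts to the candidate table
#'
#' Per-stage differential expression (mid, late and -- when present -- lcm),
#' restriction of up-calls to B-located genes, hypergeometric enrichment of
#' each B-up set against the B-only universe, terminal-term selection, and
#' candidate-table assembly.
#'
#' @param cm a [count_matrix()].
#' @param annotation a [gene_annotation()].
#' @param b_contig_ids contig ids classified/known as B.
#' @param dag,map ontology and (direct) annotation map.
#' @param relevant_terms curated term list.
#' @param config a [run_config()].
#' @return list: `de` (per analysed stage), `b_up` (per-stage B-located
#'   up-sets, including early when present), `enrichment`
#'   (per analysis), `overlaps` (Venn tallies of the whole-embryo stages),
#'   `candidates` (final table).
#' @export
candidate_screen <- function(cm, annotation, b_contig_ids, dag, map,
                             relevant_terms = default_relevant_terms(),
                             config = run_config()) {
  closed <- propagate_annotations(map, dag)
  universe <- annotation$gene_id[annotation$contig_id %in% b_contig_ids]
  stages <- intersect(c("early", "mid", "late", "lcm"),
                      unique(cm$samples$stage))
  de <- list(); b_up <- list(); enr <- list()
  for (st in stages) {
    d <- de_test(cm, st, config)
    de[[st]] <- d
    up <- d$gene_id[d$call == "up"]
    b_up[[st]] <- match_to_b_contigs(up, annotation, b_contig_ids)
    if (st %in% c("mid", "late", "lcm")) {
      study <- intersect(b_up[[st]], universe)
      e <- hypergeom_enrich(study, universe, closed, config$enrich_alpha)
      enr[[st]] <- select_terminal_significant(e, dag, config$enrich_alpha)
    }
  }
  embryo <- intersect(c("early", "mid", "late"), names(b_up))
  overlaps <- if (length(embryo) >= 2) stage_overlaps(b_up[embryo]) else NULL
  candidates <- build_candidate_table(
    enrich_by_stage = enr[intersect(c("mid", "late"), names(enr))],
    up_by_stage = b_up[intersect(c("mid", "late"), names(b_up))],
    lcm_enrich = enr[["lcm"]],
    lcm_up = b_up[["lcm"]] %||% character(0),
    relevant_terms = relevant_terms, closed_map = closed)
  list(de = de, b_up = b_up, enrichment = enr, overlaps = overlaps,
       candidates = candidates)
}
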