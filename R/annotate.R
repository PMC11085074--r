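#' Root-level GO biological process terms excluded from enrichment
#'
#' Terms at or near the root of the BP hierarchy (biological_process,
#' cellular process, metabolic process, response to stimulus, generic
#' regulation terms, ...) annotate so many genes that their enrichment
#' is uninformative; they are removed on load and asserted absent from
#' every downstream result.
#'
#' @return Character vector of the 15 excluded GO ids.
#' @export
go_root_exclusion <- function() {
  c("GO:0008150", "GO:0009987", "GO:0008152", "GO:0044237", "GO:0071704",
    "GO:0050896", "GO:0065007", "GO:0032502", "GO:0050789", "GO:0032501",
    "GO:0007275", "GO:0050794", "GO:0006355", "GO:0045893", "GO:0045892")
}

#' Default evidence-code whitelist (experimental and curated)
#' @return Character vector of accepted GO evidence codes.
#' @export
default_evidence_whitelist <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")
}

#' Load GO biological-process annotations
#'
#' Accepts either a simplified 4-column TSV (`gene_id`, `term_id`,
#' `aspect`, `evidence`; header optional) or GAF 2.x (17 columns, `!`
#' comments). Keeps BP-aspect rows (`P`/`BP`) passing the evidence
#' whitelist, drops root-level terms, and skips malformed rows with a
#' warning count.
#'
#' @param path Annotation file path.
#' @param evidence_whitelist Accepted evidence codes; `NULL` keeps all.
#' @param root_exclusion Term ids to drop (default
#'   [go_root_exclusion()]).
#' @return A `GOAnnotationSet` data frame with columns `gene_id`,
#'   `term_id`.
#' @export
load_annotations <- function(path, evidence_whitelist = default_evidence_whitelist(),
                             root_exclusion = go_root_exclusion()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!") & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  gaf <- any(nf >= 15)
  if (gaf) {
    ok <- nf >= 15
    gene <- vapply(parts[ok], `[[`, "", 2)   # DB object id
    term <- vapply(parts[ok], `[[`, "", 5)
    evid <- vapply(parts[ok], `[[`, "", 7)
    aspect <- vapply(parts[ok], `[[`, "", 9)
  } else {
    ok <- nf == 4
    first <- if (any(ok)) parts[ok][[1]] else NULL
    gene <- vapply(parts[ok], `[[`, "", 1)
    term <- vapply(parts[ok], `[[`, "", 2)
    aspect <- vapply(parts[ok], `[[`, "", 3)
    evid <- vapply(parts[ok], `[[`, "", 4)
    if (!is.null(first) && identical(tolower(first[1]), "gene_id")) {
      gene <- gene[-1]; term <- term[-1]; aspect <- aspect[-1]; evid <- evid[-1]
    }
  }
  n_skipped <- sum(!ok)
  if (n_skipped) warning(n_skipped, " malformed annotation row(s) skipped")
  keep <- aspect %in% c("P", "BP") &
    (is.null(evidence_whitelist) | evid %in% evidence_whitelist) &
    !term %in% root_exclusion
  ann <- unique(data.frame(gene_id = gene[keep], term_id = term[keep],
                           stringsAsFactors = FALSE))
  rownames(ann) <- NULL
  attr(ann, "root_exclusion") <- root_exclusion
  class(ann) <- c("GOAnnotationSet", "data.frame")
  ann
}

#' Build a GOAnnotationSet from a data frame in code
#'
#' @param df Data frame with columns `gene_id`, `term_id` (already
#'   BP-filtered).
#' @param root_exclusion Term ids to drop.
#' @return A `GOAnnotationSet`.
#' @export
annotation_set <- function(df, root_exclusion = go_root_exclusion()) {
  stopifnot(all(c("gene_id", "term_id") %in% names(df)))
  ann <- unique(data.frame(gene_id = as.character(df$gene_id),
                           term_id = as.character(df$term_id),
                           stringsAsFactors = FALSE))
  ann <- ann[!ann$term_id %in% root_exclusion, , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "root_exclusion") <- root_exclusion
  class(ann) <- c("GOAnnotationSet", "data.frame")
  ann
}

#' GO enrichment of a target set
#'
#' Tests every term annotating at least one target (the conventional
#' candidate-term family) with the upper-tail hypergeometric test
#' against the universe, adjusts with BH across the tested terms, and
#' returns records passing the cutoff.
#'
#' @param target_set Character vector of gene ids (subset of
#'   `universe`).
#' @param annotations A `GOAnnotationSet`.
#' @param universe Character vector of the gene universe.
#' @param q_cutoff BH-adjusted cutoff (default 0.05); use 1 to see every
#'   tested term.
#' @return Data frame of `EnrichmentRecord`s: `term_id`, `k` (annotated
#'   targets), `n` (targets in universe), `K` (annotated universe
#'   genes), `N` (universe size), `p`, `q`.
#' @export
enrich_targets <- function(target_set, annotations, universe, q_cutoff = 0.05) {
  universe <- unique(universe)
  target_set <- intersect(unique(target_set), universe)
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  if (!nrow(ann) && length(target_set) == 0)
    stop("no annotated gene intersects the universe")
  empty <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (!length(target_set)) return(empty)
  cand_terms <- unique(ann$term_id[ann$gene_id %in% target_set])
  if (!length(cand_terms)) return(empty)
  by_term <- split(ann$gene_id, ann$term_id)
  N <- length(universe)
  n <- length(target_set)
  rows <- lapply(cand_terms, function(tm) {
    genes <- unique(by_term[[tm]])
    k <- length(intersect(genes, target_set))
    data.frame(term_id = tm, k = k, n = n, K = length(genes), N = N,
               p = stats::phyper(k - 1, length(genes), N - length(genes), n,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  out <- tab[tab$q < q_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer TF functions from predicted-target GO enrichment
#'
#' Runs [enrich_targets()] on every TF's predicted target set; a TF is
#' inferred to participate in each biological process enriched among its
#' targets. TFs with zero predicted targets are omitted.
#'
#' @param edges A thresholded `EdgeList`.
#' @param annotations A `GOAnnotationSet`.
#' @param universe Gene universe for the hypergeometric test.
#' @param q_cutoff BH cutoff (default 0.05).
#' @return Named list mapping tf_id to a character vector of enriched
#'   term ids (possibly empty).
#' @export
infer_tf_functions <- function(edges, annotations, universe, q_cutoff = 0.05) {
  sets <- .target_sets(edges)
  out <- lapply(sets, function(tg)
    enrich_targets(tg, annotations, universe, q_cutoff)$term_id)
  out[order(names(out))]
}

#' Recovery rate of known TF annotations
#'
#' A TF is recovered for a term when it both carries the annotation and
#' has that term enriched among its predicted targets. Per term, the
#' recovery rate is recovered TFs / TFs annotated with the term; terms
#' annotated to no TF are omitted.
#'
#' @param inferred Named list tf_id -> enriched term ids (from
#'   [infer_tf_functions()]).
#' @param known Named list tf_id -> annotated term ids.
#' @param rate_threshold Threshold used in the global summary fraction
#'   (default 0.5).
#' @return A list with `per_term` (term_id, n_tfs_with_term,
#'   n_recovered, recovery_rate) and `summary` (mean_rate,
#'   fraction_above_threshold).
#' @export
recovery_report <- function(inferred, known, rate_threshold = 0.5) {
  terms <- unique(unlist(known, use.names = FALSE))
  per_term <- do.call(rbind, lapply(terms, function(tm) {
    with_term <- names(known)[vapply(known, function(x) tm %in% x, logical(1))]
    recovered <- sum(vapply(with_term, function(tf)
      tm %in% inferred[[tf]], logical(1)))
    data.frame(term_id = tm, n_tfs_with_term = length(with_term),
               n_recovered = recovered,
               recovery_rate = recovered / length(with_term),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_term))
    per_term <- data.frame(term_id = character(), n_tfs_with_term = integer(),
                           n_recovered = integer(), recovery_rate = numeric(),
                           stringsAsFactors = FALSE)
  list(per_term = per_term,
       summary = list(
         mean_rate = if (nrow(per_term)) mean(per_term$recovery_rate) else NA_real_,
         fraction_above_threshold = if (nrow(per_term))
           mean(per_term$recovery_rate > rate_threshold) else NA_real_))
}

#' Candidate novel functions per TF
#'
#' Terms enriched among a TF's predicted targets but absent from its
#' known annotations. TFs with no known BP annotation at all are flagged
#' fully novel.
#'
#' @param inferred Named list tf_id -> enriched term ids.
#' @param known Named list tf_id -> annotated term ids.
#' @return Data frame with columns `tf_id`, `term_id`, `fully_novel`.
#' @export
novel_function_report <- function(inferred, known) {
  rows <- lapply(names(inferred), function(tf) {
    nov <- setdiff(inferred[[tf]], known[[tf]])
    if (!length(nov)) return(NULL)
    data.frame(tf_id = tf, term_id = nov,
               fully_novel = is.null(known[[tf]]) || length(known[[tf]]) == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf_id = character(), term_id = character(),
                      fully_novel = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
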