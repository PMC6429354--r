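# Over-representation layer: gene-level aggregation, set intersections,
# hypergeometric upper-tail test and BH correction.

#' Genes with at least one switch event
#'
#' Several isoform pairs of one gene can switch, so the number of events
#' generally exceeds the number of genes.
#'
#' @param events Switch-event `data.frame`.
#' @return Character vector of unique gene ids.
#' @export
genes_with_switches <- function(events) {
  unique(as.character(events$gene_id))
}

#' Venn partition of named gene sets
#'
#' Every non-empty inclusion region of the Venn diagram is reported with
#' its member list; region counts sum to the union size.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return `data.frame` with columns `region` (set names joined by `&`),
#'   `n` and list-column `members`.
#' @export
intersect_gene_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- split(universe, key)
  data.frame(
    region = names(regions),
    n = lengths(regions),
    members = I(unname(regions)),
    row.names = NULL
  )
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated.
#' Computed by exact summation of the point masses.
#'
#' @param k Observed overlap.
#' @param K Annotated-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return Scalar in `[0, 1]`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n) <= N)")
  }
  min(1, sum(stats::dhyper(k:min(K, n), K, N - K, n)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Over-representation analysis of a gene set against a GMT collection
#'
#' One hypergeometric upper-tail test per collection set with overlap of
#' at least `min_overlap` (sets below that are excluded from the BH
#' denominator), BH correction across the tested sets, then retention of
#' results with `p <= p_max` and `p_adj <= q_max`, sorted by adjusted then
#' raw p-value, truncated to the `top` best. For disease-ontology-style
#' collections use `q_max = 0.5`; the defaults reproduce the pathway
#' settings (p 0.05, q 0.2, top 10).
#'
#' @param query Character vector of gene ids; members outside the universe
#'   are dropped with a message.
#' @param collection A collection from [read_gmt()].
#' @param universe Background gene ids; defaults to the union of all
#'   collection members.
#' @param p_max,q_max Raw and adjusted p-value cutoffs.
#' @param top Maximum number of results returned.
#' @param min_overlap Minimum query/set overlap for a set to be tested.
#' @param method Multiple-testing method, see [bh_adjust()].
#' @return `data.frame` with columns `set_id`, `description`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`; the full tested table (before cutoffs) is
#'   attached as attribute `tested`.
#' @export
run_ora <- function(query, collection, universe = NULL, p_max = 0.05,
                    q_max = 0.2, top = 10, min_overlap = 1,
                    method = "BH") {
  if (is.null(universe)) universe <- unique(unlist(collection$sets))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    k <- length(intersect(query, members))
    if (k < min_overlap) return(NULL)
    data.frame(set_id = id,
               description = if (id %in% names(collection$descriptions))
                 collection$descriptions[[id]] else "",
               k = k, K = length(members), n = n, N = N,
               p = hypergeom_upper(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  empty <- data.frame(set_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0))
  if (!length(rows)) {
    attr(empty, "tested") <- empty
    return(empty)
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p, method = method)
  tested <- tab[order(tab$p_adj, tab$p), , drop = FALSE]
  keep <- tested[tested$p <= p_max & tested$p_adj <= q_max, , drop = FALSE]
  out <- utils::head(keep, top)
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

#' Write an ORA result table as TSV
#'
#' @param result Table from [run_ora()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ora <- function(result, path) {
  utils::write.table(
    result[, c("set_id", "k", "K", "n", "N", "p", "p_adj")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
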