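# Neighbor-gene discovery around lncRNA loci and hypergeometric
# over-representation testing of the neighbor sets against a user-supplied
# term-to-gene mapping.

#' Find protein-coding neighbors of lncRNA loci
#'
#' Emits a pair for every (lncRNA, gene) whose gene-body intervals are
#' within `window` bp of each other on the same chromosome, strand-agnostic.
#' The distance is the minimal end-to-start gap in half-open coordinates;
#' overlapping or abutting bodies have distance 0. A gap of exactly
#' `window` is included.
#'
#' @param lncrnas,genes [transcript_table()] objects (query and subject;
#'   the pair set is symmetric in the two roles).
#' @param window maximum gap in bp (default 10,000).
#' @return data.frame with `lncrna_id`, `gene_id`, `distance_bp`, sorted by
#'   lncRNA then gene id.
#' @export
find_neighbors <- function(lncrnas, genes, window = 10000) {
  if (window < 0) stop("window must be non-negative")
  out <- list()
  for (chr in intersect(unique(lncrnas$chrom), unique(genes$chrom))) {
    li <- which(lncrnas$chrom == chr)
    gi <- which(genes$chrom == chr)
    idx <- expand.grid(l = li, g = gi)
    gap <- interval_gap(lncrnas$start[idx$l], lncrnas$end[idx$l],
                        genes$start[idx$g], genes$end[idx$g])
    keep <- gap <= window
    if (any(keep))
      out[[chr]] <- data.frame(
        lncrna_id = lncrnas$transcript_id[idx$l[keep]],
        gene_id = genes$gene_id[idx$g[keep]],
        distance_bp = as.integer(gap[keep]),
        stringsAsFactors = FALSE
      )
  }
  if (length(out) == 0L)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hypergeometric term over-representation test
#'
#' For each term with `K` genes in a universe of `N`, a selection of `n`
#' genes containing `k` term genes is scored by the upper-tail
#' hypergeometric probability `P(X >= k)` and the enrichment ratio
#' `(k/n)/(K/N)`. A term is significant when `p < p_max` and enrichment is
#' at least `min_enrichment`; no multiple-testing correction is applied
#' (the enrichment floor plays that conservative role).
#'
#' @param selected character vector of selected gene ids (must lie in the
#'   mapping's universe).
#' @param mapping a [term_mapping()].
#' @param p_max raw p-value cutoff (default 0.01).
#' @param min_enrichment enrichment-ratio floor (default 2).
#' @return list with `significant` (filtered rows) and `table` (all terms,
#'   columns `term_id`, `k`, `n`, `K`, `N`, `enrichment`, `p`).
#' @export
enrich <- function(selected, mapping, p_max = 0.01, min_enrichment = 2.0) {
  stopifnot(inherits(mapping, "TermMapping"))
  selected <- unique(as.character(selected))
  stray <- setdiff(selected, mapping$universe)
  if (length(stray))
    stop("selected gene outside universe: ", paste(stray, collapse = ", "))
  N <- length(mapping$universe)
  n <- length(selected)
  tab <- do.call(rbind, lapply(names(mapping$terms), function(term) {
    gs <- mapping$terms[[term]]
    K <- length(gs)
    k <- length(intersect(selected, gs))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, n = n, K = K, N = N,
               enrichment = if (n > 0) (k / n) / (K / N) else 0,
               p = p, stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), enrichment = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  sig <- tab[tab$p < p_max & tab$enrichment >= min_enrichment, ,
             drop = FALSE]
  rownames(tab) <- rownames(sig) <- NULL
  list(significant = sig, table = tab)
}
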