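#' Random protein-interaction testbed with planted compartment profiles
#'
#' Draws a simple undirected random graph over synthetic gene symbols,
#' assigns each gene a random set of compartment annotations, and records
#' for every gene the brute-force compartment profile of its direct
#' interactors. The planted profiles are by construction recomputable from
#' the edge list and annotations, which is exactly what the enrichment
#' module is tested against.
#'
#' @param n_genes number of genes.
#' @param n_edges number of undirected edges; at most `choose(n_genes, 2)`.
#' @param compartments compartment labels to annotate with.
#' @param seed integer seed.
#' @param annotation_prob probability that a gene carries each compartment
#'   label (independent per label; sets may overlap).
#' @return class `ppi_testbed`: list with `genes`, `edges` (two-column
#'   data.frame `a`, `b`), `annotations` (named list of gene sets) and
#'   `planted_profiles` (data.frame: `gene`, `n_interactors`, one percentage
#'   column per compartment, `NA` for degree-zero genes).
#' @export
generate_ppi_testbed <- function(n_genes, n_edges,
                                 compartments = c("mitochondrion",
                                                  "autophagosome",
                                                  "endolysosome"),
                                 seed = 1L, annotation_prob = 0.25) {
  max_edges <- n_genes * (n_genes - 1) / 2
  if (n_edges > max_edges)
    stop("infeasible edge count: ", n_edges, " > ", max_edges)
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    if (n_edges > 0 && max_edges <= 2e6) {
      # small pair space: enumerate and sample without replacement
      ut <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
      pick <- ut[sample.int(nrow(ut), n_edges), , drop = FALSE]
      edges <- data.frame(a = genes[pick[, 1]], b = genes[pick[, 2]],
                          stringsAsFactors = FALSE)
    } else if (n_edges > 0) {
      # draw distinct unordered pairs by rejection on a pair key
      seen <- new.env(hash = TRUE)
      i <- integer(n_edges); j <- integer(n_edges)
      got <- 0L
      while (got < n_edges) {
        ii <- sample.int(n_genes, 1L); jj <- sample.int(n_genes, 1L)
        if (ii == jj) next
        if (ii > jj) { tmp <- ii; ii <- jj; jj <- tmp }
        key <- sprintf("%d_%d", ii, jj)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        got <- got + 1L
        i[got] <- ii; j[got] <- jj
      }
      edges <- data.frame(a = genes[i], b = genes[j],
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(a = character(0), b = character(0))
    }
    annotations <- lapply(stats::setNames(compartments, compartments),
                          function(cp)
                            genes[stats::runif(n_genes) < annotation_prob])
    profiles <- brute_force_profiles(genes, edges, annotations)
    structure(list(genes = genes, edges = edges, annotations = annotations,
                   planted_profiles = profiles),
              class = "ppi_testbed")
  })
}

# direct-neighbour compartment percentages by plain counting
brute_force_profiles <- function(genes, edges, annotations) {
  nbrs <- function(g) unique(c(edges$b[edges$a == g], edges$a[edges$b == g]))
  out <- data.frame(gene = genes, n_interactors = 0L)
  for (cp in names(annotations)) out[[cp]] <- NA_real_
  for (k in seq_along(genes)) {
    nb <- nbrs(genes[k])
    out$n_interactors[k] <- length(nb)
    if (length(nb) > 0)
      for (cp in names(annotations))
        out[[cp]][k] <- 100 * sum(nb %in% annotations[[cp]]) / length(nb)
  }
  out
}
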