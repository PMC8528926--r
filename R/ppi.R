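#' Parse a MITAB-style interaction table into a simple graph
#'
#' Reads PSI-MI tab-separated interaction records (the BioGRID organism
#' dialect: identifier, alternative-identifier and alias columns carrying
#' `entrez gene/locuslink:SYMBOL` entries), extracts one uppercase gene
#' symbol per interactor (first parsable alias wins), and builds a simple
#' undirected graph: self-loops dropped, duplicate pairs merged regardless
#' of column order. Malformed rows are skipped and counted.
#'
#' @param path a MITAB TSV file, or a data.frame already read (first two or
#'   more tab columns).
#' @return object of class `interaction_graph`: list with `graph`
#'   (an igraph), `n_self_loops`, `n_duplicates`, `n_malformed`.
#' @export
parse_interactions <- function(path) {
  if (is.character(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0)
      return(new_interaction_graph(character(0), character(0), 0L, 0L, 0L))
    fields <- strsplit(lines, "\t", fixed = TRUE)
  } else {
    df <- as.data.frame(path)
    fields <- lapply(seq_len(nrow(df)), function(i)
      as.character(unlist(df[i, ])))
  }
  a <- character(0); b <- character(0); bad <- 0L
  for (f in fields) {
    if (length(f) < 2) { bad <- bad + 1L; next }
    ga <- mitab_symbol(f, c(1, 3, 5))
    gb <- mitab_symbol(f, c(2, 4, 6))
    if (is.na(ga) || is.na(gb)) { bad <- bad + 1L; next }
    a <- c(a, ga); b <- c(b, gb)
  }
  if (bad > 0)
    warning(bad, " malformed interaction row(s) skipped")
  self <- a == b
  a2 <- a[!self]; b2 <- b[!self]
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  new_interaction_graph(lo[!dup], hi[!dup], sum(self), sum(dup), bad)
}

new_interaction_graph <- function(a, b, n_self, n_dup, n_bad) {
  g <- igraph::graph_from_data_frame(data.frame(a = a, b = b),
                                     directed = FALSE)
  structure(list(graph = g, n_self_loops = n_self, n_duplicates = n_dup,
                 n_malformed = n_bad),
            class = "interaction_graph")
}

# extract a gene symbol from the identifier columns of one interactor:
# prefer 'entrez gene/locuslink:SYMBOL' in id/altid/alias fields, fall back
# to the bare identifier with its namespace stripped
mitab_symbol <- function(fields, cols) {
  for (cl in cols) {
    if (cl > length(fields)) next
    entries <- strsplit(fields[cl], "|", fixed = TRUE)[[1]]
    for (e in entries) {
      m <- regmatches(e, regexec("locuslink:([A-Za-z0-9_.-]+)", e))[[1]]
      if (length(m) == 2) return(toupper(m[2]))
    }
  }
  e <- fields[cols[1]]
  if (is.na(e) || e == "" || e == "-") return(NA_character_)
  sym <- sub("^[^:]*:", "", strsplit(e, "|", fixed = TRUE)[[1]][1])
  sym <- sub("\\(.*$", "", sym)
  if (nzchar(sym)) toupper(sym) else NA_character_
}

#' Serialize an interaction graph as an edge-list TSV
#'
#' @param ig an `interaction_graph`.
#' @param path output file; two tab-separated symbol columns, one edge per
#'   line. Re-parsing the file reproduces the graph.
#' @export
write_interactions <- function(ig, path) {
  el <- igraph::as_edgelist(ig$graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a compartment annotation table
#'
#' @param path TSV with two columns: compartment label, gene symbol.
#' @return named list: compartment -> character vector of uppercase genes.
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("compartment", "gene"),
                         stringsAsFactors = FALSE)
  lapply(split(toupper(d$gene), d$compartment), unique)
}

#' Compartment profile of a candidate's direct interactors
#'
#' For each compartment, the percentage of the candidate's first-shell
#' interaction partners annotated to it — the descriptive profile used to
#' prioritise screen candidates by where their interactors live.
#'
#' @param ig an `interaction_graph` (or igraph).
#' @param candidate gene symbol.
#' @param annotation named list: compartment -> gene set.
#' @return list of class `enrichment_profile`: `candidate`, `present`,
#'   `n_interactors`, `pct_per_compartment` (named; `NA` when degree 0).
#' @export
interactor_profile <- function(ig, candidate, annotation) {
  g <- if (inherits(ig, "interaction_graph")) ig$graph else ig
  candidate <- toupper(candidate)
  comp_names <- names(annotation)
  if (!(candidate %in% igraph::V(g)$name)) {
    return(structure(list(candidate = candidate, present = FALSE,
                          n_interactors = 0L,
                          pct_per_compartment =
                            stats::setNames(rep(NA_real_,
                                                length(comp_names)),
                                            comp_names)),
                     class = "enrichment_profile"))
  }
  nb <- igraph::neighbors(g, candidate)$name
  pct <- if (length(nb) == 0) {
    stats::setNames(rep(NA_real_, length(comp_names)), comp_names)
  } else {
    vapply(annotation, function(set)
      100 * sum(nb %in% toupper(set)) / length(nb), numeric(1))
  }
  structure(list(candidate = candidate, present = TRUE,
                 n_interactors = length(nb), pct_per_compartment = pct),
            class = "enrichment_profile")
}

#' Screen-wide baseline compartment percentages
#'
#' Unweighted mean of the per-gene compartment percentages over all
#' screened genes with at least one interactor — the dashed-line reference
#' a candidate's profile is compared against.
#'
#' @param ig an `interaction_graph` (or igraph).
#' @param screened_genes character vector of screened gene symbols.
#' @param annotation named list: compartment -> gene set.
#' @return named numeric vector of baseline percentages; attribute
#'   `n_genes_used`.
#' @export
screen_baseline <- function(ig, screened_genes, annotation) {
  profs <- lapply(screened_genes, function(g)
    interactor_profile(ig, g, annotation))
  use <- vapply(profs, function(p)
    p$present && p$n_interactors > 0, logical(1))
  if (!any(use))
    stop("no screened gene has interactors: baseline undefined")
  mat <- do.call(rbind, lapply(profs[use], `[[`, "pct_per_compartment"))
  structure(colMeans(mat), n_genes_used = sum(use))
}

#' @export
print.enrichment_profile <- function(x, ...) {
  if (!x$present) {
    cat(x$candidate, ": absent from the interaction graph\n")
    return(invisible(x))
  }
  cat(x$candidate, " (", x$n_interactors, " interactors)\n", sep = "")
  print(round(x$pct_per_compartment, 1))
  invisible(x)
}
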