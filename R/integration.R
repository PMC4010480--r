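#' Read a cross-cancer altered-mRNA table
#'
#' Parses the wide tab-separated layout used for the common-mRNA catalogues
#' shipped in `inst/extdata`: one row per gene with `gene_symbol`, `location`
#' (cytoband), `pcsr` (`yes`/`no`), one `<Cancer>_M` (microarray) and one
#' `<Cancer>_D` (digital differential display) mark column per cancer holding
#' `up`, `down`, `both` or empty, and `class`.
#'
#' @param file Path to the table.
#' @return List with `genes` (`data.frame`: `gene_symbol`, `location`, `pcsr`
#'   logical, `class`) and `calls` (long `data.frame`: `gene`, `cancer`,
#'   `direction`, `source`).
#' @export
read_common_rna_table <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = NULL)
  markcols <- grep("_(M|D)$", names(tab), value = TRUE)
  if (!length(markcols)) stop("no <Cancer>_M / <Cancer>_D mark columns found")
  calls <- marks_to_calls(tab, id_col = "gene_symbol", markcols = markcols)
  genes <- data.frame(gene_symbol = tab$gene_symbol, location = tab$location,
                      pcsr = tab$pcsr == "yes", class = tab$class,
                      stringsAsFactors = FALSE)
  list(genes = genes, calls = calls)
}

#' Read a cross-cancer altered-miRNA table
#'
#' Same idea as [read_common_rna_table()] for the miRNA catalogue: one mark
#' column per cancer (no microarray/DDD split; marks are recorded as
#' microarray evidence), plus `location` and `pcsr`.
#'
#' @param file Path to the table.
#' @return List with `mirnas` (`data.frame`: `mirna`, `location`, `pcsr`) and
#'   `calls` (long `data.frame`).
#' @export
read_mirna_table <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = NULL)
  markcols <- setdiff(names(tab), c("mirna", "location", "pcsr"))
  calls <- marks_to_calls(tab, id_col = "mirna", markcols = markcols)
  mirnas <- data.frame(mirna = tab$mirna, location = tab$location,
                       pcsr = tab$pcsr == "yes", stringsAsFactors = FALSE)
  list(mirnas = mirnas, calls = calls)
}

marks_to_calls <- function(tab, id_col, markcols) {
  rows <- list()
  for (mc in markcols) {
    cancer <- sub("_(M|D)$", "", mc)
    source <- if (grepl("_D$", mc)) "DDD"
              else if (grepl("_M$", mc)) "microarray" else "microarray"
    v <- tab[[mc]]
    for (dir in c("over", "down")) {
      mk <- if (dir == "over") c("up", "both") else c("down", "both")
      hit <- which(v %in% mk)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = tab[[id_col]][hit], cancer = cancer, direction = dir,
          source = source, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$gene, tab[[id_col]]), out$cancer, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes altered in at least `min_cancers` distinct cancers
#'
#' A gene counts as altered in a cancer when it has at least one call of any
#' direction from any evidence source (microarray or DDD) in that cancer.
#'
#' @param calls Long call `data.frame` with columns `gene`, `cancer`,
#'   `direction` (and optionally `source`).
#' @param min_cancers Commonality threshold (default 6).
#' @param n_cancers Size of the cancer panel (>= `min_cancers`); recorded for
#'   bookkeeping only.
#' @return `data.frame` with `gene` and `n_cancers_altered` for genes at or
#'   above the threshold, in decreasing count order.
#' @export
collect_common <- function(calls, min_cancers = 6, n_cancers = 11) {
  stopifnot(min_cancers <= n_cancers,
            all(c("gene", "cancer", "direction") %in% names(calls)))
  n <- tapply(calls$cancer, calls$gene, function(x) length(unique(x)))
  out <- data.frame(gene = names(n), n_cancers_altered = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cancers_altered >= min_cancers, , drop = FALSE]
  out <- out[order(-out$n_cancers_altered, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a cross-cancer expression class
#'
#' Classifies one gene's per-cancer calls: Class `I` when every altered cancer
#' shows only over-expression, Class `II` when every altered cancer shows only
#' down-expression, Class `III` otherwise (mixed directions across cancers, or
#' conflicting directions within one cancer). "Majority" is thus
#' operationalized as purity: a single opposing call already demotes a gene to
#' Class III.
#'
#' @param record `data.frame` of calls for one gene, columns `cancer` and
#'   `direction`.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
assign_class <- function(record) {
  stopifnot(nrow(record) >= 1,
            all(c("cancer", "direction") %in% names(record)))
  per <- split(record$direction, record$cancer)
  u <- sum(vapply(per, function(d) all(d == "over"), logical(1)))
  d <- sum(vapply(per, function(d) all(d == "down"), logical(1)))
  m <- length(per) - u - d
  if (d == 0 && m == 0) "I" else if (u == 0 && m == 0) "II" else "III"
}

#' Assign expression classes for every gene in a call table
#'
#' @param calls Long call `data.frame` (`gene`, `cancer`, `direction`).
#' @return `data.frame` with `gene` and `class`, in first-appearance order.
#' @export
assign_classes <- function(calls) {
  genes <- unique(calls$gene)
  cls <- vapply(genes, function(g)
    assign_class(calls[calls$gene == g, , drop = FALSE]), character(1))
  data.frame(gene = genes, class = unname(cls), stringsAsFactors = FALSE)
}

#' Count cancers altered in a given direction
#'
#' Number of distinct cancers in which the record has at least one call of the
#' requested direction, from either evidence source.
#'
#' @param record `data.frame` of calls for one gene (`cancer`, `direction`).
#' @param direction `"over"` or `"down"`.
#' @return Integer count.
#' @export
count_direction <- function(record, direction = c("over", "down")) {
  direction <- match.arg(direction)
  if (nrow(record) == 0L) return(0L)
  length(unique(record$cancer[record$direction == direction]))
}

#' Flag records located on predicted risk regions
#'
#' Sets `on_pcsr` to `TRUE` for records whose cytoband appears in the PCSR
#' set (either direction list). Band labels not present in the set — including
#' malformed ones — simply yield `FALSE`.
#'
#' @param records `data.frame` with a `location` (band label) column.
#' @param pcsrs Either a character vector of risk-band labels or the
#'   `data.frame` returned by [select_pcsrs()] (its `band` column is used).
#' @return `records` with an `on_pcsr` logical column.
#' @export
flag_pcsr <- function(records, pcsrs) {
  stopifnot("location" %in% names(records))
  bands <- if (is.data.frame(pcsrs)) unique(pcsrs$band) else unique(as.character(pcsrs))
  records$on_pcsr <- records$location %in% bands
  records
}

#' Detect same-band miRNA clusters
#'
#' Groups miRNAs by cytoband and reports every band carrying at least two
#' distinct miRNAs — the genomic clusters whose co-expression hints at shared
#' regulation or a shared causal variant. Clusters are sorted by chromosome
#' (numeric, then X, Y) and band label.
#'
#' @param records `data.frame` with `mirna` and `location` (band) columns.
#' @return `data.frame` with `band`, `n_members`, `members` (comma-separated,
#'   in input order); attribute `member_list` holds the same as a named list.
#' @export
detect_mirna_clusters <- function(records) {
  stopifnot(all(c("mirna", "location") %in% names(records)))
  by_band <- lapply(split(records$mirna, records$location), unique)
  by_band <- by_band[vapply(by_band, length, 1L) >= 2L]
  if (!length(by_band)) {
    out <- data.frame(band = character(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
    attr(out, "member_list") <- list()
    return(out)
  }
  chr <- sub("^([0-9]+|X|Y).*$", "\\1", names(by_band))
  o <- order(chromosome_order(chr), names(by_band))
  by_band <- by_band[o]
  out <- data.frame(band = names(by_band),
                    n_members = vapply(by_band, length, 1L),
                    members = vapply(by_band, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "member_list") <- by_band
  out
}

#' Summarize the neighbourhood of a node in an interaction network
#'
#' Takes the induced subgraph of all nodes within `radius` hops of `focus`
#' (hops follow edges in either direction) and reports its size. Edges are
#' counted when both endpoints lie in the neighbourhood.
#'
#' @param edges `data.frame` with columns `source`, `target` and optionally
#'   `effect` (e.g. `positive`, `negative`, `regulation`, `miRNA_effect`).
#' @param focus Node label at the centre.
#' @param radius Hop count (default 1); 0 returns just the focus node.
#' @return List with `n_nodes`, `n_edges`, `members` (sorted labels). A focus
#'   absent from the edge table yields an empty result with a warning.
#' @export
network_summary <- function(edges, focus, radius = 1) {
  stopifnot(all(c("source", "target") %in% names(edges)), radius >= 0)
  if (any(edges$source == edges$target)) stop("self-loop edges not allowed")
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE)
  if (!focus %in% igraph::V(g)$name) {
    warning("focus node '", focus, "' absent from the edge table")
    return(list(n_nodes = 0L, n_edges = 0L, members = character(0)))
  }
  nb <- igraph::ego(g, order = radius, nodes = focus, mode = "all")[[1]]
  sub <- igraph::induced_subgraph(g, nb)
  list(n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub),
       members = sort(igraph::V(sub)$name))
}
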