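#' Build an association network from per-pair test results
#'
#' An edge is drawn between two proteins when the association p-value is
#' strictly below the primary threshold in the primary cell line and — when
#' a secondary cell line was measured — strictly below the secondary
#' threshold there as well.
#'
#' @param records data.frame with columns `protein_a`, `protein_b`,
#'   `p_primary`, optionally `p_secondary`, and optionally `ka_median`,
#'   `ka_mad`, `score_median` (carried onto edges).
#' @param p_primary strict p-value threshold for the primary cell line.
#' @param p_secondary strict threshold for the secondary line (applied only
#'   to records with a non-missing `p_secondary`... see Details).
#' @details If the `p_secondary` column is absent or entirely `NA`,
#'   filtering uses the primary line only.  Duplicate (unordered) pairs are
#'   rejected.
#' @return object of class `association_network` with `nodes` (sorted,
#'   union of all record endpoints), `edges` (data.frame of passing pairs,
#'   endpoints sorted within and across rows) and the thresholds used.
#' @export
build_network <- function(records, p_primary = 1e-4, p_secondary = 0.02) {
  stopifnot(is.data.frame(records),
            all(c("protein_a", "protein_b", "p_primary") %in% names(records)))
  if (any(records$protein_a == records$protein_b))
    stop("self-pairs are not allowed")
  ab <- sort_pair_columns(records)
  key <- paste(ab[, 1], ab[, 2], sep = "|")
  if (anyDuplicated(key))
    stop("duplicate pair record(s): ", key[duplicated(key)][1])
  records$protein_a <- ab[, 1]; records$protein_b <- ab[, 2]
  has_secondary <- "p_secondary" %in% names(records) &&
    any(!is.na(records$p_secondary))
  keep <- records$p_primary < p_primary
  if (has_secondary)
    keep <- keep & !is.na(records$p_secondary) &
      records$p_secondary < p_secondary
  edges <- records[keep, , drop = FALSE]
  edges <- edges[order_c(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort_c(unique(c(records$protein_a, records$protein_b)))
  structure(list(nodes = nodes, edges = edges,
                 p_primary = p_primary,
                 p_secondary = if (has_secondary) p_secondary else NA_real_),
            class = "association_network")
}

#' Association network directly from a node/edge fixture
#'
#' @param nodes character vector of protein names.
#' @param edges data.frame with `protein_a`, `protein_b`.
#' @return an `association_network` (no p-values attached).
#' @export
as_association_network <- function(nodes, edges) {
  stopifnot(all(edges$protein_a %in% nodes), all(edges$protein_b %in% nodes),
            all(edges$protein_a != edges$protein_b))
  ab <- sort_pair_columns(edges)
  edges <- data.frame(protein_a = ab[, 1], protein_b = ab[, 2],
                      stringsAsFactors = FALSE)
  edges <- edges[order_c(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort_c(nodes), edges = edges,
                 p_primary = NA_real_, p_secondary = NA_real_),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d proteins, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# per-row C-locale-sorted (protein_a, protein_b) matrix; robust to 0 rows
sort_pair_columns <- function(df) {
  a <- as.character(df$protein_a); b <- as.character(df$protein_b)
  if (!length(a)) return(cbind(a, b))
  swap <- vapply(seq_along(a), function(i)
    sort_c(c(a[i], b[i]))[1] != a[i], logical(1))
  cbind(ifelse(swap, b, a), ifelse(swap, a, b))
}

net_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE, vertices = net$nodes)
}

#' Enumerate candidate ternary (and larger) complexes
#'
#' A fully intra-connected sub-graph — a clique — of pairwise physical
#' associations is the signature of a potential multi-protein complex.
#' Returns all maximal cliques with at least `min_size` members.
#'
#' @param net an `association_network`.
#' @param min_size smallest clique size reported (default 3).
#' @return list of character vectors, each sorted, list ordered
#'   lexicographically; empty list when none.
#' @export
find_ternary_complexes <- function(net, min_size = 3L) {
  stopifnot(inherits(net, "association_network"))
  if (!nrow(net$edges)) return(list())
  g <- net_igraph(net)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort_c(names(v)))
  cl[order_c(vapply(cl, paste, character(1), collapse = "|"))]
}

#' Infer mutually exclusive interactions
#'
#' Reports, for every hub protein, each maximal set of two or more of its
#' interaction partners that are pairwise *not* associated with each other:
#' if several proteins bind the hub but never each other, their
#' interactions with the hub are mutually exclusive (e.g. they compete for
#' a shared binding site) and no higher-order complex containing the hub
#' and two of them can form.
#'
#' @param net an `association_network`.
#' @return list of records, each `list(hub = <name>, partners = <sorted
#'   character vector>)`, deterministically ordered by hub then partners;
#'   empty when the network has no such configuration.
#' @export
infer_mutual_exclusivity <- function(net) {
  stopifnot(inherits(net, "association_network"))
  if (!nrow(net$edges)) return(list())
  g <- net_igraph(net)
  out <- list()
  for (h in sort_c(net$nodes)) {
    nb <- names(igraph::neighbors(g, h))
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(g, nb)
    mis <- igraph::max_ivs(sub)
    mis <- Filter(function(v) length(v) >= 2, mis)
    for (v in mis)
      out[[length(out) + 1L]] <- list(hub = h, partners = sort_c(names(v)))
  }
  if (!length(out)) return(list())
  ord <- order_c(vapply(out, function(r)
    paste(r$hub, paste(r$partners, collapse = "|")), character(1)))
  out[ord]
}

#' Co-dynamics distance matrix
#'
#' Proteins sharing one type of building block should exchange at adhesion
#' sites with the same kinetics.  The per-protein median FRAP half-time and
#' mobile fraction are z-scored across proteins (sample sd, n - 1) and the
#' pairwise Euclidean distance in that plane is the co-dynamics distance.
#'
#' @param profile data.frame from [dynamics_profile()] with columns
#'   `protein`, `median_half_time`, `median_mobile_fraction` (>= 3 rows).
#' @return symmetric distance matrix with protein dimnames.
#' @export
co_dynamics_distance <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("protein", "median_half_time", "median_mobile_fraction")
                %in% names(profile)))
  if (nrow(profile) < 3) stop("need >= 3 proteins")
  m <- cbind(profile$median_half_time, profile$median_mobile_fraction)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("zero variance in a coordinate; z-score undefined")
  z <- scale(m)  # center, then divide by sample sd (n - 1)
  d <- as.matrix(stats::dist(z))
  dimnames(d) <- list(profile$protein, profile$protein)
  d
}

#' Export an association network
#'
#' Writes the edge list as TSV (with any p-value / Ka columns present) and,
#' optionally, the graph as GraphML.
#'
#' @param net an `association_network`.
#' @param tsv_path edge-list TSV destination.
#' @param graphml_path optional GraphML destination.
#' @return `tsv_path`, invisibly.
#' @export
write_network <- function(net, tsv_path, graphml_path = NULL) {
  stopifnot(inherits(net, "association_network"))
  utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(net_igraph(net), graphml_path, format = "graphml")
  invisible(tsv_path)
}
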