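# internal: canonical unordered pair keys for an edge data frame
pair_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

edges_of <- function(net) {
  if (inherits(net, "clr_network")) net$edges
  else if (is.data.frame(net)) net
  else stop("expected a clr_network or an edge data frame")
}

#' Intersect two inferred networks into conserved subnetworks
#'
#' The conserved edge set is the unordered-pair intersection of the two
#' networks' edges; its connected components are the conserved subnetworks.
#' When per-gene regulation directions are supplied for both systems, each
#' component is annotated with whether every member gene is regulated in the
#' same direction in both systems (the hallmark of a consistently repressed
#' or induced conserved module).
#'
#' @param a,b `clr_network` objects or edge data frames with columns
#'   `gene_a`, `gene_b`.
#' @param directions_a,directions_b optional named character vectors
#'   (`"up"`/`"down"`/`"none"`) giving each gene's regulation direction in
#'   the two systems.
#' @return A list of class `conserved_subnetworks`: `edges` (conserved edge
#'   data frame with scores from both networks where available), and
#'   `components` (list; each has `nodes`, `edges`, and, when directions are
#'   given, `direction_agreement` — TRUE when every member gene is regulated
#'   in the same direction in both systems — plus `module_direction`
#'   (`"up"`/`"down"` for coherently induced/repressed modules, `"mixed"`
#'   otherwise).
#' @export
intersect_networks <- function(a, b, directions_a = NULL, directions_b = NULL) {
  ea <- edges_of(a)
  eb <- edges_of(b)
  ka <- pair_keys(ea$gene_a, ea$gene_b)
  kb <- pair_keys(eb$gene_a, eb$gene_b)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  edges <- data.frame(
    gene_a = pmin(ea$gene_a[ia], ea$gene_b[ia]),
    gene_b = pmax(ea$gene_a[ia], ea$gene_b[ia]),
    stringsAsFactors = FALSE)
  if ("clr_score" %in% names(ea)) edges$score_a <- ea$clr_score[ia]
  if ("clr_score" %in% names(eb)) edges$score_b <- eb$clr_score[ib]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  comps <- connected_components(edges)
  comps <- lapply(comps, function(cp) {
    if (!is.null(directions_a) && !is.null(directions_b)) {
      da <- directions_a[cp$nodes]
      db <- directions_b[cp$nodes]
      # every member regulated the same way in both systems
      cp$direction_agreement <- !anyNA(da) && !anyNA(db) && all(da == db) &&
        all(da %in% c("up", "down"))
      # and is the whole module coherently induced or repressed?
      cp$module_direction <- if (!isTRUE(cp$direction_agreement)) NA_character_
        else if (length(unique(da)) == 1L) unique(da) else "mixed"
    }
    cp
  })
  structure(list(edges = edges, components = comps),
            class = "conserved_subnetworks")
}

#' @export
print.conserved_subnetworks <- function(x, ...) {
  cat(sprintf("conserved_subnetworks: %d edges in %d component(s)\n",
              nrow(x$edges), length(x$components)))
  for (cp in x$components)
    cat(sprintf("  %d nodes / %d edges: %s%s\n", length(cp$nodes),
                nrow(cp$edges), paste(utils::head(cp$nodes, 6L), collapse = ", "),
                if (length(cp$nodes) > 6L) ", ..." else ""))
  invisible(x)
}

#' Connected components of an undirected edge set
#'
#' Components are returned largest first; ties broken by the
#' lexicographically smallest member node.
#'
#' @param edges data frame with columns `gene_a`, `gene_b` (one row per
#'   undirected edge).
#' @return A list of components, each a list with `nodes` (sorted) and
#'   `edges` (the rows of `edges` inside the component). Empty edge set
#'   gives an empty list.
#' @export
connected_components <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[[`, "", 1L))
  lapply(comps[ord], function(nodes) {
    inside <- edges$gene_a %in% nodes & edges$gene_b %in% nodes
    list(nodes = nodes, edges = edges[inside, , drop = FALSE])
  })
}

#' Transcription-factor connectivity table
#'
#' Degree (number of incident edges) of each listed transcription factor in
#' a network; TFs absent from the network are reported with degree 0. The
#' highlight flag marks hubs with strictly more than `min_connections`
#' edges.
#'
#' @param net a `clr_network` or edge data frame.
#' @param tf_ids character vector of transcription-factor gene ids.
#' @param min_connections hub threshold (strict `>`, default 15).
#' @return Data frame `tf`, `degree`, `highlight`, sorted by decreasing
#'   degree then id.
#' @export
tf_degree_table <- function(net, tf_ids, min_connections = 15L) {
  e <- edges_of(net)
  incid <- c(e$gene_a, e$gene_b)
  deg <- vapply(tf_ids, function(tf) sum(incid == tf), 0L)
  out <- data.frame(tf = tf_ids, degree = deg,
                    highlight = deg > min_connections,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag regulators with strongly asymmetric connectivity
#'
#' A TF is flagged when its degree in one network is at least `ratio` times
#' its degree in the other. Any positive degree versus zero counts as
#' flagged; zero versus zero does not.
#'
#' @param degrees_a,degrees_b named integer vectors of per-TF degrees over a
#'   shared TF namespace.
#' @param ratio fold-difference threshold (default 2).
#' @return Data frame `tf`, `degree_a`, `degree_b`, `higher_in`, `flagged`.
#' @export
degree_ratio_flags <- function(degrees_a, degrees_b, ratio = 2.0) {
  tfs <- union(names(degrees_a), names(degrees_b))
  da <- ifelse(tfs %in% names(degrees_a), degrees_a[tfs], 0L)
  db <- ifelse(tfs %in% names(degrees_b), degrees_b[tfs], 0L)
  flagged <- mapply(function(x, y) {
    if (x == 0 && y == 0) return(FALSE)
    if (min(x, y) == 0) return(TRUE)
    max(x, y) >= ratio * min(x, y)
  }, da, db)
  data.frame(tf = tfs, degree_a = as.integer(da), degree_b = as.integer(db),
             higher_in = ifelse(da == db, "equal",
                                ifelse(da > db, "a", "b")),
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Score network recovery against a planted truth
#'
#' Evaluates inferred CLR scores (or a thresholded network) against a known
#' regulator-to-target truth using the standard regulator-restricted
#' protocol of the network-inference assessment literature: only candidate
#' pairs with at least one regulator endpoint are scored. Co-target pairs
#' carry genuine statistical dependence under any common-regulator model, so
#' they are neither true nor false for a directed truth and are excluded.
#'
#' @param scores a `clr_scores` object (for ranking metrics), or a
#'   `clr_network` (for thresholded recall/precision only).
#' @param truth_edges data frame with columns `regulator`, `target`.
#' @param regulators character vector of regulator ids (defaults to the
#'   regulators appearing in `truth_edges`).
#' @param z_cutoff threshold for recall/precision of the thresholded
#'   network; taken from the scores' parameters when omitted.
#' @return A list: `aupr`, `baseline` (truth density among candidate pairs),
#'   `precision_at_k` (k = number of true edges), `recall`, `precision`,
#'   `n_true`, `n_candidates`. Ranking metrics are `NA` when only a
#'   thresholded network is supplied.
#' @export
score_network_recovery <- function(scores, truth_edges, regulators = NULL,
                                   z_cutoff = NULL) {
  if (is.null(regulators)) regulators <- unique(truth_edges$regulator)
  true_keys <- unique(pair_keys(truth_edges$regulator, truth_edges$target))
  if (inherits(scores, "clr_scores")) {
    S <- scores$scores
    ids <- rownames(S)
    if (is.null(z_cutoff)) z_cutoff <- scores$params$z_cutoff
    reg <- ids %in% regulators
    cand <- outer(reg, reg, "|")
    sel <- which(upper.tri(S) & cand, arr.ind = TRUE)
    keys <- pair_keys(ids[sel[, 1L]], ids[sel[, 2L]])
    sc <- S[sel]
    is_true <- keys %in% true_keys
    k <- sum(is_true)
    ord <- order(-sc, keys)                 # deterministic tie-break
    tp <- cumsum(is_true[ord])
    prec <- tp / seq_along(tp)
    rec <- tp / k
    aupr <- sum(diff(c(0, rec)) * prec)
    pass <- sc >= z_cutoff
    list(aupr = aupr, baseline = k / length(sc),
         precision_at_k = mean(is_true[ord[seq_len(k)]]),
         recall = sum(pass & is_true) / k,
         precision = if (any(pass)) sum(pass & is_true) / sum(pass) else NA_real_,
         n_true = k, n_candidates = length(sc))
  } else {
    e <- edges_of(scores)
    incid <- e$gene_a %in% regulators | e$gene_b %in% regulators
    keys <- pair_keys(e$gene_a[incid], e$gene_b[incid])
    tp <- sum(keys %in% true_keys)
    list(aupr = NA_real_, baseline = NA_real_, precision_at_k = NA_real_,
         recall = tp / length(true_keys),
         precision = if (length(keys)) tp / length(keys) else NA_real_,
         n_true = length(true_keys), n_candidates = length(keys))
  }
}

#' Write a network edge list as TSV
#' @param net a `clr_network` or edge data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(edges_of(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#' @param path input path.
#' @return An edge data frame.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a network in SIF format (`gene_a  clr  gene_b`)
#' @inheritParams write_edge_list
#' @param interaction interaction label (default `"clr"`).
#' @export
write_sif <- function(net, path, interaction = "clr") {
  e <- edges_of(net)
  writeLines(paste(e$gene_a, interaction, e$gene_b, sep = "\t"), path)
  invisible(path)
}

#' Write a network in GraphML format for Cytoscape
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(net, path) {
  e <- edges_of(net)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
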