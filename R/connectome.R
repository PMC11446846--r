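# Signed connectome: loading, neurotransmitter sign rule, weight matrix,
# in-silico silencing and thresholded wiring-diagram export.

NT_LEVELS <- c("ACh", "GABA", "Glu", "DA", "5-HT", "OA", "unknown")
HEMI_LEVELS <- c("left", "right", "unknown")
INHIBITORY_NT <- c("GABA", "Glu")

#' Build a signed connectome from neuron and edge tables
#'
#' Constructs the signed, synapse-count-weighted connectivity used by the
#' network simulator. Each directed edge carries the synapse count linking the
#' two cells, and its sign follows the presynaptic neurotransmitter
#' prediction: GABAergic and glutamatergic cells are inhibitory, all other
#' transmitters (including unknown) excitatory. This makes the graph
#' Dale-consistent by construction: all outgoing edges of one neuron share
#' the sign implied by its transmitter.
#'
#' @param neurons data.frame with columns `id` (unique non-negative integer),
#'   `label`, `hemisphere` (`left`/`right`/`unknown`), `nt` (one of
#'   `r paste(NT_LEVELS, collapse = ", ")`), `class_tag` (free annotation,
#'   e.g. `walk`, `halt`, `DN`).
#' @param edges data.frame with columns `pre`, `post` (neuron ids) and
#'   `count` (positive integer synapse count). Duplicate `(pre, post)` rows —
#'   as produced by dumps that split an edge across neuropils — are summed
#'   into a single edge.
#' @return an object of class `signed_connectome`: a list with `neurons`
#'   (validated neuron table), `edges` (deduplicated edge table with a
#'   `sign` column in \{-1, +1\}).
#' @examples
#' nn <- data.frame(id = 1:3, label = c("A", "B", "C"),
#'                  hemisphere = "left", nt = c("ACh", "GABA", "ACh"),
#'                  class_tag = "other")
#' ee <- data.frame(pre = c(1, 2), post = c(2, 3), count = c(10, 7))
#' con <- signed_connectome(nn, ee)
#' con$edges$sign  # +1 (cholinergic), -1 (GABAergic)
#' @export
signed_connectome <- function(neurons, edges) {
  req_n <- c("id", "label", "hemisphere", "nt", "class_tag")
  req_e <- c("pre", "post", "count")
  missing_n <- setdiff(req_n, names(neurons))
  if (length(missing_n))
    stopf("neuron table lacks column(s): %s", paste(missing_n, collapse = ", "))
  missing_e <- setdiff(req_e, names(edges))
  if (length(missing_e))
    stopf("edge table lacks column(s): %s", paste(missing_e, collapse = ", "))

  neurons <- as.data.frame(neurons)[req_n]
  neurons$id <- as.integer(neurons$id)
  if (anyNA(neurons$id) || any(neurons$id < 0))
    stopf("neuron ids must be non-negative integers")
  if (anyDuplicated(neurons$id))
    stopf("duplicate neuron id(s): %s",
          paste(unique(neurons$id[duplicated(neurons$id)]), collapse = ", "))
  if (!all(neurons$hemisphere %in% HEMI_LEVELS))
    stopf("hemisphere values outside {%s}", paste(HEMI_LEVELS, collapse = ", "))
  bad_nt <- !(neurons$nt %in% NT_LEVELS)
  if (any(bad_nt))
    stopf("neurotransmitter label(s) outside the vocabulary: %s",
          paste(unique(neurons$nt[bad_nt]), collapse = ", "))
  n_unknown <- sum(neurons$nt == "unknown")
  if (n_unknown > 0)
    warning(sprintf("%d neuron(s) with unknown neurotransmitter treated as excitatory",
                    n_unknown), call. = FALSE)

  edges <- as.data.frame(edges)[req_e]
  edges$pre <- as.integer(edges$pre)
  edges$post <- as.integer(edges$post)
  edges$count <- as.integer(edges$count)
  if (nrow(edges)) {
    bad_cnt <- which(is.na(edges$count) | edges$count < 1L)
    if (length(bad_cnt))
      stopf("non-positive synapse count in edge row(s): %s",
            paste(bad_cnt, collapse = ", "))
    bad_ref <- which(!(edges$pre %in% neurons$id) | !(edges$post %in% neurons$id))
    if (length(bad_ref))
      stopf("edge row(s) %s reference unknown neuron id(s): %s",
            paste(bad_ref, collapse = ", "),
            paste(unique(c(edges$pre[bad_ref], edges$post[bad_ref])
                         [!(c(edges$pre[bad_ref], edges$post[bad_ref]) %in% neurons$id)]),
                  collapse = ", "))
    # merge duplicate (pre, post) rows by summing synapse counts
    key <- paste(edges$pre, edges$post, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- rowsum(edges$count, group = key, reorder = FALSE)
      first <- !duplicated(key)
      edges <- edges[first, , drop = FALSE]
      edges$count <- as.integer(agg[match(paste(edges$pre, edges$post, sep = "\r"),
                                          rownames(agg)), 1L])
    }
    nt_pre <- neurons$nt[match(edges$pre, neurons$id)]
    edges$sign <- ifelse(nt_pre %in% INHIBITORY_NT, -1L, +1L)
  } else {
    edges$sign <- integer(0)
  }
  rownames(edges) <- NULL
  structure(list(neurons = neurons, edges = edges),
            class = "signed_connectome")
}

#' @export
print.signed_connectome <- function(x, ...) {
  cat(sprintf("signed_connectome: %d neurons, %d edges (%d inhibitory), %d synapses\n",
              nrow(x$neurons), nrow(x$edges), sum(x$edges$sign < 0),
              sum(x$edges$count)))
  invisible(x)
}

#' Load a signed connectome from CSV tables
#'
#' Reads FlyWire-style columnar dumps: a neuron table with header
#' `id,label,hemisphere,nt,class_tag` and an edge table with header
#' `pre,post,count`, then applies the neurotransmitter sign rule (see
#' [signed_connectome()]).
#'
#' @param neuron_file,edge_file paths to CSV files.
#' @return a `signed_connectome`.
#' @export
load_connectome <- function(neuron_file, edge_file) {
  nn <- utils::read.csv(neuron_file, stringsAsFactors = FALSE)
  ee <- utils::read.csv(edge_file, stringsAsFactors = FALSE)
  signed_connectome(nn, ee)
}

#' Write a signed connectome back to CSV tables
#'
#' Inverse of [load_connectome()]: emits the neuron and edge tables in the
#' same column layout so that a written connectome reloads identically.
#'
#' @param conn a `signed_connectome`.
#' @param neuron_file,edge_file output CSV paths.
#' @return invisibly, `conn`.
#' @export
write_connectome <- function(conn, neuron_file, edge_file) {
  stopifnot(inherits(conn, "signed_connectome"))
  utils::write.csv(conn$neurons, neuron_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(conn$edges[c("pre", "post", "count")], edge_file,
                   row.names = FALSE, quote = FALSE)
  invisible(conn)
}

#' Signed synaptic weight matrix
#'
#' Converts a signed connectome into the sparse weight matrix driving the
#' integrate-and-fire simulation: `weight(pre, post) = sign(pre) * count *
#' w_unit`, where `w_unit` is the membrane-potential increment (mV) one
#' presynaptic spike delivers per synapse. Pairs without an edge have
#' weight 0.
#'
#' @param conn a `signed_connectome`.
#' @param w_unit voltage increment per synapse per spike, mV; must be > 0.
#' @return a `Matrix::sparseMatrix` (rows = presynaptic, columns =
#'   postsynaptic) with dimnames set to the neuron ids.
#' @export
build_weight_matrix <- function(conn, w_unit) {
  stopifnot(inherits(conn, "signed_connectome"))
  if (!is.numeric(w_unit) || length(w_unit) != 1L || w_unit <= 0)
    stopf("w_unit must be a single positive number (mV per synapse)")
  ids <- conn$neurons$id
  n <- length(ids)
  e <- conn$edges
  Matrix::sparseMatrix(
    i = match(e$pre, ids), j = match(e$post, ids),
    x = as.double(e$sign) * e$count * w_unit,
    dims = c(n, n), dimnames = list(as.character(ids), as.character(ids))
  )
}

#' Silence neurons by severing their outputs
#'
#' In-silico optogenetic silencing: every outgoing synaptic connection of the
#' listed neurons is removed; their incoming edges are retained, so they may
#' still integrate and spike but can no longer influence the network.
#'
#' @param conn a `signed_connectome`.
#' @param ids neuron ids to silence (may be empty).
#' @return a `signed_connectome` without the outgoing edges of `ids`.
#' @export
silence_neurons <- function(conn, ids) {
  stopifnot(inherits(conn, "signed_connectome"))
  ids <- as.integer(ids)
  unknown <- setdiff(ids, conn$neurons$id)
  if (length(unknown))
    stopf("cannot silence unknown neuron id(s): %s",
          paste(unknown, collapse = ", "))
  if (length(ids) == 0L) return(conn)
  conn$edges <- conn$edges[!(conn$edges$pre %in% ids), , drop = FALSE]
  rownames(conn$edges) <- NULL
  conn
}

#' Extract a thresholded wiring diagram
#'
#' Builds the signed graph used for circuit schematics: nodes are neurons
#' whose trial-averaged firing rate exceeds `rate_threshold` (weak responders
#' are hidden), edges are connections among retained nodes with at least
#' `min_synapses` synapses (the conventional floor is five), and node values
#' are rates normalized to the maximum retained rate so the strongest
#' responder is 1.
#'
#' @param conn a `signed_connectome`.
#' @param node_ids candidate neuron ids (non-empty).
#' @param rates named numeric vector of trial-averaged rates (Hz); names are
#'   neuron ids and must cover `node_ids`.
#' @param min_synapses integer edge floor (default 5).
#' @param rate_threshold node rate floor in Hz (default 0); nodes with rate
#'   strictly greater are kept.
#' @return a `wiring_diagram`: list with `nodes` (id, label, rate, norm_rate)
#'   and `edges` (pre, post, count, sign) data.frames plus the thresholds.
#' @export
extract_wiring_diagram <- function(conn, node_ids, rates,
                                   min_synapses = 5L, rate_threshold = 0) {
  stopifnot(inherits(conn, "signed_connectome"))
  node_ids <- as.integer(node_ids)
  if (length(node_ids) == 0L) stopf("node_ids must be non-empty")
  unknown <- setdiff(node_ids, conn$neurons$id)
  if (length(unknown))
    stopf("unknown node id(s): %s", paste(unknown, collapse = ", "))
  r <- rates[as.character(node_ids)]
  if (anyNA(r))
    stopf("rates missing for node id(s): %s",
          paste(node_ids[is.na(r)], collapse = ", "))
  keep <- node_ids[r > rate_threshold]
  kept_rates <- as.numeric(r[r > rate_threshold])
  mx <- if (length(kept_rates) && max(kept_rates) > 0) max(kept_rates) else 1
  nodes <- data.frame(
    id = keep,
    label = conn$neurons$label[match(keep, conn$neurons$id)],
    rate = kept_rates,
    norm_rate = kept_rates / mx
  )
  e <- conn$edges
  e <- e[e$pre %in% keep & e$post %in% keep & e$count >= min_synapses, ,
         drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e[c("pre", "post", "count", "sign")],
                 min_synapses = as.integer(min_synapses),
                 rate_threshold = rate_threshold),
            class = "wiring_diagram")
}

#' Write a wiring diagram as node/edge CSV tables
#'
#' Emits `nodes.csv` (`id,label,rate,norm_rate`) and `edges.csv`
#' (`pre,post,count,sign`) into `dir`, a layout generic graph viewers accept.
#'
#' @param wd a `wiring_diagram`.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_wiring_diagram <- function(wd, dir) {
  stopifnot(inherits(wd, "wiring_diagram"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- file.path(dir, "nodes.csv")
  ef <- file.path(dir, "edges.csv")
  utils::write.csv(wd$nodes, nf, row.names = FALSE, quote = FALSE)
  utils::write.csv(wd$edges, ef, row.names = FALSE, quote = FALSE)
  invisible(c(nodes = nf, edges = ef))
}
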