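# Synthetic connectome generator: named neuron groups, probabilistic
# connection rules and planted pathway motifs with a machine-readable
# ground-truth manifest.

#' Motif specification for a synthetic connectome
#'
#' @param populations data.frame with `name`, `size`, `nt`, `class_tag`
#'   (and optionally `hemisphere`); one row per neuron group.
#' @param rules data.frame with `source`, `target` (group names), `prob`
#'   (per-pair connection probability in \[0, 1\]), `count_min`,
#'   `count_max` (synapse-count range, >= 1); may have zero rows.
#' @param motifs optional data.frame of planted pathways with `name`,
#'   `source`, `target`, `count`: every (source, target) neuron pair is
#'   connected with exactly `count` synapses, and the manifest records the
#'   motif with its expected sign.
#' @return a `motif_spec` list.
#' @export
motif_spec <- function(populations, rules = NULL, motifs = NULL) {
  stopifnot(all(c("name", "size", "nt", "class_tag") %in% names(populations)))
  if (anyDuplicated(populations$name)) stopf("duplicate population names")
  if (!all(populations$nt %in% NT_LEVELS))
    stopf("population nt outside the vocabulary")
  if (is.null(rules))
    rules <- data.frame(source = character(0), target = character(0),
                        prob = numeric(0), count_min = integer(0),
                        count_max = integer(0))
  for (col in c("source", "target"))
    for (tbl in list(rules, motifs))
      if (!is.null(tbl) && nrow(tbl) &&
          !all(tbl[[col]] %in% populations$name))
        stopf("connection rule references unknown group(s): %s",
              paste(setdiff(tbl[[col]], populations$name), collapse = ", "))
  if (nrow(rules) && (any(rules$prob < 0) || any(rules$prob > 1)))
    stopf("rule probabilities must lie in [0, 1]")
  if (nrow(rules) && any(rules$count_min < 1))
    stopf("synapse counts must be >= 1")
  structure(list(populations = populations, rules = rules, motifs = motifs),
            class = "motif_spec")
}

#' Canonical walk-OFF test circuit
#'
#' A minimal planted motif mirroring halting by inhibition of walking
#' commands: an excitatory walking command group projecting onto a
#' descending neuron group, and a GABAergic halt group projecting onto the
#' same descending neurons. Co-stimulating the halt group must lower the
#' descending neurons' rate, and silencing the halt group while both drives
#' are on must raise it — the manifest records both predictions.
#'
#' @param n_walk,n_halt,n_dn group sizes.
#' @param walk_count,halt_count synapse counts of the planted connections.
#' @return a `motif_spec`.
#' @export
walkoff_motif_spec <- function(n_walk = 1L, n_halt = 1L, n_dn = 1L,
                               walk_count = 30L, halt_count = 40L) {
  pops <- data.frame(
    name = c("walk", "halt", "dn"),
    size = c(n_walk, n_halt, n_dn),
    nt = c("ACh", "GABA", "ACh"),
    class_tag = c("walk", "halt", "DN")
  )
  motifs <- data.frame(
    name = c("walk_drive", "walk_off"),
    source = c("walk", "halt"),
    target = c("dn", "dn"),
    count = c(walk_count, halt_count)
  )
  motif_spec(pops, motifs = motifs)
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Draws neurons for each population, connects pairs according to the
#' probabilistic rules and plants the motif pathways deterministically. The
#' returned manifest is a plain list (JSON-serializable) recording id
#' ranges per group and every planted edge with its expected sign, so
#' round-trip tests never parse prose.
#'
#' @param spec a [motif_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with `neurons`, `edges` (tables loadable by
#'   [signed_connectome()]) and `manifest`.
#' @export
synth_connectome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  pops <- spec$populations
  sizes <- as.integer(pops$size)
  stops_ <- cumsum(sizes)
  starts <- stops_ - sizes + 1L
  ids_of <- function(g) {
    k <- match(g, pops$name)
    seq(starts[k], stops_[k])
  }
  hemi <- if ("hemisphere" %in% names(pops)) pops$hemisphere else
    rep("left", nrow(pops))
  neurons <- data.frame(
    id = seq_len(sum(sizes)),
    label = unlist(mapply(function(nm, s) paste0(nm, "_", seq_len(s)),
                          pops$name, sizes, SIMPLIFY = FALSE)),
    hemisphere = rep(hemi, sizes),
    nt = rep(pops$nt, sizes),
    class_tag = rep(pops$class_tag, sizes)
  )

  pre <- integer(0); post <- integer(0); cnt <- integer(0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (nrow(spec$rules)) for (k in seq_len(nrow(spec$rules))) {
    rl <- spec$rules[k, ]
    src <- ids_of(rl$source); tgt <- ids_of(rl$target)
    pairs <- expand.grid(pre = src, post = tgt)
    set.seed(substream_seed(seed, 1L, k))
    hit <- stats::runif(nrow(pairs)) < rl$prob
    if (any(hit)) {
      pre <- c(pre, pairs$pre[hit]); post <- c(post, pairs$post[hit])
      cnt <- c(cnt, sample(rl$count_min:rl$count_max, sum(hit),
                           replace = TRUE))
    }
  }
  planted <- list()
  if (!is.null(spec$motifs) && nrow(spec$motifs))
    for (k in seq_len(nrow(spec$motifs))) {
      mf <- spec$motifs[k, ]
      src <- ids_of(mf$source); tgt <- ids_of(mf$target)
      pairs <- expand.grid(pre = src, post = tgt)
      pre <- c(pre, pairs$pre); post <- c(post, pairs$post)
      cnt <- c(cnt, rep(as.integer(mf$count), nrow(pairs)))
      src_nt <- pops$nt[match(mf$source, pops$name)]
      planted[[mf$name]] <- list(
        source_ids = src, target_ids = tgt, count = as.integer(mf$count),
        sign = if (src_nt %in% INHIBITORY_NT) -1L else 1L,
        # severing an inhibitor releases its targets; severing an exciter
        # suppresses them
        silencing_effect_on_target = if (src_nt %in% INHIBITORY_NT)
          "increase" else "decrease"
      )
    }
  edges <- data.frame(pre = pre, post = post, count = cnt)
  manifest <- list(
    format_version = 1L, seed = as.integer(seed),
    groups = lapply(seq_len(nrow(pops)), function(k)
      list(name = pops$name[k], ids = seq(starts[k], stops_[k]),
           nt = pops$nt[k], class_tag = pops$class_tag[k])),
    planted_motifs = planted
  )
  list(neurons = neurons, edges = edges, manifest = manifest)
}

#' Write synthetic connectome tables and manifest to disk
#'
#' @param sc result of [synth_connectome()].
#' @param dir output directory (created if needed); writes `neurons.csv`,
#'   `edges.csv` and `manifest.json`.
#' @return invisibly, the file paths.
#' @export
write_synth_connectome <- function(sc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- file.path(dir, "neurons.csv"); ef <- file.path(dir, "edges.csv")
  mf <- file.path(dir, "manifest.json")
  utils::write.csv(sc$neurons, nf, row.names = FALSE, quote = FALSE)
  utils::write.csv(sc$edges, ef, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sc$manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(neurons = nf, edges = ef, manifest = mf))
}
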