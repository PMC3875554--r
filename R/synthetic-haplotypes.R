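#' Parameters for the haplotype-set simulator
#'
#' Describes a true mutation graph: nodes are haplotypes, each edge
#' carries a known number of mutational steps, and each observed node is
#' sampled a given number of times. The graph must be connected and the
#' total step count cannot exceed the sequence length (each step uses a
#' private site, so pairwise Hamming distances equal shortest-path step
#' sums by construction).
#'
#' @param seq_length number of sites.
#' @param graph data frame (or 3-column matrix) of edges `node_a`,
#'   `node_b`, `steps`.
#' @param counts named integer vector: sampled copies per node (>= 1).
#' @param seed RNG seed.
#' @return An object of class `haplo_sim_params`.
#' @export
haplo_sim_params <- function(seq_length, graph, counts, seed = 1L) {
  graph <- as.data.frame(graph, stringsAsFactors = FALSE)
  names(graph) <- c("node_a", "node_b", "steps")
  graph$node_a <- as.character(graph$node_a)
  graph$node_b <- as.character(graph$node_b)
  graph$steps <- as.integer(graph$steps)
  if (any(graph$steps < 1)) stop("edge steps must be >= 1")
  nodes <- unique(c(graph$node_a, graph$node_b))
  if (sum(graph$steps) > seq_length)
    stop("total steps (", sum(graph$steps),
         ") exceed sequence length (", seq_length, ")")
  # connectivity check
  seen <- nodes[1]
  repeat {
    nb <- unique(c(graph$node_b[graph$node_a %in% seen],
                   graph$node_a[graph$node_b %in% seen]))
    new <- setdiff(nb, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  if (length(setdiff(nodes, seen)))
    stop("truth graph is not connected: ",
         paste(setdiff(nodes, seen), collapse = ", "))
  if (nrow(graph) != length(nodes) - 1L)
    stop("truth graph must be a tree (", length(nodes) - 1L,
         " edges for ", length(nodes), " nodes); cycles cannot have ",
         "edge-disjoint mutated sites with consistent distances")
  if (is.null(names(counts)) || !all(names(counts) %in% nodes))
    stop("`counts` must be named by graph nodes")
  if (any(counts < 1)) stop("counts must be >= 1")
  structure(list(seq_length = as.integer(seq_length), graph = graph,
                 nodes = nodes, counts = counts,
                 seed = as.integer(seed)),
            class = "haplo_sim_params")
}

#' Simulate haplotype sequences on a known mutation graph
#'
#' Draws a random ancestral sequence and walks the truth graph from its
#' first node; each edge substitutes its stated number of steps at site
#' positions used by no other edge, so the Hamming distance between
#' adjacent nodes equals the edge's step count exactly, and distances
#' between any two nodes equal path step sums. Each node is then emitted
#' `counts[node]` times as identical copies.
#'
#' @param params a [haplo_sim_params].
#' @return A list with `alignment` (a [seq_alignment]; sequence ids
#'   `<node>_<k>`, groups = node), `truth` (the edge data frame) and
#'   `node_sequences` (named character vector).
#' @export
simulate_haplotypes <- function(params) {
  if (!inherits(params, "haplo_sim_params"))
    stop("`params` must be created by haplo_sim_params()")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)
  bases <- c("A", "C", "G", "T")
  L <- params$seq_length
  anc <- sample(bases, L, replace = TRUE)
  g <- params$graph
  # disjoint site blocks, one per edge
  sites <- sample.int(L, sum(g$steps))
  offs <- c(0, cumsum(g$steps))
  node_seq <- list()
  node_seq[[params$nodes[1]]] <- anc
  todo <- g
  while (nrow(todo)) {
    ready <- which(todo$node_a %in% names(node_seq) |
                     todo$node_b %in% names(node_seq))[1]
    e <- todo[ready, ]
    ei <- which(g$node_a == e$node_a & g$node_b == e$node_b &
                  g$steps == e$steps)[1]
    from <- if (e$node_a %in% names(node_seq)) e$node_a else e$node_b
    to <- setdiff(c(e$node_a, e$node_b), from)
    s <- node_seq[[from]]
    for (pos in sites[(offs[ei] + 1):offs[ei + 1]]) {
      s[pos] <- sample(setdiff(bases, s[pos]), 1)
    }
    if (!to %in% names(node_seq)) node_seq[[to]] <- s
    todo <- todo[-ready, , drop = FALSE]
  }
  ids <- unlist(lapply(params$nodes, function(nd)
    paste0(nd, "_", seq_len(params$counts[[nd]]))))
  groups <- stats::setNames(rep(params$nodes, params$counts[params$nodes]),
                            ids)
  seqs <- do.call(rbind, lapply(params$nodes, function(nd)
    matrix(rep(node_seq[[nd]], params$counts[[nd]]),
           nrow = params$counts[[nd]], byrow = TRUE)))
  rownames(seqs) <- ids
  list(alignment = seq_alignment(seqs, groups = groups),
       truth = g,
       node_sequences = vapply(node_seq, paste, character(1),
                               collapse = ""))
}
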