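test_that("identical and compatible sequences collapse together", {
  aln <- seq_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  hs <- collapse_haplotypes(aln)
  expect_length(hs$haplotypes, 1)
  expect_equal(hs$haplotypes$H1$count, 3L)

  # N is missing: ACNT joins ACGT and the consensus stays resolved
  aln2 <- seq_alignment(c(a = "ACGT", b = "ACNT", c = "AGGT"))
  hs2 <- collapse_haplotypes(aln2)
  expect_length(hs2$haplotypes, 2)
  expect_equal(hs2$haplotypes$H1$members, c("a", "b"))
  expect_equal(hs2$haplotypes$H1$sequence, c("A", "C", "G", "T"))

  # masked columns are removed before collapsing
  aln3 <- seq_alignment(c(a = "ACGT", b = "ACGA"), mask = 4L)
  expect_length(collapse_haplotypes(aln3)$haplotypes, 1)

  # gaps: missing by default, fifth state on request
  aln4 <- seq_alignment(c(a = "ACGT", b = "AC-T"))
  expect_length(collapse_haplotypes(aln4)$haplotypes, 1)
  expect_length(collapse_haplotypes(aln4, gap_as_state = TRUE)$haplotypes,
                2)
})

test_that("parsimony probabilities are monotone and properly bounded", {
  P <- parsimony_probability(1:30, 700)
  expect_true(all(diff(P) < 0))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(parsimony_probability(0, 700), 1)
  # j_max non-decreasing in sequence length
  jm <- vapply(seq(100, 1000, by = 100), connection_limit, integer(1))
  expect_true(all(diff(jm) >= 0))
  # tiny confidence connects everything
  expect_equal(connection_limit(150, confidence = 1e-300), 150L)
  expect_equal(connection_limit(500, fixed_limit = 3), 3L)
  expect_error(connection_limit(0), "at least 1")
})

test_that("minimum-spanning core keeps chains and drops redundant links", {
  # A-B-C at 1+1 steps: the 2-step A-C link is redundant, not a loop
  aln <- seq_alignment(c(a = "AAAA", b = "AAAT", c = "AATT"))
  net <- build_network(collapse_haplotypes(aln), j_max = 5)
  expect_equal(nrow(net$connections), 2)
  expect_true(all(net$connections$steps == 1))
  expect_equal(nrow(net$ambiguous), 0)
  expect_equal(sum(net$nodes$type == "inferred"), 0)
  expect_length(net$components, 1)
})

test_that("connections beyond the limit split the network", {
  aln <- seq_alignment(c(a = "AAAAAA", b = "TTTCAA"))
  hs <- collapse_haplotypes(aln)   # 4 steps apart
  net <- build_network(hs, j_max = 3)
  expect_equal(nrow(net$connections), 0)
  expect_length(net$components, 2)
  net2 <- build_network(hs, j_max = 4)
  expect_equal(nrow(net2$connections), 1)
  # a 4-step realized connection inserts exactly 3 intermediates
  expect_equal(sum(net2$nodes$type == "inferred"), 3)
  expect_equal(nrow(net2$edges), 4)
  expect_true(all(net2$edges$steps == 1))
})

test_that("equal-step alternatives closing a cycle are reported", {
  # three haplotypes pairwise 2 steps apart: two connections realized,
  # the third is an ambiguous loop at the same step level
  aln <- seq_alignment(c(a = "AATT", b = "TTTT", c = "TAAT"))
  hs <- collapse_haplotypes(aln)
  net <- build_network(hs, j_max = 4)
  expect_equal(nrow(net$connections), 2)
  expect_equal(nrow(net$ambiguous), 1)
  expect_equal(net$ambiguous$steps, 2)
})

test_that("simulated truth graphs are recovered within the limit", {
  graph <- data.frame(
    node_a = c("A", "B", "B", "C"),
    node_b = c("B", "C", "D", "E"),
    steps = c(1, 3, 2, 4))
  sim <- simulate_haplotypes(haplo_sim_params(
    500, graph, counts = c(A = 4, B = 1, C = 2, D = 1, E = 3),
    seed = 8))
  # simulated Hamming distances equal shortest-path step sums
  ns <- sim$node_sequences
  h <- function(u, v) sum(strsplit(ns[[u]], "")[[1]] !=
                            strsplit(ns[[v]], "")[[1]])
  expect_equal(h("A", "B"), 1)
  expect_equal(h("A", "C"), 4)
  expect_equal(h("D", "E"), 9)
  hs <- collapse_haplotypes(sim$alignment)
  expect_length(hs$haplotypes, 5)
  net <- build_network(hs, j_max = connection_limit(500))
  got <- net$connections
  # map haplotype ids back to truth nodes via their members
  lab <- vapply(hs$haplotypes, function(hp)
    unique(sim$alignment$groups[hp$members]), character(1))
  got_edges <- sort(paste(pmin(lab[got$a], lab[got$b]),
                          pmax(lab[got$a], lab[got$b]), got$steps))
  want_edges <- sort(paste(pmin(graph$node_a, graph$node_b),
                           pmax(graph$node_a, graph$node_b),
                           graph$steps))
  expect_identical(got_edges, want_edges)
})

test_that("network construction is deterministic", {
  sim <- simulate_haplotypes(haplo_sim_params(
    300, data.frame(a = c("A", "B"), b = c("B", "C"), steps = c(2, 3)),
    counts = c(A = 2, B = 2, C = 2), seed = 4))
  hs <- collapse_haplotypes(sim$alignment)
  n1 <- build_network(hs, j_max = 8)
  n2 <- build_network(hs, j_max = 8)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("simulator validates its truth graph", {
  expect_error(haplo_sim_params(
    5, data.frame(a = "A", b = "B", steps = 9), counts = c(A = 1, B = 1)),
    "exceed")
  expect_error(haplo_sim_params(
    100, data.frame(a = c("A", "C"), b = c("B", "D"), steps = c(1, 1)),
    counts = c(A = 1, B = 1, C = 1, D = 1)), "not connected")
  expect_error(haplo_sim_params(
    100, data.frame(a = c("A", "B", "C"), b = c("B", "C", "A"),
                    steps = c(1, 1, 1)),
    counts = c(A = 1, B = 1, C = 1)), "tree")
  # A-B one step, counts 2/1: three sequences, two identical
  sim <- simulate_haplotypes(haplo_sim_params(
    50, data.frame(a = "A", b = "B", steps = 1), counts = c(A = 2, B = 1),
    seed = 1))
  S <- sim$alignment$seqs
  expect_equal(nrow(S), 3)
  expect_identical(S["A_1", ], S["A_2", ])
  expect_equal(sum(S["A_1", ] != S["B_1", ]), 1)
  # determinism
  sim2 <- simulate_haplotypes(haplo_sim_params(
    50, data.frame(a = "A", b = "B", steps = 1), counts = c(A = 2, B = 1),
    seed = 1))
  expect_identical(sim$alignment$seqs, sim2$alignment$seqs)
})
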