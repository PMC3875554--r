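AMBIG_MISSING <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                   "N", "?", "U")

#' Collapse aligned sequences into haplotypes
#'
#' Removes masked columns, then groups sequences by identity over
#' mutually resolved sites: ambiguity codes (and, by default, gaps) are
#' treated as missing data, and a sequence joins an existing haplotype
#' exactly when it is compatible at every site where both it and the
#' haplotype's resolved consensus carry a state. Assignment order is
#' deterministic (first occurrence; a sequence joins the earliest
#' compatible haplotype and its resolved states are merged into that
#' haplotype's consensus).
#'
#' @param aln a [seq_alignment].
#' @param gap_as_state treat `-` as a fifth character state rather than
#'   missing (default FALSE: residual gaps in masked protein-coding or
#'   rDNA alignments are treated as alignment artifacts).
#' @return An object of class `haplotype_set`: `haplotypes` (list of
#'   `sequence` (consensus character vector), `count`, `members`),
#'   `site_count`, `labels` (per-haplotype group labels from the
#'   alignment's group map).
#' @export
collapse_haplotypes <- function(aln, gap_as_state = FALSE) {
  if (!nrow(aln$seqs)) stop("empty alignment")
  keep <- setdiff(seq_len(ncol(aln$seqs)), aln$mask)
  S <- aln$seqs[, keep, drop = FALSE]
  missing_states <- if (gap_as_state) AMBIG_MISSING else
    c(AMBIG_MISSING, "-")
  S[S %in% missing_states] <- NA_character_
  haps <- list()
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    placed <- FALSE
    for (h in seq_along(haps)) {
      cons <- haps[[h]]$sequence
      both <- !is.na(s) & !is.na(cons)
      if (all(s[both] == cons[both])) {
        fill <- !is.na(s) & is.na(cons)
        haps[[h]]$sequence[fill] <- s[fill]
        haps[[h]]$count <- haps[[h]]$count + 1L
        haps[[h]]$members <- c(haps[[h]]$members, rownames(S)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      haps[[length(haps) + 1L]] <- list(
        sequence = s, count = 1L, members = rownames(S)[i])
  }
  names(haps) <- paste0("H", seq_along(haps))
  labels <- vapply(haps, function(h)
    paste(sort(unique(aln$groups[h$members])), collapse = "+"),
    character(1))
  structure(list(haplotypes = haps, site_count = ncol(S),
                 labels = labels),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set: ", length(x$haplotypes), " haplotypes from ",
      sum(vapply(x$haplotypes, `[[`, integer(1), "count")),
      " sequences over ", x$site_count, " sites\n", sep = "")
  invisible(x)
}

#' Probability that a j-step connection is parsimonious
#'
#' The probability that two haplotypes differing at `j` of `L`
#' comparable sites are connected by exactly `j` substitutions, i.e.
#' that no site on the path mutated more than once. Computed under an
#' explicit Poisson multiple-hit model with Jukes-Cantor state dynamics:
#' the per-site expected hit count `d` is estimated by inverting the
#' observed difference fraction `j/L = 3/4 (1 - exp(-4d/3))`, and
#' `P_j = P(exactly one hit | site differs)^j * P(zero hits | site
#' identical)^(L-j)`. The sequence `P_1 >= P_2 >= ...` is monotone
#' non-increasing, as required of a parsimony-probability sequence.
#' This model is deliberately conservative relative to older
#' coalescent-based operationalizations of the same limit.
#'
#' @param j number of observed differences (steps).
#' @param L number of comparable sites.
#' @return Probability in \[0, 1\].
#' @export
parsimony_probability <- function(j, L) {
  if (L < 1) stop("L must be at least 1")
  raw <- vapply(seq_len(max(j, 1)), function(jj) {
    # cap the difference fraction just below the 3/4 saturation point
    # so the probability stays positive for every j <= L
    pd <- min(jj / L, 0.75 * (1 - 1 / (2 * L)))
    d <- -0.75 * log(1 - 4 * pd / 3)
    p_one_given_diff <- d * exp(-d) / pd          # k=1 always visible
    p_zero_given_same <- exp(-d) / (1 - pd)
    p_one_given_diff^jj * p_zero_given_same^(L - jj)
  }, numeric(1))
  # monotone envelope: a longer connection is never more plausible
  env <- cummin(raw)
  vapply(j, function(jj) if (jj == 0) 1 else env[jj], numeric(1))
}

#' Statistical-parsimony connection limit
#'
#' The largest step count `j` whose parsimony probability
#' ([parsimony_probability()]) is at least `confidence` (0.95 by
#' default): connections longer than this are not justified at the
#' stated confidence and are left unmade. Monotone non-decreasing in
#' `L`. `fixed_limit` bypasses the computation.
#'
#' @param L number of comparable sites.
#' @param confidence required parsimony probability.
#' @param fixed_limit optional integer override.
#' @return Integer step limit.
#' @export
connection_limit <- function(L, confidence = 0.95, fixed_limit = NULL) {
  if (!is.null(fixed_limit)) return(as.integer(fixed_limit))
  if (L < 1) stop("L must be at least 1")
  j <- 0L
  while (j < L && parsimony_probability(j + 1L, L) >= confidence)
    j <- j + 1L
  j
}

hamming_resolved <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) return(NA_integer_)
  sum(a[both] != b[both])
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects haplotypes in order of increasing step count (Hamming
#' distance over mutually resolved sites), adding a connection only when
#' it is within the parsimony limit and joins two components not yet
#' connected (a minimum-spanning-network core; ties in step count are
#' processed in lexicographic node order). Equal-step alternatives that
#' would close a cycle at the step level where their endpoints were
#' joined are retained as "ambiguous loops" and reported separately.
#' Each realized multi-step connection is expanded into a path of
#' single-step edges through `steps - 1` anonymous inferred
#' intermediates (unsampled alleles). Haplotypes farther than the limit
#' from every component stay unconnected.
#'
#' @param haps a [haplotype_set].
#' @param j_max connection limit in steps; default computed from the
#'   site count via [connection_limit()].
#' @param confidence confidence for the default limit.
#' @return An object of class `parsimony_network`: `nodes` (id, type
#'   observed/inferred, count, label), `edges` (single-step edges after
#'   intermediate insertion), `connections` (realized
#'   haplotype-to-haplotype connections with step counts), `ambiguous`
#'   (loop-closing alternatives), `components` (list of node-id
#'   vectors), `j_max`.
#' @export
build_network <- function(haps, j_max = NULL, confidence = 0.95) {
  if (is.null(j_max))
    j_max <- connection_limit(haps$site_count, confidence)
  hs <- haps$haplotypes
  ids <- names(hs)
  n <- length(hs)
  cand <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- hamming_resolved(hs[[i]]$sequence, hs[[j]]$sequence)
        if (!is.na(d))
          cand[[length(cand) + 1L]] <-
            data.frame(a = ids[i], b = ids[j], steps = d)
      }
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(a = character(0), b = character(0), steps = integer(0))
  cand <- cand[cand$steps > 0 & cand$steps <= j_max, , drop = FALSE]
  cand <- cand[order(cand$steps, cand$a, cand$b), , drop = FALSE]
  comp <- stats::setNames(seq_len(n), ids)   # union-find by relabel
  conns <- cand[0, ]
  ambig <- cand[0, ]
  for (s in unique(cand$steps)) {
    grp <- cand[cand$steps == s, , drop = FALSE]
    comp_before <- comp
    for (r in seq_len(nrow(grp))) {
      ca <- comp[grp$a[r]]; cb <- comp[grp$b[r]]
      if (ca != cb) {
        comp[comp == cb] <- ca
        conns <- rbind(conns, grp[r, ])
      } else if (comp_before[grp$a[r]] != comp_before[grp$b[r]]) {
        # endpoints were joined within this step level: true alternative
        ambig <- rbind(ambig, grp[r, ])
      }
    }
  }
  nodes <- data.frame(
    id = ids, type = "observed",
    count = vapply(hs, `[[`, integer(1), "count"),
    label = unname(haps$labels), stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0))
  n_inferred <- 0L
  if (nrow(conns)) {
    for (r in seq_len(nrow(conns))) {
      s <- conns$steps[r]
      chain <- conns$a[r]
      if (s > 1) {
        mids <- paste0("m", n_inferred + seq_len(s - 1))
        n_inferred <- n_inferred + s - 1L
        nodes <- rbind(nodes, data.frame(
          id = mids, type = "inferred", count = 0L, label = "",
          stringsAsFactors = FALSE))
        chain <- c(chain, mids)
      }
      chain <- c(chain, conns$b[r])
      edges <- rbind(edges, data.frame(
        from = chain[-length(chain)], to = chain[-1], steps = 1L,
        stringsAsFactors = FALSE))
    }
  }
  comp_ids <- unique(comp)
  components <- lapply(comp_ids, function(cid) {
    obs <- ids[comp == cid]
    extra <- unique(c(edges$from, edges$to))
    c(obs, setdiff(extra[extra %in% reachable(edges, obs)], obs))
  })
  structure(list(nodes = nodes, edges = edges, connections = conns,
                 ambiguous = ambig, components = components,
                 j_max = j_max),
            class = "parsimony_network")
}

# node ids reachable from `start` along `edges`
reachable <- function(edges, start) {
  seen <- unique(start)
  repeat {
    nb <- unique(c(edges$to[edges$from %in% seen],
                   edges$from[edges$to %in% seen]))
    new <- setdiff(nb, seen)
    if (!length(new)) return(seen)
    seen <- c(seen, new)
  }
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("Statistical-parsimony network (limit ", x$j_max, " steps): ",
      sum(x$nodes$type == "observed"), " observed + ",
      sum(x$nodes$type == "inferred"), " inferred nodes, ",
      nrow(x$connections), " connections in ",
      length(x$components), " component(s)", sep = "")
  if (nrow(x$ambiguous))
    cat(", ", nrow(x$ambiguous), " ambiguous loop(s)", sep = "")
  cat("\n")
  invisible(x)
}
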