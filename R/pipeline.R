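write_provenance <- function(outdir, subcommand, params) {
  lines <- c(
    paste0("morphodiv ",
           as.character(utils::packageVersion("morphodiv"))),
    paste0("subcommand: ", subcommand),
    vapply(names(params), function(k)
      paste0(k, ": ", paste(format(params[[k]]), collapse = " ")),
      character(1)))
  writeLines(lines, file.path(outdir, "run_info.txt"))
}

write_num_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
}

#' Run the landmark morphometrics pipeline end to end
#'
#' Symmetrize, reduce to unique landmarks, superimpose (GPA), extract
#' shape principal components, fit and hierarchically prune a Type III
#' MANCOVA of the scores on clade, sex and size, residualize on the
#' retained nuisance terms, run the quadratic DFA with LOOCV, and
#' compute per-clade canonical mean shapes for thin-plate-spline
#' rendering. Writes aligned coordinates, centroid sizes, eigenvalues,
#' scores, the MANCOVA table, confusion tables, warp polylines and a
#' plain-text report to `outdir`.
#'
#' @param dataset a `morpho_dataset` (e.g. from [assemble_dataset()] or
#'   [simulate_landmarks()]).
#' @param outdir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param threshold PCA variance retention threshold.
#' @param alpha MANCOVA pruning threshold.
#' @param magnify warp display magnification.
#' @param log_size use log centroid size as the covariate (default
#'   FALSE: size enters untransformed).
#' @return A list with `shapes`, `pca`, `mancova` (pruned), `dfa`,
#'   `warps`, `data` (model frame), invisibly when writing.
#' @export
run_morpho <- function(dataset, outdir = NULL, threshold = 0.95,
                       alpha = 0.05, magnify = 10, log_size = FALSE) {
  sym <- lapply(dataset$configs, symmetrize)
  uni <- lapply(sym, unique_landmarks)
  shapes <- gpa(uni)
  pca <- shape_pca(shapes, threshold)
  size <- unname(shapes$centroid_sizes)
  if (log_size) size <- log(size)
  df <- data.frame(clade = factor(dataset$meta$clade),
                   sex = factor(dataset$meta$sex),
                   size = size)
  pruned <- prune_and_refit(pca$scores, df, ~ clade * sex * size,
                            alpha = alpha)
  retained <- attr(stats::terms(pruned$formula), "term.labels")
  nuisance <- retained[!vapply(retained, function(tm)
    "clade" %in% term_factors(tm), logical(1))]
  res <- residualize(pca$scores, df, stats::reformulate(nuisance))
  dfa <- qda_loocv(res, df$clade)
  warps <- canonical_warp(shapes, pruned$fit, "clade")
  out <- list(shapes = shapes, pca = pca, mancova = pruned, dfa = dfa,
              warps = warps, data = df)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_provenance(outdir, "morpho",
                     list(n = length(dataset$configs),
                          threshold = threshold, alpha = alpha,
                          magnify = magnify, log_size = log_size))
    write_num_csv(data.frame(specimen_id = shapes$specimen_ids,
                             centroid_size = size, shapes$coords,
                             check.names = FALSE),
                  file.path(outdir, "aligned_coords.csv"))
    write_num_csv(data.frame(eigenvalue = pca$eigenvalues),
                  file.path(outdir, "eigenvalues.csv"))
    write_num_csv(data.frame(specimen_id = shapes$specimen_ids,
                             pca$scores),
                  file.path(outdir, "scores.csv"))
    write_num_csv(pruned$fit$table,
                  file.path(outdir, "mancova.csv"))
    write_num_csv(as.data.frame(dfa$loocv$percent),
                  file.path(outdir, "confusion_loocv.csv"))
    write_num_csv(as.data.frame(dfa$resubstitution$percent),
                  file.path(outdir, "confusion_resubstitution.csv"))
    for (g in names(warps$predicted)) {
      tr <- fit_tps(shapes$consensus, warps$predicted[[g]])
      grid <- warp_grid(tr, magnify = magnify)
      poly <- do.call(rbind, lapply(seq_along(grid$polylines),
        function(i) data.frame(polyline = i, x = grid$polylines[[i]][, 1],
                               y = grid$polylines[[i]][, 2])))
      write_num_csv(poly, file.path(outdir,
                                    paste0("warp_grid_", g, ".csv")))
    }
    rpt <- file.path(outdir, "report.txt")
    sink(rpt); on.exit(sink(), add = TRUE)
    print(pca); cat("\n"); print(pruned$fit); cat("\n"); print(dfa)
  }
  invisible(out)
}

#' Run the K2P divergence summary
#'
#' @param aln a [seq_alignment] with group labels.
#' @param outdir output directory, or `NULL`.
#' @param deletion site-deletion mode, see [k2p_matrix()].
#' @return The `divergence_summary`, invisibly when writing.
#' @export
run_divergence <- function(aln, outdir = NULL, deletion = "pairwise") {
  summ <- group_summary(aln, deletion)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_provenance(outdir, "k2p",
                     list(n = nrow(aln$seqs), deletion = deletion))
    write_num_csv(data.frame(id = rownames(summ$distances),
                             summ$distances, check.names = FALSE),
                  file.path(outdir, "k2p_matrix.csv"))
    write_num_csv(summ$within, file.path(outdir, "within.csv"))
    write_num_csv(summ$between, file.path(outdir, "between.csv"))
    rpt <- file.path(outdir, "report.txt")
    sink(rpt); on.exit(sink(), add = TRUE)
    print(summ)
  }
  invisible(summ)
}

#' Run the statistical-parsimony network pipeline
#'
#' @param aln a [seq_alignment].
#' @param outdir output directory, or `NULL`.
#' @param confidence parsimony confidence for the connection limit.
#' @param fixed_limit optional step-limit override.
#' @param gap_as_state treat gaps as a fifth state when collapsing.
#' @return The `parsimony_network`, invisibly when writing.
#' @export
run_network <- function(aln, outdir = NULL, confidence = 0.95,
                        fixed_limit = NULL, gap_as_state = FALSE) {
  haps <- collapse_haplotypes(aln, gap_as_state = gap_as_state)
  j_max <- connection_limit(haps$site_count, confidence, fixed_limit)
  net <- build_network(haps, j_max)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_provenance(outdir, "network",
                     list(n = nrow(aln$seqs), confidence = confidence,
                          j_max = j_max, gap_as_state = gap_as_state))
    write_num_csv(net$nodes, file.path(outdir, "nodes.csv"))
    write_num_csv(net$edges, file.path(outdir, "edges.csv"))
    write_num_csv(net$connections, file.path(outdir, "connections.csv"))
    rpt <- file.path(outdir, "report.txt")
    sink(rpt); on.exit(sink(), add = TRUE)
    print(haps); print(net)
  }
  invisible(net)
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline functions, used by the
#' `inst/cli/morphodiv.R` script. Subcommands: `simulate-landmarks`
#' (writes TPS + metadata CSV), `simulate-haplotypes` (writes FASTA +
#' truth edge list), `morpho`, `k2p`, `network`. Options are
#' `--key=value` pairs; every subcommand takes `--out=<dir>` and the
#' simulators take `--seed=<int>`.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, 0 on success (invisibly); validation failures
#'   signal an error with a one-line diagnostic.
#' @export
cli_main <- function(args) {
  if (!length(args))
    stop("usage: morphodiv <simulate-landmarks|simulate-haplotypes|",
         "morpho|k2p|network> [--key=value ...]")
  sub <- args[1]
  opts <- list()
  for (a in args[-1]) {
    if (!grepl("^--[a-z-]+(=.*)?$", a)) stop("bad option: ", a)
    kv <- sub("^--", "", a)
    k <- sub("=.*$", "", kv)
    v <- if (grepl("=", kv)) sub("^[^=]*=", "", kv) else "TRUE"
    opts[[gsub("-", "_", k)]] <- v
  }
  out <- opts$out
  if (is.null(out)) stop("--out=<dir> is required")
  num <- function(k, d) if (is.null(opts[[k]])) d else
    as.numeric(opts[[k]])
  switch(sub,
    "simulate-landmarks" = {
      p <- morpho_sim_params(seed = as.integer(num("seed", 1)))
      sim <- simulate_landmarks(p)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_tps(sim$dataset$configs, file.path(out, "landmarks.tps"))
      write_num_csv(sim$dataset$meta, file.path(out, "meta.csv"))
      write_provenance(out, sub, list(seed = p$seed))
    },
    "simulate-haplotypes" = {
      p <- haplo_sim_params(
        seq_length = as.integer(num("length", 700)),
        graph = data.frame(node_a = c("A", "B", "C"),
                           node_b = c("B", "C", "D"),
                           steps = c(1, 2, 3)),
        counts = c(A = 3, B = 2, C = 1, D = 1),
        seed = as.integer(num("seed", 1)))
      sim <- simulate_haplotypes(p)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_alignment(sim$alignment, file.path(out, "haplotypes.fasta"),
                      "fasta")
      write_num_csv(sim$truth, file.path(out, "truth_edges.csv"))
      write_provenance(out, sub, list(seed = p$seed))
    },
    "morpho" = {
      tps <- opts$tps; meta <- opts$meta
      if (is.null(tps) || !file.exists(tps))
        stop("landmark file not found: ",
             if (is.null(tps)) "(missing --tps)" else tps)
      if (is.null(meta) || !file.exists(meta))
        stop("metadata file not found: ",
             if (is.null(meta)) "(missing --meta)" else meta)
      ds <- assemble_dataset(read_tps(tps, y_down = !is.null(opts$y_down)),
                             read_meta_csv(meta))
      run_morpho(ds, out, threshold = num("threshold", 0.95),
                 alpha = num("alpha", 0.05),
                 magnify = num("magnify", 10),
                 log_size = !is.null(opts$log_size))
    },
    "k2p" = {
      if (is.null(opts$aln) || !file.exists(opts$aln))
        stop("alignment file not found: ",
             if (is.null(opts$aln)) "(missing --aln)" else opts$aln)
      aln <- read_alignment(opts$aln)
      if (!is.null(opts$groups)) {
        g <- utils::read.csv(opts$groups, stringsAsFactors = FALSE)
        aln$groups <- stats::setNames(g[[2]], g[[1]])[rownames(aln$seqs)]
      }
      run_divergence(aln, out,
                     deletion = if (!is.null(opts$complete_deletion))
                       "complete" else "pairwise")
    },
    "network" = {
      if (is.null(opts$aln) || !file.exists(opts$aln))
        stop("alignment file not found: ",
             if (is.null(opts$aln)) "(missing --aln)" else opts$aln)
      aln <- read_alignment(opts$aln)
      run_network(aln, out, confidence = num("confidence", 0.95),
                  fixed_limit = if (!is.null(opts$fixed_limit))
                    as.integer(opts$fixed_limit),
                  gap_as_state = !is.null(opts$gap_as_state))
    },
    stop("unknown subcommand: ", sub))
  invisible(0L)
}
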