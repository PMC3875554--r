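IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")

#' Aligned sequence set with an exclusion mask
#'
#' Container for a multiple sequence alignment over the IUPAC DNA
#' alphabet (gaps allowed), an exclusion mask of alignment columns to
#' ignore (1-based indices; e.g. positions flagged as unreliably aligned
#' by an external confidence analysis -- masks are consumed as given,
#' never recomputed here), and an optional id-to-group mapping.
#'
#' @param seqs character matrix (sequences x sites, single characters,
#'   rownames = ids), or a named character vector of equal-length
#'   strings.
#' @param mask integer vector of excluded column indices (1-based).
#' @param groups named character vector mapping sequence id to
#'   clade/taxon label (defaults to each id as its own group).
#' @return An object of class `seq_alignment`.
#' @export
seq_alignment <- function(seqs, mask = integer(0), groups = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "))
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  } else {
    seqs <- as.matrix(seqs)
    seqs[] <- toupper(seqs)
    if (is.null(rownames(seqs)))
      rownames(seqs) <- paste0("seq", seq_len(nrow(seqs)))
  }
  bad <- setdiff(unique(as.vector(seqs)), IUPAC_DNA)
  if (length(bad))
    stop("unknown sequence character(s): ",
         paste(shQuote(bad), collapse = ", "))
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1 || max(mask) > ncol(seqs)))
    stop("mask indices outside 1..", ncol(seqs))
  if (is.null(groups))
    groups <- stats::setNames(rownames(seqs), rownames(seqs))
  structure(list(seqs = seqs, mask = mask,
                 groups = groups[rownames(seqs)]),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("Alignment: ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " sites (", length(x$mask), " masked), ",
      length(unique(x$groups)), " groups\n", sep = "")
  invisible(x)
}

#' Read an alignment from FASTA or NEXUS
#'
#' FASTA is read via \pkg{ape}; NEXUS via `ape::read.nexus.data`, with
#' any `EXSET` exclusion sets in an ASSUMPTIONS block (e.g.
#' `EXSET * untitled = 12 40-60;`) parsed and merged into the mask.
#' Sequences are uppercased; a ragged alignment or a character outside
#' the IUPAC DNA alphabet is an error.
#'
#' @param path input file.
#' @param format `"fasta"` or `"nexus"` (default guessed from the
#'   extension).
#' @param groups optional named character vector, id -> group label.
#' @return A [seq_alignment].
#' @export
read_alignment <- function(path, format = NULL, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  format <- match.arg(format, c("fasta", "nexus"))
  if (format == "fasta") {
    d <- ape::read.FASTA(path)
    ch <- lapply(as.character(d), toupper)
    lens <- lengths(ch)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "))
    seqs <- do.call(rbind, ch)
    rownames(seqs) <- names(ch)
    mask <- integer(0)
  } else {
    d <- ape::read.nexus.data(path)
    lens <- lengths(d)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "))
    seqs <- do.call(rbind, lapply(d, toupper))
    mask <- parse_nexus_exsets(readLines(path, warn = FALSE))
  }
  seq_alignment(seqs, mask = mask, groups = groups)
}

# parse `EXSET [*] name = <ranges>;` site lists (1-based, `a-b` ranges)
parse_nexus_exsets <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  hits <- regmatches(txt, gregexpr(
    "(?i)EXSET\\s*\\*?\\s*[^=;]*=\\s*[^;]*;", txt, perl = TRUE))[[1]]
  mask <- integer(0)
  for (h in hits) {
    body <- sub(";$", "", sub("^[^=]*=", "", h))
    for (tok in strsplit(trimws(body), "\\s+")[[1]]) {
      if (grepl("^\\d+-\\d+$", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        mask <- c(mask, seq(ab[1], ab[2]))
      } else if (grepl("^\\d+$", tok)) {
        mask <- c(mask, as.integer(tok))
      }
    }
  }
  sort(unique(mask))
}

#' Write an alignment to FASTA or NEXUS
#'
#' NEXUS output includes an ASSUMPTIONS block with an `EXSET` recording
#' the exclusion mask, so a round trip preserves it.
#'
#' @param aln a [seq_alignment].
#' @param path output file.
#' @param format `"fasta"` or `"nexus"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  ids <- rownames(aln$seqs)
  strs <- apply(aln$seqs, 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", ids), strs)), path)
  } else {
    out <- c("#NEXUS", "BEGIN DATA;",
             paste0("DIMENSIONS NTAX=", length(ids),
                    " NCHAR=", ncol(aln$seqs), ";"),
             "FORMAT DATATYPE=DNA MISSING=N GAP=-;",
             "MATRIX",
             paste(ids, strs),
             ";", "END;")
    if (length(aln$mask)) {
      out <- c(out, "BEGIN ASSUMPTIONS;",
               paste0("EXSET * excluded = ",
                      paste(collapse_ranges(aln$mask), collapse = " "),
                      ";"),
               "END;")
    }
    writeLines(out, path)
  }
  invisible(path)
}

collapse_ranges <- function(idx) {
  idx <- sort(unique(idx))
  brk <- c(0, which(diff(idx) != 1), length(idx))
  vapply(seq_len(length(brk) - 1), function(i) {
    a <- idx[brk[i] + 1]; b <- idx[brk[i + 1]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computed over alignment columns not in the mask where both sequences
#' carry an unambiguous base (A, C, G or T): gaps and ambiguity codes
#' are excluded pairwise. With transition proportion `P` (A<->G, C<->T)
#' and transversion proportion `Q`,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When a log argument is
#' non-positive (saturation) or no comparable sites remain the distance
#' is undefined and `NA` is returned with a `"reason"` attribute.
#'
#' @param a,b character vectors of aligned single characters (or
#'   strings), equal length.
#' @param mask integer vector of excluded columns (1-based).
#' @return Distance as substitutions per site, or `NA` with a reason
#'   attribute.
#' @export
k2p <- function(a, b, mask = integer(0)) {
  if (length(a) == 1 && is.character(a)) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1 && is.character(b)) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b))
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  keep <- rep(TRUE, length(a))
  keep[mask] <- FALSE
  ok <- keep & a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  L <- sum(ok)
  if (L == 0)
    return(structure(NA_real_, reason = "no comparable sites"))
  aa <- a[ok]; bb <- b[ok]
  diff <- aa != bb
  purines <- c("A", "G")
  transition <- diff & ((aa %in% purines) == (bb %in% purines))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(structure(NA_real_, reason = "saturated (log argument <= 0)"))
  -0.5 * log(arg1) - 0.25 * log(arg2) + 0  # + 0 drops IEEE negative zero
}

#' All pairwise K2P distances in an alignment
#'
#' @param aln a [seq_alignment].
#' @param deletion `"pairwise"` (default; sites excluded per pair) or
#'   `"complete"` (any column with a gap/ambiguity in any sequence is
#'   excluded for all pairs).
#' @return Symmetric distance matrix (NA where undefined).
#' @export
k2p_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  S <- aln$seqs
  mask <- aln$mask
  if (deletion == "complete") {
    resolved <- apply(S, 2, function(col)
      all(col %in% c("A", "C", "G", "T")))
    mask <- sort(unique(c(mask, which(!resolved))))
  }
  n <- nrow(S)
  D <- matrix(0, n, n, dimnames = list(rownames(S), rownames(S)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- k2p(S[i, ], S[j, ], mask)
    }
  }
  D
}

#' Within- and between-group divergence summary
#'
#' Minimum and maximum pairwise K2P distance within each group (NA for
#' singleton groups) and between each pair of groups, in the layout of a
#' lower/upper-triangle divergence table with within-group ranges on the
#' diagonal.
#'
#' @param aln a [seq_alignment] with a group mapping.
#' @param deletion passed to [k2p_matrix()].
#' @return An object of class `divergence_summary` with data frames
#'   `within` (group, n, min, max) and `between` (group_a, group_b, min,
#'   max), plus the full distance matrix.
#' @export
group_summary <- function(aln, deletion = "pairwise") {
  D <- k2p_matrix(aln, deletion)
  grp <- aln$groups
  labels <- unique(grp)
  within <- do.call(rbind, lapply(labels, function(g) {
    idx <- which(grp == g)
    if (length(idx) < 2)
      return(data.frame(group = g, n = length(idx), min = NA_real_,
                        max = NA_real_))
    d <- D[idx, idx][upper.tri(diag(length(idx)))]
    data.frame(group = g, n = length(idx),
               min = suppressWarnings(min(d, na.rm = TRUE)),
               max = suppressWarnings(max(d, na.rm = TRUE)))
  }))
  pairs <- if (length(labels) > 1) utils::combn(labels, 2) else
    matrix(character(0), 2, 0)
  between <- do.call(rbind, c(list(
    data.frame(group_a = character(0), group_b = character(0),
               min = numeric(0), max = numeric(0))),
    lapply(seq_len(ncol(pairs)), function(k) {
      ia <- which(grp == pairs[1, k]); ib <- which(grp == pairs[2, k])
      d <- D[ia, ib, drop = FALSE]
      data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                 min = suppressWarnings(min(d, na.rm = TRUE)),
                 max = suppressWarnings(max(d, na.rm = TRUE)))
    })))
  structure(list(within = within, between = between, distances = D,
                 groups = labels),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, percent = TRUE, ...) {
  f <- function(v) if (percent) sprintf("%.2f", 100 * v) else
    sprintf("%.4f", v)
  labels <- x$groups
  M <- matrix("", length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(x$within))) {
    w <- x$within[i, ]
    M[w$group, w$group] <- if (is.na(w$min)) "N/A" else
      paste0(f(w$min), "-", f(w$max))
  }
  for (i in seq_len(nrow(x$between))) {
    b <- x$between[i, ]
    M[b$group_a, b$group_b] <- M[b$group_b, b$group_a] <-
      paste0(f(b$min), "-", f(b$max))
  }
  cat("K2P divergence (", if (percent) "percent" else "proportion",
      "; diagonal = within-group range):\n", sep = "")
  print(M, quote = FALSE)
  invisible(x)
}
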