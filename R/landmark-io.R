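#' Read landmark configurations from a TPS file
#'
#' Parses the TpsDig dialect of the TPS landmark format: records of the
#' form `LM=<k>` followed by `k` whitespace-separated coordinate lines,
#' with optional `SCALE=<s>` and `ID=<id>` or `IMAGE=<name>` keys after
#' the coordinates. Records with a landmark count other than 27 are
#' accepted here; the count is validated downstream when a dataset is
#' assembled.
#'
#' TpsDig digitizes in image coordinates where y increases downward;
#' internal math assumes a right-handed frame (y up). Set `y_down =
#' TRUE` for files digitized from images to negate y on input.
#'
#' @param path path to a TPS file.
#' @param y_down logical; negate y coordinates on read.
#' @return A list of [landmark_config] objects (empty list for an empty
#'   file).
#' @export
read_tps <- function(path, y_down = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected 'LM=<count>', got '",
           line, "'")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("TPS parse error at line ", i, ": bad landmark count")
    if (i + k > n)
      stop("TPS parse error at line ", i,
           ": record truncated (expected ", k, " coordinate lines)")
    pts <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      fields <- strsplit(trimws(lines[i + j]), "\\s+")[[1]]
      xy <- suppressWarnings(as.numeric(fields))
      if (length(xy) != 2L || anyNA(xy))
        stop("TPS parse error at line ", i + j,
             ": expected two numeric coordinates, got '",
             trimws(lines[i + j]), "'")
      pts[j, ] <- xy
    }
    i <- i + k + 1L
    id <- NA_character_
    scale <- 1
    while (i <= n) {
      key <- trimws(lines[i])
      if (grepl("^SCALE\\s*=", key, ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=\\s*", "", key, ignore.case = TRUE)))
        if (is.na(scale))
          stop("TPS parse error at line ", i, ": bad SCALE value")
      } else if (grepl("^ID\\s*=", key, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", key, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", key, ignore.case = TRUE)) {
        if (is.na(id))
          id <- sub("^IMAGE\\s*=\\s*", "", key, ignore.case = TRUE)
      } else break
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("specimen_", length(configs) + 1L)
    if (y_down) pts[, 2] <- -pts[, 2]
    configs[[length(configs) + 1L]] <-
      landmark_config(pts, specimen_id = id, scale = scale)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written with 6 significant digits, matching TpsDig
#' output precision; `SCALE=` is written only when it differs from 1.
#'
#' @param configs list of [landmark_config] objects.
#' @param path output path.
#' @export
write_tps <- function(configs, path) {
  out <- character(0)
  for (cfg in configs) {
    pts <- cfg$points
    out <- c(out,
             paste0("LM=", nrow(pts)),
             paste(format_sig6(pts[, 1]), format_sig6(pts[, 2])))
    if (cfg$scale != 1)
      out <- c(out, paste0("SCALE=", format_sig6(cfg$scale)))
    out <- c(out, paste0("ID=", cfg$specimen_id))
  }
  writeLines(out, path)
  invisible(path)
}

format_sig6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

#' Read a specimen metadata table
#'
#' Expects a CSV with header `specimen_id,locality,clade,sex`; sex must
#' be one of `M` (male), `F` (gravid female), `J` (juvenile or
#' non-gravid female).
#'
#' @param path path to a CSV file.
#' @return A validated data frame of specimen metadata.
#' @export
read_meta_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}
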