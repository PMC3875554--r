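#' Landmark configuration for one specimen
#'
#' A `landmark_config` holds one specimen's ordered 2-D landmarks in
#' digitizer units together with an optional physical scale factor
#' (physical units per digitizer unit). The standard body scheme uses 27
#' landmarks: 1 and 25 mark the posterior eye margins at the body
#' perimeter, 2--11 and 15--24 the posterior-most point of each segment,
#' 12 and 14 the lateral posterior points of the pleotelson, 13 its
#' posterior tip, and 26/27 the inner eye margins.
#'
#' @param points numeric matrix with one row per landmark and columns
#'   `x`, `y`. Internally y increases upward (right-handed frame).
#' @param specimen_id character scalar identifying the specimen.
#' @param scale positive scalar, physical units per digitizer unit.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, specimen_id = "unnamed", scale = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must have two columns (x, y)")
  if (!all(is.finite(points)))
    stop("non-finite coordinate in configuration '", specimen_id, "'")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("`scale` must be a single positive number")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(specimen_id = as.character(specimen_id), points = points,
         scale = as.numeric(scale)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "': ",
      nrow(x$points), " landmarks, scale = ", format(x$scale), "\n",
      sep = "")
  invisible(x)
}

n_landmarks <- function(config) nrow(config$points)

#' Assemble a morphometric dataset from configurations and metadata
#'
#' Joins landmark configurations to a specimen metadata table on
#' `specimen_id`. Every configuration must have exactly one metadata row;
#' metadata rows without a configuration are dropped with a message.
#'
#' @param configs list of [landmark_config] objects.
#' @param meta data frame with columns `specimen_id`, `locality`,
#'   `clade`, `sex` (sex one of `"M"`, `"F"`, `"J"`).
#' @return An object of class `morpho_dataset` with elements `configs`
#'   (ordered as input) and `meta` (one row per configuration, same
#'   order).
#' @export
assemble_dataset <- function(configs, meta) {
  if (!length(configs)) stop("no configurations supplied")
  if (!all(vapply(configs, inherits, logical(1), "landmark_config")))
    stop("`configs` must be a list of landmark_config objects")
  meta <- validate_meta(meta)
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids))
    stop("duplicate specimen_id among configurations: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(ids, meta$specimen_id)
  if (length(missing))
    stop("no metadata row for specimen(s): ",
         paste(missing, collapse = ", "))
  nlm <- vapply(configs, n_landmarks, integer(1))
  if (length(unique(nlm)) != 1L)
    stop("configurations have unequal landmark counts: ",
         paste(unique(nlm), collapse = ", "))
  extra <- setdiff(meta$specimen_id, ids)
  if (length(extra))
    message("dropping ", length(extra),
            " metadata row(s) without a configuration: ",
            paste(extra, collapse = ", "))
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(configs = configs, meta = meta),
            class = "morpho_dataset")
}

validate_meta <- function(meta) {
  meta <- as.data.frame(meta)
  need <- c("specimen_id", "locality", "clade", "sex")
  absent <- setdiff(need, names(meta))
  if (length(absent))
    stop("metadata lacks column(s): ", paste(absent, collapse = ", "))
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$sex <- as.character(meta$sex)
  bad <- setdiff(unique(meta$sex), c("M", "F", "J"))
  if (length(bad))
    stop("unknown sex code(s): ", paste(bad, collapse = ", "),
         " (expected M, F or J)")
  if (anyDuplicated(meta$specimen_id))
    stop("duplicate specimen_id in metadata: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  meta
}

#' @export
print.morpho_dataset <- function(x, ...) {
  cat("Morphometric dataset: ", length(x$configs), " specimens, ",
      n_landmarks(x$configs[[1]]), " landmarks\n", sep = "")
  tab <- table(clade = x$meta$clade, sex = x$meta$sex)
  print(tab)
  invisible(x)
}
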