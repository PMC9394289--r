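#' Electrode montages
#'
#' A montage is the set of named scalp electrode positions, as 3D coordinates
#' on a unit-head-radius sphere, used to compute inter-electrode distances for
#' the distance-based adjacency matrix.
#'
#' @param channels character vector of channel names
#' @param positions numeric matrix, one row per channel, columns x, y, z
#'   (unit head-radius scale)
#' @return an object of class `crgcn_montage`: a list with elements
#'   `channels` and `positions`
#' @seealso [default_montage()], [read_montage()], [distance_adjacency()]
#' @export
montage <- function(channels, positions) {
  positions <- as.matrix(positions)
  if (length(channels) != nrow(positions))
    stop("montage: ", length(channels), " channel names but ",
         nrow(positions), " position rows")
  if (ncol(positions) != 3L)
    stop("montage: positions must have 3 columns (x, y, z)")
  if (anyDuplicated(channels))
    stop("montage: duplicate channel names: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (!all(is.finite(positions)))
    stop("montage: non-finite electrode coordinates")
  d <- as.matrix(stats::dist(positions))
  if (any(d[upper.tri(d)] == 0))
    stop("montage: coincident electrodes (zero pairwise distance)")
  storage.mode(positions) <- "double"
  dimnames(positions) <- list(channels, c("x", "y", "z"))
  structure(list(channels = as.character(channels), positions = positions),
            class = "crgcn_montage")
}

#' Bundled 32-channel 10-20 montage
#'
#' Standard 10-20 system 3D coordinates for the 32 EEG channels of the DEAP
#' recording layout (Fp1 ... O2), scaled to unit mean head radius. Shipped as
#' a plain-text table in `inst/extdata/montage_deap32.tsv`.
#'
#' @return a `crgcn_montage` with 32 channels
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_deap32.tsv", package = "crgcn",
                      mustWork = TRUE)
  read_montage(path)
}

#' Read a montage from a tab- or whitespace-separated text file
#'
#' Expected columns: channel name, x, y, z (one electrode per line, with a
#' header line).
#'
#' @param path file path
#' @return a `crgcn_montage`
#' @export
read_montage <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("read_montage: expected columns channel, x, y, z in ", path)
  montage(tab[[1L]], as.matrix(tab[, 2:4]))
}

#' @export
print.crgcn_montage <- function(x, ...) {
  cat("<crgcn_montage> ", length(x$channels), " channels: ",
      paste(utils::head(x$channels, 4L), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Restrict a montage to a subset of its channels
#'
#' @param m a `crgcn_montage`
#' @param idx integer or character channel selector
#' @return a `crgcn_montage`
#' @export
subset_montage <- function(m, idx) {
  stopifnot(inherits(m, "crgcn_montage"))
  if (is.character(idx)) idx <- match(idx, m$channels)
  montage(m$channels[idx], m$positions[idx, , drop = FALSE])
}

#' Pairwise squared Euclidean electrode distances
#'
#' @param m a `crgcn_montage`
#' @return symmetric matrix of squared 3D distances, zero diagonal
#' @export
electrode_dist2 <- function(m) {
  stopifnot(inherits(m, "crgcn_montage"))
  d <- as.matrix(stats::dist(m$positions))^2
  dimnames(d) <- list(m$channels, m$channels)
  d
}
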