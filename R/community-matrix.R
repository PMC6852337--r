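#' Construct a community matrix
#'
#' Sites x species (or spectral-cluster) abundance counts together with the
#' site centre coordinates, the spectral coverage fraction of each site and
#' site ids. This is the container passed between the spectral, diversity
#' and model-fitting stages.
#'
#' @param counts non-negative integer matrix, sites in rows.
#' @param coords two-column matrix of site centres (metres).
#' @param coverage per-site fraction of valid pixels in `[0, 1]`.
#' @param ids site identifiers.
#' @return an object of class `community_matrix`.
#' @export
community_matrix <- function(counts, coords, coverage = NULL, ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("abundances must be non-negative integers")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(counts), ncol(coords) == 2)
  coverage <- coverage %||% rep(1, nrow(counts))
  if (any(coverage < 0 | coverage > 1)) stop("coverage must lie in [0, 1]")
  ids <- ids %||% paste0("s", seq_len(nrow(counts)))
  rownames(counts) <- ids
  colnames(coords) <- c("x", "y")
  structure(list(counts = counts, coords = coords,
                 coverage = coverage, ids = ids),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", nrow(x$counts), " sites x ", ncol(x$counts),
      " taxa, total abundance ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.community_matrix <- function(x, ...) {
  data.frame(cell_id = x$ids, x = x$coords[, 1], y = x$coords[, 2],
             coverage = x$coverage, x$counts, check.names = FALSE)
}
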