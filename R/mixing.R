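#' Lateral nearest-neighbour census by lipid class
#'
#' For every reference molecule, neighbours are molecules of the same
#' leaflet whose 2-D (xy) minimum-image distance is within `cutoff`; a
#' molecule is never its own neighbour.  Counts are accumulated per
#' (reference class, neighbour class) pair and per frame, pooled over
#' leaflets.
#'
#' @param points A `lateral_points` object (see
#'   [generate_lateral_types()]), or a single data.frame with columns
#'   `x`, `y`, `class` (one leaflet, one frame; supply `box_xy`).
#' @param cutoff Lateral cutoff in Angstrom.
#' @param box_xy Lateral box lengths (needed only for the data.frame form).
#' @return A `neighbor_census`: `counts` (class x class x frame array of
#'   neighbour tallies), `classes`, `class_counts` (molecules per class in
#'   one leaflet), `n_frames`, `cutoff`.
#' @export
neighbor_census <- function(points, cutoff, box_xy = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.data.frame(points)) {
    if (is.null(box_xy)) stop("box_xy required for data.frame input")
    points <- structure(list(
      leaflets = list(upper = list(x = matrix(points$x), y = matrix(points$y),
                                   class = as.character(points$class))),
      box_xy = box_xy,
      classes = sort(unique(as.character(points$class)))),
      class = "lateral_points")
  }
  stopifnot(inherits(points, "lateral_points"))
  classes <- points$classes
  k <- length(classes)
  nf <- ncol(points$leaflets[[1]]$x)
  counts <- array(0, c(k, k, nf), dimnames = list(classes, classes, NULL))
  lx <- points$box_xy[1]; ly <- points$box_xy[2]
  for (leaf in points$leaflets) {
    n <- nrow(leaf$x)
    if (n == 0L) stop("empty leaflet in neighbour census")
    ci <- match(leaf$class, classes)
    for (f in seq_len(nf)) {
      dx <- outer(leaf$x[, f], leaf$x[, f], "-")
      dy <- outer(leaf$y[, f], leaf$y[, f], "-")
      dx <- dx - lx * round(dx / lx)
      dy <- dy - ly * round(dy / ly)
      adj <- (dx * dx + dy * dy) <= cutoff^2
      diag(adj) <- FALSE
      # tally: rows = reference, cols = neighbour
      for (i in seq_len(k)) {
        ri <- which(ci == i)
        if (!length(ri)) next
        nb <- adj[ri, , drop = FALSE]
        tallies <- tabulate(ci[which(nb, arr.ind = TRUE)[, 2L]], nbins = k)
        counts[i, , f] <- counts[i, , f] + tallies
      }
    }
  }
  first_leaf <- points$leaflets[[1]]
  class_counts <- vapply(classes,
                         function(cl) sum(first_leaf$class == cl), 0L)
  structure(list(counts = counts, classes = classes,
                 class_counts = class_counts, n_frames = nf,
                 cutoff = cutoff),
            class = "neighbor_census")
}

#' Grouped lipid enrichment/depletion index
#'
#' `E[i, j]` is the frame-averaged fraction of class-j molecules among
#' the neighbours of class-i references, divided by the bulk fraction of
#' class j with the reference molecule excluded from its own bulk
#' denominator (`(N_j - delta_ij) / (N - 1)` in a leaflet of N
#' molecules).  An index of 1 corresponds to random mixing, > 1 to
#' enrichment and < 1 to depletion of class j around class i.  The
#' normalisation identity `sum_j f_j|i E[i, j] = 1` holds for every row
#' by construction.  Frames in which a reference class has no neighbours
#' at all are skipped for that row; classes absent from the composition
#' yield masked (`NA`) entries.
#'
#' @param census A `neighbor_census`.
#' @param comp Optional `membrane_composition` supplying per-leaflet class
#'   counts; by default the census' own point counts are used.
#' @return An `enrichment_matrix`: `index` (class x class), `classes`,
#'   `n_frames` (frames used per reference class), `cutoff`,
#'   `per_frame_fraction` (mean neighbour fraction before normalisation).
#' @export
enrichment_index <- function(census, comp = NULL) {
  stopifnot(inherits(census, "neighbor_census"))
  classes <- census$classes
  k <- length(classes)
  if (!is.null(comp)) {
    cf <- class_fractions(comp)
    nvec <- stats::setNames(cf$count, cf$class)[classes]
    if (anyNA(nvec)) stop("composition lacks a class present in the census")
  } else {
    nvec <- census$class_counts
  }
  n_tot <- sum(nvec)
  if (n_tot < 2L) stop("degenerate census: fewer than two molecules")
  mean_frac <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  frames_used <- stats::setNames(integer(k), classes)
  for (i in seq_len(k)) {
    tot <- colSums(matrix(census$counts[i, , ], k))  # per-frame totals
    use <- tot > 0
    frames_used[i] <- sum(use)
    if (!any(use)) next
    fr <- sweep(matrix(census$counts[i, , use], k), 2L, tot[use], "/")
    mean_frac[i, ] <- rowMeans(fr)
  }
  index <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) {
    if (nvec[i] == 0L) next
    for (j in seq_len(k)) {
      f_bulk <- (nvec[j] - (i == j)) / (n_tot - 1)
      if (f_bulk <= 0) next  # masked: class absent from the bulk
      index[i, j] <- mean_frac[i, j] / f_bulk
    }
  }
  structure(list(index = index, classes = classes,
                 n_frames = frames_used, cutoff = census$cutoff,
                 per_frame_fraction = mean_frac),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> cutoff %.3g A, %s frames\n",
              x$cutoff, paste(unique(x$n_frames), collapse = "/")))
  print(round(x$index, 3))
  invisible(x)
}

#' Long-format export of an enrichment matrix
#' @param x An `enrichment_matrix`.
#' @return data.frame `ref_class`, `neighbor_class`, `index`.
#' @export
enrichment_long <- function(x) {
  stopifnot(inherits(x, "enrichment_matrix"))
  k <- length(x$classes)
  data.frame(ref_class = rep(x$classes, each = k),
             neighbor_class = rep(x$classes, k),
             index = as.vector(t(x$index)),
             stringsAsFactors = FALSE)
}
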