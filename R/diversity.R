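## Per-pixel species richness and Faith's phylogenetic diversity surfaces,
## from stacked binary range rasters or gridded occurrence records plus a
## rooted phylogeny with branch lengths.

#' Community matrix from stacked binary range rasters
#'
#' Each species' range arrives as a binary (0/1) raster; stacking them gives
#' the pixels-by-species presence/absence matrix, whose row sums are the
#' species richness surface.
#'
#' @param ranges list of binary [RasterLayer-class] (or a
#'   [RasterStack-class]) on one shared grid.
#' @param species species names, one per range layer.
#' @return A [CommunityMatrix-class]. A cell is valid if it is unmasked in
#'   at least one range layer.
#' @export
stackRanges <- function(ranges, species = NULL) {
  if (is(ranges, "RasterStack")) {
    if (is.null(species)) species <- ranges@labels
    ranges <- ranges@layers
  }
  if (is.null(species)) species <- names(ranges)
  stopifnot(length(species) == length(ranges))
  grid <- ranges[[1]]@grid
  pres <- matrix(FALSE, grid@nrow * grid@ncol, length(ranges))
  valid <- rep(FALSE, nrow(pres))
  for (i in seq_along(ranges)) {
    if (!sameGrid(ranges[[i]]@grid, grid))
      stop("range layer '", species[i], "' is not on the shared grid")
    v <- cellValues(ranges[[i]])
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad))
      stop("range layer '", species[i], "' is not binary (0/1)")
    pres[, i] <- !is.na(v) & v == 1
    valid <- valid | !is.na(v)
  }
  colnames(pres) <- species
  new("CommunityMatrix", grid = grid, species = as.character(species),
      presence = pres, mask = valid)
}

#' Community matrix from occurrence records
#'
#' Bins point records `(species, lon, lat, year)` onto a grid by half-open
#' cell-center binning: a species is present in a pixel if at least one of
#' its records falls there (within `yearRange` when given). Records outside
#' the grid extent are counted and reported via attribute `nOutside`, not
#' fatal. Records with missing year are excluded when `yearRange` is given
#' and kept otherwise.
#'
#' @param records data.frame with columns `species`, `lon`, `lat` and
#'   optionally `year`.
#' @param grid target [GridSpec-class].
#' @param yearRange optional `c(first, last)` filter on `year`.
#' @return A [CommunityMatrix-class]; all grid cells are valid.
#' @export
gridOccurrences <- function(records, grid, yearRange = NULL) {
  stopifnot(all(c("species", "lon", "lat") %in% names(records)))
  if (!is.null(yearRange)) {
    stopifnot("year" %in% names(records))
    records <- records[!is.na(records$year) &
                         records$year >= yearRange[1] &
                         records$year <= yearRange[2], , drop = FALSE]
  }
  species <- sort(unique(as.character(records$species)))
  ncell <- grid@nrow * grid@ncol
  pres <- matrix(FALSE, ncell, length(species),
                 dimnames = list(NULL, species))
  nOutside <- 0L
  if (nrow(records) == 0) {
    warning("no occurrence records to grid")
  } else {
    idx <- cellFromXY(grid, records$lon, records$lat)
    nOutside <- sum(is.na(idx))
    ok <- !is.na(idx)
    pres[cbind(idx[ok], match(as.character(records$species)[ok], species))] <- TRUE
  }
  cm <- new("CommunityMatrix", grid = grid, species = species,
            presence = pres, mask = rep(TRUE, ncell))
  attr(cm, "nOutside") <- nOutside
  cm
}

#' Species richness surface
#'
#' @param cm a [CommunityMatrix-class].
#' @return A [RasterLayer-class] of per-pixel species counts (masked cells
#'   are `NA`).
#' @export
richnessFromCommunity <- function(cm) {
  counts <- rowSums(cm@presence)
  counts[!cm@mask] <- NA_real_
  layerFromVec(counts, cm@grid)
}

#' Faith's phylogenetic diversity surface
#'
#' Rooted Faith's PD per pixel: the summed branch lengths of the union of
#' root-to-tip paths over the species present there. The path to the root is
#' included, so a single-species pixel gets that species' root-to-tip
#' distance; a pixel with all species gets the total tree length plus the
#' root edge (if any). Empty pixels get PD = 0.
#'
#' @param cm a [CommunityMatrix-class]; all present species must be tips of
#'   `tree`.
#' @param tree a rooted `phylo` tree with branch lengths (see [ape::read.tree]).
#' @return A [RasterLayer-class] of PD in branch-length units.
#' @export
faithPD <- function(cm, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  present <- cm@species[colSums(cm@presence) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))

  ## logical edges x tips incidence: edge e is on the root-to-tip path of tip t
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    desc[par, ] <- desc[par, ] | desc[child, ]
  }
  inc <- desc[tr$edge[, 2], , drop = FALSE]       # edges x tips
  colnames(inc) <- tr$tip.label

  inTree <- cm@species %in% tr$tip.label          # all-absent species may be off-tree
  pres <- cm@presence[, inTree, drop = FALSE]
  incSel <- inc[, match(cm@species[inTree], tr$tip.label), drop = FALSE]
  ## pixels x edges: does any present species descend from this edge?
  onPath <- (pres %*% t(incSel)) > 0
  pd <- as.vector(onPath %*% tr$edge.length)
  pd[!cm@mask] <- NA_real_
  layerFromVec(pd, cm@grid)
}
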