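#' Simulate a species phylogeny
#'
#' A Yule (pure-birth) simulation conditioned on the number of tips, giving a
#' rooted, ultrametric, bifurcating tree whose tips are exactly the supplied
#' species ids.  Tree depth is rescaled to `depth` so branch lengths are on a
#' stable scale regardless of the number of species.
#'
#' @param speciesIds character vector (>= 2, unique) of tip labels.
#' @param seed integer seed (substream `"phylo"`).
#' @param birth Yule speciation rate.
#' @param depth root-to-tip depth after rescaling.
#' @return an [ape::phylo] object.
#' @examples
#' phy <- generatePhylogeny(c("sp1", "sp2", "sp3"), seed = 1)
#' ape::is.ultrametric(phy)
#' @export
generatePhylogeny <- function(speciesIds, seed, birth = 1, depth = 100) {
  if (length(speciesIds) < 2) stop("need at least 2 species")
  if (anyDuplicated(speciesIds)) stop("duplicate tip labels are not allowed")
  withSubstream(seed, "phylo", {
    phy <- ape::rphylo(length(speciesIds), birth = birth, death = 0)
    phy$tip.label <- as.character(speciesIds)
    d <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * depth / d
    phy
  })
}

#' Write / read a phylogeny as Newick text
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that keep
#' enough digits for branch lengths to round-trip to 1e-9 relative accuracy.
#'
#' @param phy an [ape::phylo] object.
#' @param path file path.
#' @return `readNewick` returns the parsed tree.
#' @export
writeNewick <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
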