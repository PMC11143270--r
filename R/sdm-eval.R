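#' Predict, clip and binarise a species distribution
#'
#' Ensemble suitability over unmasked cells inside the species' range under
#' the requested scenario's climate (soil layers and elevation constant
#' across scenarios), binarised by the model's max-TSS threshold with the
#' `probability >= threshold` presence convention.  Cells outside the range
#' or masked are no-data.
#'
#' @param model an [EnsembleSDM-class].
#' @param env an [EnvStack-class].
#' @param range a [SpeciesRange-class] on the same grid.
#' @param scenario `"current"` or a future scenario name.
#' @return list with `suitability` (numeric matrix, NA outside range) and
#'   `binary` (0/1 matrix, NA outside range).
#' @export
predictAndBinarize <- function(model, env, range, scenario = "current") {
  if (!(scenario == "current" || scenario %in% envScenarios(env)))
    stop("unknown scenario: ", scenario)
  grid <- env@grid
  cells <- which(range@cells & env@mask, arr.ind = TRUE)
  suit <- matrix(NA_real_, grid@nRows, grid@nCols)
  if (nrow(cells) > 0) {
    x <- predictorMatrix(env, cells[, 1], cells[, 2], scenario)
    suit[cells] <- predictEnsemble(model, x)
  }
  binary <- ifelse(is.na(suit), NA_real_, as.numeric(suit >= model@threshold))
  list(suitability = suit, binary = binary)
}

#' Evaluate a binary distribution against presence-absence plots
#'
#' Plots outside the species' range (or on no-data cells) are excluded; the
#' species is skipped (returns `NULL`) when fewer than `minPresences`
#' in-range plot presences remain.  Metrics come from the 2x2 confusion
#' matrix of the binary map value at the plot's cell against the recorded
#' presence.
#'
#' @param binary 0/1/NA matrix from [predictAndBinarize()].
#' @param plots data.frame for one species: `lon`, `lat`, `present`.
#' @param range a [SpeciesRange-class].
#' @param minPresences minimum in-range plot presences.
#' @return list with `TSS`, `precision`, `recall`, `FPR`, `FNR` and the
#'   confusion counts, or `NULL` if skipped.
#' @export
evaluatePlots <- function(binary, plots, range, minPresences = 5) {
  grid <- range@grid
  idx <- cellIndex(grid, plots$lon, plots$lat)
  keep <- !is.na(idx$row)
  keep[keep] <- range@cells[cbind(idx$row[keep], idx$col[keep])] &
    !is.na(binary[cbind(idx$row[keep], idx$col[keep])])
  obs <- as.integer(plots$present[keep])
  if (sum(obs) < minPresences) return(NULL)
  pred <- binary[cbind(idx$row[keep], idx$col[keep])]
  TP <- sum(pred == 1 & obs == 1); FN <- sum(pred == 0 & obs == 1)
  FP <- sum(pred == 1 & obs == 0); TN <- sum(pred == 0 & obs == 0)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  list(TSS = sens + spec - 1,
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = sens,
       FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
       FNR = if (FN + TP > 0) FN / (FN + TP) else NA_real_,
       TP = TP, FP = FP, FN = FN, TN = TN)
}

#' Intersection over union of two binary maps
#'
#' @param a,b 0/1/NA matrices on the same grid.
#' @return |A intersect B| / |A union B| over suitable cells; 0 with
#'   attribute `empty_union = TRUE` if the union is empty.
#' @export
iouOverlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("binary maps are on different grids")
  A <- !is.na(a) & a == 1
  B <- !is.na(b) & b == 1
  uni <- sum(A | B)
  if (uni == 0) return(structure(0, empty_union = TRUE))
  sum(A & B) / uni
}
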