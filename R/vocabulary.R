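#' Controlled vocabulary of the N fertilization product
#'
#' Returns the fixed sets of labels the whole package computes over: the 21
#' crop groups of the gridded product, the 11 aggregate crop groups used by
#' fertilizer-use-by-crop (FUBC) surveys together with the many-to-one map
#' between the two, the 13 fertilizer types (11 synthetic types plus crop
#' residues CR and manure MA), the three N input classes (SN/MA/CR), the two
#' placements, and the 11 annual crops considered suitable for no-till.
#'
#' @return A named list with elements `cropGroups`, `fubcCropGroups`,
#'   `cropToFubc` (named character, crop -> FUBC group), `fertilizerTypes`,
#'   `snTypes`, `classes`, `placements`, `notillCrops`.
#' @examples
#' v <- nfertVocabulary()
#' length(v$cropGroups)      # 21
#' length(v$fertilizerTypes) # 13
#' @export
nfertVocabulary <- function() {
  cropGroups <- c(
    "Barley", "Cassava", "Cotton", "Fruits", "Groundnut", "Maize", "Millet",
    "Oilpalm", "Potato", "Rapeseed", "Rye", "Rice", "Sorghum", "Soybean",
    "Sugarbeet", "Sugarcane", "Sunflower", "Sweetpotato", "Vegetables",
    "Wheat", "Other crops")
  cropToFubc <- c(
    Barley = "Other cereals", Cassava = "Other crops", Cotton = "Cotton",
    Fruits = "Other crops", Groundnut = "Other oil crops", Maize = "Maize",
    Millet = "Other cereals", Oilpalm = "Oil palm", Potato = "Other crops",
    Rapeseed = "Other oil crops", Rye = "Other cereals", Rice = "Rice",
    Sorghum = "Other cereals", Soybean = "Soybean", Sugarbeet = "Sugar crops",
    Sugarcane = "Sugar crops", Sunflower = "Other oil crops",
    Sweetpotato = "Other crops", Vegetables = "Vegetables and fruits",
    Wheat = "Wheat", "Other crops" = "Other crops")
  fertilizerTypes <- c("AA", "AN", "AS", "CAN", "NS", "ONS", "Urea",
                       "AP", "NK", "NPK", "ONP", "CR", "MA")
  list(
    cropGroups = cropGroups,
    fubcCropGroups = c("Rice", "Maize", "Wheat", "Other cereals",
                       "Sugar crops", "Oil palm", "Other oil crops",
                       "Cotton", "Soybean", "Vegetables and fruits",
                       "Other crops"),
    cropToFubc = cropToFubc[cropGroups],
    fertilizerTypes = fertilizerTypes,
    snTypes = setdiff(fertilizerTypes, c("CR", "MA")),
    classes = c("SN", "MA", "CR"),
    placements = c("Surface", "Deep"),
    notillCrops = c("Soybean", "Wheat", "Maize", "Barley", "Rapeseed",
                    "Sunflower", "Sorghum", "Cotton", "Millet", "Groundnut",
                    "Vegetables"))
}
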