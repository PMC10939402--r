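#' Default cultivar roster
#'
#' The study roster of 45 grapevine cultivars used for one-hot encoding:
#' 24 cold-hardy interspecific hybrids and 21 *Vitis vinifera* cultivars
#' commonly grown in cool-climate viticultural regions of North America.
#' The order is fixed (hybrids first, each group alphabetical) and must be
#' serialized with any trained model, because it defines the position of
#' every cultivar indicator column.
#'
#' @return Character vector of 45 cultivar names with a `"group"` attribute
#'   (`"hybrid"` or `"vinifera"` per cultivar).
#' @export
#' @examples
#' length(default_roster())  # 45
default_roster <- function() {
  hybrids <- c(
    "Aromella", "Baco Noir", "Brianna", "Cayuga White", "Chambourcin",
    "Chancellor", "Chardonel", "Concord", "Corot Noir", "Frontenac",
    "Frontenac Gris", "Itasca", "La Crescent", "La Crosse", "Leon Millot",
    "Marechal Foch", "Marquette", "Niagara", "Noiret", "Petite Pearl",
    "Seyval Blanc", "St. Croix", "Traminette", "Vidal Blanc"
  )
  vinifera <- c(
    "Auxerrois", "Cabernet Franc", "Cabernet Sauvignon", "Chardonnay",
    "Chenin Blanc", "Dornfelder", "Gamay Noir", "Gewurztraminer",
    "Gruner Veltliner", "Lemberger", "Malbec", "Merlot", "Muscat Ottonel",
    "Pinot Blanc", "Pinot Gris", "Pinot Noir", "Riesling",
    "Sauvignon Blanc", "Syrah", "Viognier", "Zweigelt"
  )
  roster <- c(hybrids, vinifera)
  attr(roster, "group") <- c(rep("hybrid", length(hybrids)),
                             rep("vinifera", length(vinifera)))
  roster
}

validate_roster <- function(roster) {
  if (!is.character(roster) || length(roster) < 1L)
    stop_schema("cultivar roster must be a non-empty character vector")
  if (anyDuplicated(roster))
    stop_validation("cultivar roster contains duplicated names: %s",
                    paste(unique(roster[duplicated(roster)]), collapse = ", "))
  invisible(roster)
}
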