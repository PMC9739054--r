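#' Trait registry
#'
#' A trait registry records, for every trait the pipeline may touch, its
#' measurement units, its selection direction (whether larger or smaller
#' values are agronomically favourable) and a free-text description.  The
#' direction drives [rank_genotypes()]; units and descriptions are carried
#' into reports.
#'
#' @param trait character vector of trait names (abbreviations).
#' @param units character vector of measurement units, recycled if length 1.
#' @param direction character vector, each element `"higher_better"` or
#'   `"lower_better"`; recycled if length 1.
#' @param description optional character vector of descriptions.
#'
#' @return A data frame of class `"trait_registry"` with columns `trait`,
#'   `units`, `direction`, `description`.
#' @seealso [default_trait_registry()] for the wheat stress-screening traits.
#' @export
#' @examples
#' trait_registry(c("GY", "CWSI"), c("g", ""), c("higher_better", "lower_better"))
trait_registry <- function(trait, units = "", direction = "higher_better",
                           description = "") {
  trait <- as.character(trait)
  if (anyDuplicated(trait))
    stop("duplicate trait names in registry", call. = FALSE)
  direction <- rep_len(as.character(direction), length(trait))
  bad <- !direction %in% c("higher_better", "lower_better")
  if (any(bad))
    stop("direction must be 'higher_better' or 'lower_better' (trait ",
         paste(trait[bad], collapse = ", "), ")", call. = FALSE)
  out <- data.frame(trait = trait,
                    units = rep_len(as.character(units), length(trait)),
                    direction = direction,
                    description = rep_len(as.character(description),
                                          length(trait)),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_registry", "data.frame")
  out
}

#' Default registry for wheat drought/heat screening traits
#'
#' Registers the agronomic, physiological and thermal-imaging traits used in
#' terminal drought and heat stress screening of wheat, with their standard
#' abbreviations and selection directions.  Cooler canopies (lower Tc, CWSI,
#' higher Ig, CTD), retained water status (higher RWC, lower ELWL), delayed
#' senescence (lower FLSm, RCI) and larger yield components are favourable.
#'
#' @return A `"trait_registry"` data frame.
#' @export
default_trait_registry <- function() {
  trait_registry(
    trait = c("GY", "GPS", "GWS", "HI", "SF", "SL", "SN", "SPS", "PHT",
              "D50A", "DLR", "RWC", "ELWL", "FvFm", "RCI", "FLSm", "EVG",
              "Tc", "Tdry", "Twet", "CWSI", "Ig", "CTD"),
    units = c("g", "count", "g", "%", "grains/spikelet x100", "cm", "count",
              "count", "cm", "days", "days", "%", "%", "ratio", "%", "%/day",
              "cm2 per degC day", "degC", "degC", "degC", "", "", "degC"),
    direction = c("higher_better", "higher_better", "higher_better",
                  "higher_better", "higher_better", "higher_better",
                  "higher_better", "higher_better", "higher_better",
                  "lower_better", "higher_better", "higher_better",
                  "lower_better", "higher_better", "lower_better",
                  "lower_better", "higher_better", "lower_better",
                  "lower_better", "lower_better", "lower_better",
                  "higher_better", "higher_better"),
    description = c("grain yield per plant", "grains per spike",
                    "grain weight per spike", "harvest index",
                    "spike fertility", "spike length", "spikes per plant",
                    "spikelets per spike", "plant height",
                    "days to 50% anthesis", "days to leaf rolling",
                    "relative water content", "excised-leaf water loss",
                    "maximum quantum yield of PSII",
                    "relative cell-membrane injury",
                    "flag-leaf senescence rate", "early vigour index",
                    "canopy temperature", "dry reference temperature",
                    "wet reference temperature", "crop water stress index",
                    "infrared (conductance) index",
                    "canopy temperature depression"))
}

#' @export
print.trait_registry <- function(x, ...) {
  cat("Trait registry with", nrow(x), "traits\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Look up the selection direction of a trait
#'
#' @param registry a [trait_registry()].
#' @param trait trait name(s).
#' @return Character vector of directions.
#' @export
trait_direction <- function(registry, trait) {
  stopifnot(inherits(registry, "trait_registry"))
  idx <- match(trait, registry$trait)
  if (anyNA(idx))
    stop("trait(s) not in registry: ",
         paste(trait[is.na(idx)], collapse = ", "), call. = FALSE)
  registry$direction[idx]
}
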