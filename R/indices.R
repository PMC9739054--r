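#' Excised-leaf water loss
#'
#' Percentage of water lost per unit of initial water content over timed
#' intervals after leaf excision: the leaf is weighed fresh (`fw0`), after
#' four hours (`fw4`), after eight hours (`fw8`) and oven-dry (`dw`).
#' \deqn{ELWL_{0-4} = 100 (FW_0 - FW_4)/(FW_0 - DW)}
#' \deqn{ELWL_{4-8} = 100 (FW_4 - FW_8)/(FW_4 - DW)}
#' \deqn{ELWL_{0-8} = 100 (FW_0 - FW_8)/(FW_0 - DW)}
#'
#' @param fw0,fw4,fw8,dw leaf masses in grams (vectorized).
#' @return Data frame with columns `elwl_0_4`, `elwl_4_8`, `elwl_0_8`
#'   (percent).
#' @export
#' @examples
#' elwl(1.0, 0.8, 0.7, 0.5)   # 40, 33.33, 60
elwl <- function(fw0, fw4, fw8, dw) {
  d04 <- fw0 - dw
  d48 <- fw4 - dw
  if (any(d04 <= 0) || any(d48 <= 0))
    stop("degenerate sample: water content denominators must be positive",
         call. = FALSE)
  data.frame(elwl_0_4 = 100 * (fw0 - fw4) / d04,
             elwl_4_8 = 100 * (fw4 - fw8) / d48,
             elwl_0_8 = 100 * (fw0 - fw8) / d04)
}

#' Relative water content
#'
#' \deqn{RWC = 100 (FW - DW)/(TW - DW)} from fresh, turgid and dry leaf
#' mass.
#'
#' @param fw,tw,dw fresh, turgid and dry mass in grams (vectorized).
#' @return Percent relative water content.
#' @export
#' @examples
#' rwc(0.8, 1.0, 0.2)   # 75
rwc <- function(fw, tw, dw) {
  if (any(tw <= dw))
    stop("degenerate sample: turgid weight must exceed dry weight",
         call. = FALSE)
  100 * (fw - dw) / (tw - dw)
}

#' Maximum quantum yield of photosystem II
#'
#' \deqn{F_v/F_m = (F_m - F_o)/F_m} from dark-adapted minimal (`fo`) and
#' maximal (`fm`) chlorophyll fluorescence.  Values outside (0, 1) are
#' returned with a warning (they indicate a measurement problem, not an
#' arithmetic one).
#'
#' @param fo,fm minimal and maximal fluorescence (arbitrary units).
#' @return The Fv/Fm ratio.
#' @export
#' @examples
#' fv_fm(400, 2000)   # 0.8
fv_fm <- function(fo, fm) {
  if (any(fm <= 0))
    stop("maximal fluorescence must be positive", call. = FALSE)
  if (any(fm <= fo))
    warning("Fm <= Fo: Fv/Fm outside (0, 1)", call. = FALSE)
  (fm - fo) / fm
}

#' Relative cell-membrane injury
#'
#' Membrane thermostability from paired conductivity measurements of
#' heat-treated (`t1`, `t2`) and control (`c1`, `c2`) leaf-disc samples,
#' each read before and after autoclaving:
#' \deqn{RCI = 100 [1 - (1 - T_1/T_2)/(1 - C_1/C_2)]}
#'
#' @param c1,c2 control conductance before/after autoclaving.
#' @param t1,t2 treated conductance before/after autoclaving.
#' @return Percent relative injury.
#' @export
#' @examples
#' rci(c1 = 1, c2 = 10, t1 = 2, t2 = 10)   # 11.11
rci <- function(c1, c2, t1, t2) {
  if (any(c2 <= 0) || any(t2 <= 0))
    stop("post-autoclave conductances must be positive", call. = FALSE)
  if (any(c1 / c2 >= 1))
    stop("degenerate control: C1/C2 must be < 1", call. = FALSE)
  100 * (1 - (1 - t1 / t2) / (1 - c1 / c2))
}

#' Relative flag-leaf senescence rate at maturity
#'
#' Percent loss of relative greenness (SPAD) per day between the
#' after-stress reading and physiological maturity:
#' \deqn{FLS_m = \frac{100 (1 - SPAD_m/SPAD_a)}{days}}
#' where `days` runs from ten days after anthesis to maturity (a
#' genotype-specific input).
#'
#' @param spad_a SPAD reading after stress.
#' @param spad_m SPAD reading at physiological maturity.
#' @param days days from ten days after anthesis to maturity.
#' @return Percent green-area loss per day.
#' @export
#' @examples
#' flsm(50, 25, 50)   # 1 %/day
flsm <- function(spad_a, spad_m, days) {
  if (any(spad_a <= 0))
    stop("degenerate sample: after-stress SPAD must be positive",
         call. = FALSE)
  if (any(days <= 0))
    stop("days to maturity must be positive", call. = FALSE)
  100 * (1 - spad_m / spad_a) / days
}

#' Daily growing degree days
#'
#' `max(0, (t_max + t_min)/2 - base)` per day.  The wheat convention of a
#' 0 degC base temperature is the default.
#'
#' @param t_min,t_max daily minimum and maximum air temperature, degC.
#' @param base base temperature, degC.
#' @return Numeric vector of daily thermal-time increments (degC day).
#' @export
gdd <- function(t_min, t_max, base = 0) {
  if (any(t_max < t_min))
    stop("t_max must be >= t_min", call. = FALSE)
  pmax(0, (t_max + t_min) / 2 - base)
}

#' Phyllochron intervals as sowing-anchored cumulative thermal time
#'
#' The phyllochron interval of leaf *i* is the growing-degree-day sum from
#' sowing through the emergence day of leaf *i*.
#'
#' @param t_min,t_max daily temperature series starting at sowing, degC.
#' @param emergence_days day indices (1-based, within the series) at which
#'   successive leaf tips emerged.
#' @param base base temperature, degC (default 0).
#' @return Numeric vector of cumulative thermal time (degC day) at each
#'   emergence day.
#' @export
#' @examples
#' phyllochron(rep(10, 10), rep(30, 10), emergence_days = c(3, 5, 8))
phyllochron <- function(t_min, t_max, emergence_days, base = 0) {
  if (any(emergence_days < 1) || any(emergence_days > length(t_min)))
    stop("emergence day outside the temperature series", call. = FALSE)
  cum <- cumsum(gdd(t_min, t_max, base))
  cum[emergence_days]
}

#' Early vigour index
#'
#' Combines the areas of the first three leaves with their phyllochron
#' intervals: the vigour index is the summed leaf area divided by the
#' thermal time to third-leaf emergence (area accumulated per unit thermal
#' time); the components are kept so alternative composites can be
#' recomputed.
#'
#' @param areas numeric vector of three leaf areas, cm2.
#' @param intervals numeric vector of three phyllochron intervals,
#'   degC day (cumulative to each leaf's emergence).
#' @return A list with `leaf_areas`, `phyllochron_intervals` and
#'   `vigour_index` (cm2 per degC day).
#' @export
#' @examples
#' early_vigour(c(2, 3, 5), c(40, 70, 100))$vigour_index   # 0.10
early_vigour <- function(areas, intervals) {
  if (length(areas) != 3L || length(intervals) != 3L)
    stop("three leaf areas and three intervals are required", call. = FALSE)
  if (any(areas <= 0) || any(intervals <= 0))
    stop("degenerate record: areas and intervals must be positive",
         call. = FALSE)
  list(leaf_areas = as.numeric(areas),
       phyllochron_intervals = as.numeric(intervals),
       vigour_index = sum(areas) / intervals[3L])
}

#' Harvest index and spike fertility
#'
#' `HI = 100 * GY / AGDM` (grain yield over above-ground dry matter) and
#' spike fertility `SF = grains / spikelets`, reported on the x100 scale
#' conventional in screening tables (so 24 grains over 30 spikelets is
#' SF = 80).
#'
#' @param gy grain yield, g.
#' @param agdm above-ground dry matter, g.
#' @param grains grain count per spike.
#' @param spikelets spikelet count per spike.
#' @param sf_scale multiplier applied to the grains/spikelet ratio
#'   (default 100).
#' @return Data frame with columns `HI` (percent) and `SF`.
#' @export
#' @examples
#' derived_traits(5, 10, 24, 30)   # HI 50, SF 80
derived_traits <- function(gy, agdm, grains, spikelets, sf_scale = 100) {
  if (any(agdm <= 0))
    stop("above-ground dry matter must be positive", call. = FALSE)
  if (any(spikelets <= 0))
    stop("spikelet count must be positive", call. = FALSE)
  data.frame(HI = 100 * gy / agdm,
             SF = sf_scale * grains / spikelets)
}
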