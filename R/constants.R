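#' Segmentation class codes
#'
#' The frozen integer label table used by every mask in the package. Gray
#' level = class code is the public contract for mask PNGs written and read
#' by [write_mask()] / [read_mask()].
#'
#' @return Named integer vector mapping class names to codes 0..9.
#' @export
#' @examples
#' oct_classes()[["lipid"]]
oct_classes <- function() {
  c(
    background  = 0L,  # outside vessel
    lumen       = 1L,
    wall        = 2L,  # normal vessel / fibrous tissue
    lipid       = 3L,
    calcium     = 4L,
    cap         = 5L,  # fibrous cap
    shadow      = 6L,  # guidewire shadow
    bifurcation = 7L,
    catheter    = 8L,  # guide catheter
    stent       = 9L
  )
}

#' Measurement parameter names and fixed units
#'
#' Parameter vocabulary of measurement tables (see [read_measurements()]).
#'
#' @return Named character vector: parameter name -> unit.
#' @export
measurement_units <- function() {
  c(
    lumen_area_mm2  = "mm2",
    lipid_arc_deg   = "deg",
    calcium_arc_deg = "deg",
    fct_min_um      = "um",
    fct_mean_um     = "um"
  )
}

# severity order used for lesion-level classification (worst first)
PLAQUE_SEVERITY <- c("TCFA", "ThCFA", "FIBROCALCIFIC", "PIT", "AIT", "NORMAL")

# risk tiers of the two-step classification
PLAQUE_RISK_TIER <- c(
  NORMAL = "low", AIT = "low", PIT = "low",
  FIBROCALCIFIC = "higher", ThCFA = "higher", TCFA = "higher"
)

REPORT_SCHEMA_VERSION <- "1.0"

# round half away from zero (print-style rounding used for reported
# percentages; base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count, print-style rounding
#'
#' Formats k out of n as a percentage rounded half-up to `digits` decimals,
#' the convention used in clinical tables (e.g. 1140/1218 -> 93.6).
#'
#' @param k count.
#' @param n total.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
#' @examples
#' prop_pct(1140, 1218) # 93.6
prop_pct <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0, k <= n)
  round_half_up(100 * k / n, digits)
}

# run code with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
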