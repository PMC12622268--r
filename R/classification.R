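# Two-step rule-based plaque classification and diagnostic comparison.
#
# Step 1 separates low-risk (NORMAL, AIT, PIT) from higher-risk
# (FIBROCALCIFIC, ThCFA, TCFA) segments; step 2 refines higher-risk classes
# from plaque-component measurements. Only the 75 um thin-cap threshold is a
# fixed clinical constant; the remaining thresholds are configurable
# consensus-style defaults.

#' Classification thresholds
#'
#' @param tcfa_fct_um thin-cap threshold; fixed at 75 um (strict `<`).
#' @param fibroatheroma_min_lipid_arc_deg minimal maximal lipid arc for a
#'   fibroatheroma (default 90).
#' @param fibrocalcific_min_calcium_arc_deg minimal maximal calcium arc for a
#'   fibrocalcific plaque (default 90).
#' @param pit_min_intima_um intimal thickness from which thickening is
#'   pathological rather than adaptive-only (default 300).
#' @param ait_max_intima_um upper intimal thickness still compatible with
#'   adaptive thickening (default 600).
#' @return list of parameters.
#' @export
classification_params <- function(tcfa_fct_um = 75,
                                  fibroatheroma_min_lipid_arc_deg = 90,
                                  fibrocalcific_min_calcium_arc_deg = 90,
                                  pit_min_intima_um = 300,
                                  ait_max_intima_um = 600) {
  if (tcfa_fct_um != 75) {
    stop("the thin-cap threshold is a fixed clinical constant (75 um)")
  }
  list(tcfa_fct_um = tcfa_fct_um,
       fibroatheroma_min_lipid_arc_deg = fibroatheroma_min_lipid_arc_deg,
       fibrocalcific_min_calcium_arc_deg = fibrocalcific_min_calcium_arc_deg,
       pit_min_intima_um = pit_min_intima_um,
       ait_max_intima_um = ait_max_intima_um)
}

#' Risk tier of a plaque class
#' @param class character vector of plaque classes.
#' @return `"low"` or `"higher"` per class.
#' @export
plaque_risk_tier <- function(class) {
  unname(PLAQUE_RISK_TIER[class])
}

#' Classify one frame
#'
#' Decision cascade (first match wins):
#' 1. maximal lipid arc >= fibroatheroma threshold and FCT defined:
#'    TCFA if FCT_min < 75 um (strict), else ThCFA;
#' 2. maximal calcium arc >= fibrocalcific threshold: FIBROCALCIFIC;
#' 3. any lipid (total arc > 0): PIT;
#' 4. intimal thickness >= PIT threshold: AIT if <= AIT ceiling, else PIT;
#' 5. otherwise NORMAL.
#'
#' @param m one-row data.frame of frame measurements ([measure_frame()]).
#' @param intima_thickness_um intimal thickness for the AIT/PIT branch
#'   (NA when unknown).
#' @param params [classification_params()].
#' @return character plaque class, or NA for unanalyzable frames.
#' @export
classify_frame <- function(m, intima_thickness_um = NA_real_,
                           params = classification_params()) {
  if (!isTRUE(m$analyzable)) return(NA_character_)
  lipid_max <- if (is.na(m$lipid_arc_deg_max)) 0 else m$lipid_arc_deg_max
  lipid_total <- if (is.na(m$lipid_arc_deg_total)) 0 else m$lipid_arc_deg_total
  calcium_max <- if (is.na(m$calcium_arc_deg_max)) 0 else m$calcium_arc_deg_max
  fct <- m$fct_min_um
  if (lipid_max >= params$fibroatheroma_min_lipid_arc_deg && !is.na(fct)) {
    return(if (fct < params$tcfa_fct_um) "TCFA" else "ThCFA")
  }
  if (calcium_max >= params$fibrocalcific_min_calcium_arc_deg) {
    return("FIBROCALCIFIC")
  }
  if (lipid_total > 0) return("PIT")
  if (!is.na(intima_thickness_um) &&
      intima_thickness_um >= params$pit_min_intima_um) {
    return(if (intima_thickness_um <= params$ait_max_intima_um) "AIT" else "PIT")
  }
  "NORMAL"
}

#' Lesion-level class: worst member frame
#'
#' Severity order TCFA > ThCFA > FIBROCALCIFIC > PIT > AIT > NORMAL.
#'
#' @param classes character vector of member-frame classes (NAs dropped).
#' @return character plaque class.
#' @export
classify_lesion <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0) stop("empty lesion: no classified member frames")
  bad <- setdiff(classes, PLAQUE_SEVERITY)
  if (length(bad)) stop("unknown plaque class: ", paste(bad, collapse = ", "))
  PLAQUE_SEVERITY[min(match(classes, PLAQUE_SEVERITY))]
}

#' Confusion matrix and per-class diagnostic performance
#'
#' @param pred,truth aligned character vectors of plaque classes.
#' @param levels class levels (default: all severity levels present).
#' @return list: `confusion` (truth in rows, prediction in columns),
#'   `per_class` data.frame (sensitivity, specificity, PPV, NPV, accuracy per
#'   class, NA where a denominator is zero), `accuracy` (overall), and
#'   `risk_tier_accuracy` (binary low/higher-risk agreement).
#' @export
compare_classifications <- function(pred, truth, levels = NULL) {
  if (length(pred) != length(truth)) {
    stop("pred and truth have different lengths")
  }
  if (is.null(levels)) {
    levels <- PLAQUE_SEVERITY[PLAQUE_SEVERITY %in% c(pred, truth)]
    if (length(levels) == 0) levels <- sort(unique(c(pred, truth)))
  }
  pred <- factor(pred, levels = levels)
  truth <- factor(truth, levels = levels)
  cm <- table(truth = truth, pred = pred)
  per <- lapply(levels, function(cl) {
    dp <- diagnostic_performance(pred == cl, truth == cl)
    data.frame(class = cl, sensitivity = dp$sensitivity,
               specificity = dp$specificity, ppv = dp$ppv, npv = dp$npv,
               accuracy = dp$accuracy)
  })
  tier_acc <- if (all(c(pred, truth) %in% names(PLAQUE_RISK_TIER))) {
    mean(plaque_risk_tier(as.character(pred)) ==
           plaque_risk_tier(as.character(truth)))
  } else {
    NA_real_
  }
  list(confusion = cm, per_class = do.call(rbind, per),
       accuracy = mean(as.character(pred) == as.character(truth)),
       risk_tier_accuracy = tier_acc)
}

#' Class composition of a set of frames or lesions
#'
#' Counts and print-style percentages (one decimal, half-up) per class —
#' the tabulation used for reporting cohort composition.
#'
#' @param classes character vector.
#' @param levels optional class ordering.
#' @return data.frame with `class`, `n`, `pct`.
#' @export
class_composition <- function(classes, levels = NULL) {
  if (is.null(levels)) levels <- unique(classes)
  n <- vapply(levels, function(cl) sum(classes == cl), 0L)
  data.frame(class = levels, n = n,
             pct = prop_pct(n, length(classes)), row.names = NULL)
}
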