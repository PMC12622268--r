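# End-to-end pullback analysis: gating -> artifact correction ->
# (provided masks | rule-based segmentation) -> morphometry ->
# classification -> lesions -> risk flags -> report.

#' Analysis run configuration
#'
#' @param correct_artifacts run histogram-matching artifact correction.
#' @param artifact [artifact_params()].
#' @param classification [classification_params()].
#' @param gap_tolerance_frames lesion gap bridging (frames).
#' @param min_frames minimum lesion length.
#' @param n_angles angular measurement bins.
#' @param stent_gap_fill propagate gating across single-frame gaps inside
#'   catheter/stent runs.
#' @param seed run seed (recorded; the pipeline itself is deterministic).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(correct_artifacts = TRUE,
                            artifact = artifact_params(),
                            classification = classification_params(),
                            gap_tolerance_frames = 2, min_frames = 1,
                            n_angles = 360, stent_gap_fill = TRUE, seed = 1) {
  structure(list(correct_artifacts = correct_artifacts, artifact = artifact,
                 classification = classification,
                 gap_tolerance_frames = gap_tolerance_frames,
                 min_frames = min_frames, n_angles = n_angles,
                 stent_gap_fill = stent_gap_fill, seed = seed),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- analysis_config()
  cfg[names(raw)] <- raw
  for (nm in c("artifact", "classification")) {
    if (!is.null(raw[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
    }
  }
  cfg
}

#' @rdname read_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# catheter/stent gating from flags and mask classes, with single-frame
# gap fill inside gated runs
gate_frames <- function(pullback, masks, stent_gap_fill = TRUE) {
  gated <- pullback$frame_flags$in_guide_catheter | pullback$frame_flags$in_stent
  if (!is.null(masks)) {
    cls <- oct_classes()
    from_mask <- vapply(masks, function(m) {
      any(m == cls[["catheter"]]) || any(m == cls[["stent"]])
    }, TRUE)
    gated <- gated | from_mask
  }
  if (stent_gap_fill && length(gated) >= 3) {
    n <- length(gated)
    fill <- !gated & c(FALSE, gated[-n]) & c(gated[-1], FALSE)
    gated <- gated | fill
  }
  gated
}

#' Analyze a pullback end to end
#'
#' Runs the full measurement pipeline and returns a classed result holding
#' the per-frame table (with plaque classes), the lesion table (with lesion
#' classes and risk flags), the corrected frames, detected artifact regions,
#' excluded frame indices, per-stage timings, and the configuration.
#'
#' @param pullback an `oct_pullback`.
#' @param masks optional list of class-code matrices; when absent, frames are
#'   segmented with the rule-based intensity segmenter
#'   ([segment_frame_rules()]) after correction.
#' @param config an [analysis_config()].
#' @return object of class `oct_analysis`.
#' @export
analyze_pullback <- function(pullback, masks = NULL,
                             config = analysis_config()) {
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  stage <- function(name, expr) {
    t <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timing[[name]] <<- proc.time()[["elapsed"]] - t
    out
  }

  gated <- stage("gating", gate_frames(pullback, masks, config$stent_gap_fill))
  pb <- pullback
  pb$frame_flags$in_stent <- pb$frame_flags$in_stent |
    (gated & !pb$frame_flags$in_guide_catheter)

  regions <- vector("list", n_frames(pb))
  applied <- logical(n_frames(pb))
  if (config$correct_artifacts && !is.null(masks)) {
    corr <- stage("artifact_correction",
                  correct_pullback(pb, masks, config$artifact))
    pb <- corr$pullback
    regions <- corr$regions
    applied <- corr$correction_applied
  }

  if (is.null(masks)) {
    masks <- stage("segmentation", lapply(seq_len(n_frames(pb)), function(i) {
      if (gated[i]) {
        matrix(oct_classes()[["background"]], nrow = dim(pb$frames)[2],
               ncol = dim(pb$frames)[3])
      } else {
        segment_frame_rules(get_frame(pb, i))
      }
    }))
    if (config$correct_artifacts) {
      corr <- stage("artifact_correction",
                    correct_pullback(pb, masks, config$artifact))
      pb <- corr$pullback
      regions <- corr$regions
      applied <- corr$correction_applied
      # labels are never histogram-matched: re-segment corrected frames
      masks <- stage("resegmentation",
                     lapply(seq_len(n_frames(pb)), function(i) {
                       if (gated[i] || !applied[i]) {
                         masks[[i]]
                       } else {
                         segment_frame_rules(get_frame(pb, i))
                       }
                     }))
    }
  }

  fm <- stage("morphometry",
              measure_pullback(pb, masks, n_angles = config$n_angles))
  fm$plaque_class <- vapply(seq_len(nrow(fm)), function(i) {
    cl <- classify_frame(fm[i, ], params = config$classification)
    if (is.null(cl)) NA_character_ else cl
  }, "")

  lesions <- stage("lesions",
                   segment_lesions(fm, config$gap_tolerance_frames,
                                   config$min_frames))
  if (nrow(lesions) > 0) {
    lesions$plaque_class <- vapply(seq_len(nrow(lesions)), function(k) {
      member <- fm$plaque_class[fm$frame_index >= lesions$first_frame[k] &
                                  fm$frame_index <= lesions$last_frame[k] &
                                  fm$analyzable]
      classify_lesion(member)
    }, "")
    fl <- lapply(seq_len(nrow(lesions)), function(k) {
      as.data.frame(risk_flags(lesions[k, ]))
    })
    lesions <- cbind(lesions, do.call(rbind, fl))
  }

  timing[["total"]] <- proc.time()[["elapsed"]] - t0
  structure(list(frames = fm, lesions = lesions, masks = masks,
                 corrected = pb, regions = regions,
                 correction_applied = applied,
                 excluded_frames = which(gated), config = config,
                 timing = unlist(timing)),
            class = "oct_analysis")
}

#' @export
print.oct_analysis <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("OCT analysis: %d frames (%d excluded in catheter/stent), %d lesion(s)\n",
              n, length(x$excluded_frames), nrow(x$lesions)))
  if (nrow(x$lesions) > 0) {
    for (k in seq_len(nrow(x$lesions))) {
      l <- x$lesions[k, ]
      cat(sprintf("  lesion %d: frames %d-%d, %s, MLA %.2f mm2, max lipid arc %.0f deg, FCT_min %s um\n",
                  k, l$first_frame, l$last_frame, l$plaque_class, l$mla_mm2,
                  l$max_lipid_arc_deg,
                  if (is.na(l$fct_min_um)) "n/a" else sprintf("%.0f", l$fct_min_um)))
    }
  }
  invisible(x)
}

#' @export
summary.oct_analysis <- function(object, ...) {
  fm <- object$frames[object$frames$analyzable, ]
  cat(sprintf("analyzable frames: %d / %d\n", nrow(fm), nrow(object$frames)))
  if (nrow(fm) > 0) {
    cat(sprintf("pullback MLA: %.2f mm2\n", min(fm$lumen_area_mm2)))
    cat(sprintf("max lipid arc: %.0f deg; max calcium arc: %.0f deg\n",
                max(fm$lipid_arc_deg_max), max(fm$calcium_arc_deg_max)))
    if (any(!is.na(fm$fct_min_um))) {
      cat(sprintf("FCT_min: %.0f um\n", min(fm$fct_min_um, na.rm = TRUE)))
    }
    comp <- class_composition(fm$plaque_class[!is.na(fm$plaque_class)])
    cat("frame classes:\n")
    print(comp)
  }
  cat(sprintf("artifact correction applied on %d frame(s)\n",
              sum(object$correction_applied)))
  invisible(object)
}

#' @export
plot.oct_analysis <- function(x, ...) {
  fm <- x$frames
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(fm$frame_index, fm$lumen_area_mm2, type = "b",
                 xlab = "frame", ylab = "lumen area (mm2)", ...)
  graphics::abline(h = 3.5, lty = 2)
  graphics::plot(fm$frame_index, fm$lipid_arc_deg_max, type = "b",
                 xlab = "frame", ylab = "max lipid arc (deg)", ...)
  graphics::abline(h = 180, lty = 2)
  invisible(x)
}

#' Write the report files of an analysis
#'
#' @param analysis an `oct_analysis`.
#' @param path JSON report path (CSV twins derive from its stem).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(analysis, path, format = c("json", "csv")) {
  write_report(analysis$frames, analysis$lesions, path, format = format,
               config = unclass(analysis$config),
               excluded_frames = analysis$excluded_frames)
}
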