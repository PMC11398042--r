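#' Background-artifact plan of the synthetic cohort
#'
#' Which limbs carry hair-like background clutter, at what severity, and at
#' which presets/steps. The default nine-limb plan mirrors the observed
#' clinical pattern: four clean limbs, two with mild, one with moderate and
#' two with severe clutter; clutter appears only at the three presets whose
#' relative-density ranges are shifted toward low HU (60 kV; 12 mAs,
#' 70 kV; 1.2 mAs, 80 kV; 1.2 mAs), because only there does hair-range gray
#' coincide with the low wedge steps. Mild clutter arises only at the two
#' high-kV presets; moderate and severe also at 60 kV; 12 mAs, where one
#' fewer step is reached than at high kV.
#'
#' @param n_limbs Number of limbs (subjects); default 9.
#' @return Data frame with columns `limb` and `severity`
#'   (`"none"`, `"mild"`, `"moderate"`, `"severe"`).
#' @export
study_artifact_plan <- function(n_limbs = 9) {
  sev <- rep("none", n_limbs)
  if (n_limbs >= 9) sev[3:7] <- c("mild", "mild", "moderate", "severe", "severe")
  data.frame(limb = seq_len(n_limbs), severity = sev)
}

# Steps targeted by clutter for a given severity and preset.
.clutter_steps <- function(severity, exposure) {
  shifted_high <- exposure$kv >= 70
  high_mas <- exposure$mas > 1.2
  if (!shifted_high && !high_mas) return(integer(0))
  switch(severity,
    none = integer(0),
    mild = if (shifted_high) 1L else integer(0),
    moderate = if (shifted_high) 1:2 else 1L,
    severe = if (shifted_high) 1:3 else 1:2
  )
}

#' Generate the synthetic study cohort
#'
#' Renders one radiograph per limb and tube setting (default: nine limbs
#' across the five study presets), with mild per-limb anatomical variation
#' (bone thickness and limb size jitter) and background clutter injected
#' according to the artifact plan. Fully deterministic given `seed`.
#'
#' @param n_limbs Number of limbs.
#' @param presets List of [exposure_setting()]s; default [study_presets()].
#' @param model A [phantom_model()].
#' @param wedge A [wedge_spec()].
#' @param seed Integer master seed; per-radiograph seeds are derived from it.
#' @param size Image size `c(rows, cols)`.
#' @param artifact_plan As [study_artifact_plan()].
#' @return A list of class `cda_cohort`; each element has fields `limb`,
#'   `setting`, `severity`, `rad`.
#' @export
generate_cohort <- function(n_limbs = 9, presets = study_presets(),
                            model = phantom_model(), wedge = wedge_spec(),
                            seed = 1, size = c(512, 512),
                            artifact_plan = study_artifact_plan(n_limbs)) {
  jitter <- with_seed(derive_seed(seed, 999), {
    data.frame(bone = stats::runif(n_limbs, 0.9, 1.1),
               size = stats::runif(n_limbs, 0.95, 1.05))
  })
  out <- list()
  for (i in seq_len(n_limbs)) {
    tissue <- knee_tissue_spec(bone_scale = jitter$bone[i],
                               size_scale = jitter$size[i])
    severity <- artifact_plan$severity[artifact_plan$limb == i]
    for (j in seq_along(presets)) {
      exp <- presets[[j]]
      rad <- render_radiograph(
        wedge, tissue, exp, model,
        seed = derive_seed(seed, i, j), size = size,
        source_id = sprintf("limb%02d", i)
      )
      steps <- .clutter_steps(severity, exp)
      if (length(steps) > 0) {
        rad <- add_background_clutter(rad, severity,
                                      seed = derive_seed(seed, i, j, 7),
                                      steps = steps)
      }
      out[[length(out) + 1]] <- list(limb = i, setting = exp$label,
                                     severity = severity, rad = rad)
    }
  }
  structure(out, class = "cda_cohort", seed = seed)
}

#' @export
print.cda_cohort <- function(x, ...) {
  cat("<cda_cohort>", length(x), "radiographs,",
      length(unique(vapply(x, `[[`, integer(1), "limb"))), "limbs x",
      length(unique(vapply(x, `[[`, character(1), "setting"))), "settings\n")
  invisible(x)
}
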