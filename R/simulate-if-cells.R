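#' Simulate per-cell immunofluorescence intensity tables
#'
#' Generates a per-cell table of NANOG, GATA6, CDX2 and DAPI intensities for
#' embryos cultured under different treatments, emulating quantified
#' whole-mount immunofluorescence of late blastocysts. Each cell belongs to a
#' planted lineage class (`NANOG-only`, `GATA6-only`, `coexpressing`,
#' `double-negative`); intensities are drawn log-normal around class-specific
#' channel means, with a per-embryo intensity multiplier shared by all
#' channels (cancelled by DAPI normalization downstream) and per-embryo jitter
#' of class proportions. Treatments may shift class proportions and/or scale
#' channel means.
#'
#' The default treatments and effects emulate a lineage-segregation inhibitor
#' experiment: an ERK-inhibited arm (`PD03`) with an expanded NANOG-only
#' epiblast compartment and suppressed GATA6-only primitive endoderm, and a
#' WNT-inhibited arm (`IWP2`) with suppressed GATA6-only cells and an enlarged
#' NANOG-positive (hence NANOG-high) compartment, against a `DMSO` control.
#'
#' @param n_embryos_per_treatment Embryos per treatment arm (> 0).
#' @param cells_per_embryo Cells per embryo (> 0).
#' @param treatments Character vector of treatment labels.
#' @param effects Named list (by treatment) of effect descriptors, each a list
#'   with optional elements `props` (full replacement class-proportion vector,
#'   names as in `base_props`) and `mean_mult` (named channel multipliers, any
#'   of `NANOG`, `GATA6`, `CDX2`, `DAPI`). Unlisted treatments get the control
#'   settings.
#' @param base_props Control lineage-class proportions (sum to 1).
#' @param channel_means Base intensities: `positive` and `negative` marker
#'   levels and `dapi`.
#' @param intensity_log_sd Log-normal spread of per-cell intensities.
#' @param prop_concentration Dirichlet concentration controlling per-embryo
#'   proportion jitter (larger = less jitter).
#' @param seed Integer seed.
#' @return A tibble (class `cell_intensity_table`) with columns `cell_id`,
#'   `embryo_id`, `treatment`, `nanog`, `gata6`, `cdx2`, `dapi` and the ground
#'   truth column `true_class`; attribute `effects` records the planted
#'   effects.
#' @export
simulate_if_cells <- function(n_embryos_per_treatment = 8,
                              cells_per_embryo = 60,
                              treatments = c("DMSO", "PD03", "IWP2"),
                              effects = default_if_effects(),
                              base_props = c(nanog_only = 0.15,
                                             gata6_only = 0.32,
                                             coexpressing = 0.05,
                                             double_negative = 0.48),
                              channel_means = c(positive = 900,
                                                negative = 40,
                                                dapi = 1000),
                              intensity_log_sd = 0.3,
                              prop_concentration = 150,
                              seed = 1L) {
  if (n_embryos_per_treatment < 1 || cells_per_embryo < 1) {
    abort("Embryo and cell counts must be positive.")
  }
  classes <- c("nanog_only", "gata6_only", "coexpressing", "double_negative")
  if (!setequal(names(base_props), classes)) {
    abort("`base_props` must name exactly the four lineage classes.")
  }
  base_props <- base_props[classes] / sum(base_props)
  channels <- c("NANOG", "GATA6", "CDX2", "DAPI")
  for (trt in names(effects)) {
    ef <- effects[[trt]]
    if (!is.null(ef$mean_mult) &&
        !all(names(ef$mean_mult) %in% channels)) {
      bad <- setdiff(names(ef$mean_mult), channels)
      abort(paste0("Unknown channel in `effects`: ",
                   paste(bad, collapse = ", ")))
    }
    if (!is.null(ef$props) && !setequal(names(ef$props), classes)) {
      abort("Effect `props` must name exactly the four lineage classes.")
    }
  }
  set.seed(seed)
  # positivity of each marker by class
  pos_n <- c(nanog_only = TRUE, gata6_only = FALSE, coexpressing = TRUE,
             double_negative = FALSE)
  pos_g <- c(nanog_only = FALSE, gata6_only = TRUE, coexpressing = TRUE,
             double_negative = FALSE)
  rows <- list()
  for (trt in treatments) {
    ef <- effects[[trt]]
    props <- if (!is.null(ef$props)) ef$props[classes] / sum(ef$props) else base_props
    mult <- setNames(rep(1, 4), channels)
    if (!is.null(ef$mean_mult)) mult[names(ef$mean_mult)] <- ef$mean_mult
    for (e in seq_len(n_embryos_per_treatment)) {
      embryo_id <- sprintf("%s_e%02d", trt, e)
      # per-embryo proportion jitter (Dirichlet via gamma draws)
      g <- rgamma(4, shape = props * prop_concentration, rate = 1)
      p_embryo <- g / sum(g)
      cls <- sample(classes, cells_per_embryo, replace = TRUE,
                    prob = p_embryo)
      embryo_scale <- rlnorm(1, 0, 0.15)   # shared by all channels
      draw <- function(level, channel) {
        rlnorm(cells_per_embryo,
               log(level * mult[channel] * embryo_scale),
               intensity_log_sd)
      }
      nanog <- draw(ifelse(pos_n[cls], channel_means["positive"],
                           channel_means["negative"]), "NANOG")
      gata6 <- draw(ifelse(pos_g[cls], channel_means["positive"],
                           channel_means["negative"]), "GATA6")
      cdx2 <- draw(rep(channel_means["negative"], cells_per_embryo), "CDX2")
      dapi <- draw(rep(channel_means["dapi"], cells_per_embryo), "DAPI")
      rows[[length(rows) + 1L]] <- tibble(
        cell_id = sprintf("%s_c%03d", embryo_id, seq_len(cells_per_embryo)),
        embryo_id = embryo_id, treatment = trt,
        nanog = nanog, gata6 = gata6, cdx2 = cdx2, dapi = dapi,
        true_class = cls)
    }
  }
  out <- bind_rows(rows)
  out$treatment <- factor(out$treatment, levels = treatments)
  class(out) <- c("cell_intensity_table", class(out))
  attr(out, "effects") <- effects
  out
}

#' Default planted treatment effects for the immunofluorescence simulator
#'
#' Control (`DMSO`) uses the base class proportions. `PD03` (ERK inhibition)
#' expands NANOG-only cells and suppresses GATA6-only cells; `IWP2` (WNT
#' inhibition) suppresses GATA6-only cells and expands the NANOG-positive
#' compartment, which raises the fraction of NANOG-high cells under the
#' 1.5-times-embryo-mean rule.
#'
#' @return Named list of effect descriptors, see [simulate_if_cells()].
#' @export
default_if_effects <- function() {
  list(
    DMSO = list(),
    PD03 = list(props = c(nanog_only = 0.40, gata6_only = 0.10,
                          coexpressing = 0.08, double_negative = 0.42)),
    IWP2 = list(props = c(nanog_only = 0.24, gata6_only = 0.08,
                          coexpressing = 0.16, double_negative = 0.52))
  )
}
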