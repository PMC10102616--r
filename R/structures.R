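# Default roster of 66 cortical and subcortical structures for the
# regional (secondary) analysis, with typical adolescent/young-adult
# volumes in mL used as synthetic-data baselines. The roster mirrors a
# FreeSurfer-style segmentation: bilateral subcortical nuclei, bilateral
# cerebellar cortex/white matter, brainstem, five corpus-callosum
# segments, bilateral lobar gray and white matter, and eight bilateral
# cortical parcels.

.structure_baselines <- function() {
  bilat <- function(base, vols) {
    v <- rep(vols, 2L)
    names(v) <- c(paste0("left_", names(vols)), paste0("right_", names(vols)))
    v
  }
  subcortical <- c(thalamus = 7.5, caudate = 3.6, putamen = 5.0,
                   pallidum = 1.8, hippocampus = 4.2, amygdala = 1.7,
                   accumbens = 0.6, ventral_dc = 4.0)
  cerebellum <- c(cerebellum_cortex = 52, cerebellum_wm = 14)
  lobar_gm <- c(frontal_gm = 80, parietal_gm = 55, temporal_gm = 55,
                occipital_gm = 35, cingulate_gm = 13, insula = 7)
  lobar_wm <- c(frontal_wm = 70, parietal_wm = 50, temporal_wm = 40,
                occipital_wm = 25, cingulate_wm = 10, insula_wm = 5)
  parcels <- c(entorhinal = 1.8, parahippocampal = 2.1, fusiform = 9.5,
               precuneus = 9.8, lingual = 7.5, pericalcarine = 2.2,
               cuneus = 3.5, lateral_orbitofrontal = 7.8)
  cc <- c(cc_anterior = 0.9, cc_mid_anterior = 0.5, cc_central = 0.5,
          cc_mid_posterior = 0.5, cc_posterior = 0.9)
  c(bilat(vols = subcortical), bilat(vols = cerebellum),
    brainstem = 21, cc,
    bilat(vols = lobar_gm), bilat(vols = lobar_wm), bilat(vols = parcels))
}

#' Default regional structure roster
#'
#' Names of the 66 cortical and subcortical structures used by the
#' secondary regional analysis and generated by the synthetic cohort.
#'
#' @return Character vector of 66 structure names.
#' @export
default_structures <- function() {
  names(.structure_baselines())
}
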