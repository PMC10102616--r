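# Forward simulation of single-PLD pCASL studies with known CBF ground
# truth: simple labeled-block grids, a smooth positive M0 field, and a
# difference series whose noiseless repeat mean equals the kinetic
# forward model exactly, plus optional Gaussian noise and linear drift.

#' Simple labeled voxel grid for synthetic ASL studies
#'
#' Partitions a block grid into a GM half and a WM half along the first
#' axis. No attempt is made at realistic brain geometry; the grid exists
#' to exercise the voxelwise quantification path and mask bookkeeping.
#'
#' @param dim Integer length-3 grid dimensions (first dimension >= 2).
#' @return List with `dim`, and logical `gm`, `wm` arrays partitioning
#'   the grid.
#' @export
asl_grid <- function(dim = c(8L, 8L, 4L)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L) || dim[1] < 2L)
    stop("`dim` must be three positive integers with dim[1] >= 2", call. = FALSE)
  xs <- slice.index(array(0, dim), 1)
  gm <- xs <= dim[1] %/% 2
  list(dim = dim, gm = gm, wm = !gm)
}

#' Simulate an ASL study with known ground-truth CBF
#'
#' Forward-evaluates the single-compartment kinetic model on a labeled
#' grid to produce an M0 volume, a repeat series of label-control
#' differences and GM/WM masks. The noiseless mean of the series equals
#' the forward-model difference signal voxel for voxel (GM parameters in
#' GM voxels, WM parameters in WM voxels), so quantification of a
#' noiseless study must return the generating CBF to machine precision.
#' Gaussian noise of SD `noise_sd` is added independently per voxel and
#' repeat; `drift` adds a linear baseline trend across repeats (signal
#' units per repeat, mean-centered so the series mean is unchanged only
#' when `drift = 0`).
#'
#' @param participant Optional single row of an [generate_cohort()]
#'   cohort; supplies `group`, `hematocrit` and `true_gm_cbf` (WM truth
#'   defaults to 0.49 x GM, the study-typical WM/GM perfusion ratio).
#' @param protocol An [asl_protocol()].
#' @param grid An [asl_grid()].
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed Integer seed (required when `noise_sd > 0` or
#'   `drift != 0`).
#' @param drift Linear drift amplitude, signal units per repeat.
#' @param cbf_gm,cbf_wm Ground-truth CBF (ml/100 g/min), overriding the
#'   participant values; either scalars or full 3-D arrays.
#' @param hct,group Used to resolve default [quant_params()] when
#'   explicit parameter objects are not given.
#' @param gm_params,wm_params Explicit [quant_params()] overrides.
#' @param m0_scale Mean level of the M0 field, signal units.
#' @return A list: the [asl_study()], the resolved parameter objects and
#'   the ground-truth CBF field (`truth`).
#' @export
generate_asl_study <- function(participant = NULL, protocol = asl_protocol(),
                               grid = asl_grid(), noise_sd = 0, seed = NULL,
                               drift = 0, cbf_gm = NULL, cbf_wm = NULL,
                               hct = NULL, group = NULL,
                               gm_params = NULL, wm_params = NULL,
                               m0_scale = 1000) {
  if (!is.null(participant)) {
    stopifnot(nrow(participant) == 1L)
    if (is.null(group)) group <- participant$group
    if (is.null(hct)) hct <- participant$hematocrit
    if (is.null(cbf_gm)) cbf_gm <- participant$true_gm_cbf
  }
  if (is.null(cbf_gm)) stop("ground-truth `cbf_gm` is required", call. = FALSE)
  if (is.null(cbf_wm)) cbf_wm <- 0.49 * cbf_gm
  if (is.null(gm_params))
    gm_params <- quant_params("GM", group = group, hct = hct)
  if (is.null(wm_params))
    wm_params <- quant_params("WM", group = group, hct = hct)
  if ((noise_sd > 0 || drift != 0) && is.null(seed))
    stop("`seed` is required for noisy or drifting simulations", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)

  d <- grid$dim
  # deterministic smooth positive M0 field (coil-sensitivity-like bowl)
  ax <- function(k) cos(seq(-0.6, 0.6, length.out = d[k]))
  m0 <- m0_scale * (0.8 + 0.2 * outer(outer(ax(1), ax(2)), ax(3)))
  dim(m0) <- d

  truth <- array(0, d)
  truth[grid$gm] <- if (length(cbf_gm) == 1L) cbf_gm else cbf_gm[grid$gm]
  truth[grid$wm] <- if (length(cbf_wm) == 1L) cbf_wm else cbf_wm[grid$wm]

  dm <- array(0, d)
  dm[grid$gm] <- forward_delta_m(truth[grid$gm], m0[grid$gm], protocol, gm_params)
  dm[grid$wm] <- forward_delta_m(truth[grid$wm], m0[grid$wm], protocol, wm_params)

  nt <- protocol$averages
  series <- array(rep(dm, nt), c(d, nt))
  if (drift != 0) {
    tc <- seq_len(nt) - (nt + 1) / 2
    series <- series + rep(drift * tc, each = prod(d))
  }
  if (noise_sd > 0 || drift != 0) {
    series <- with_preserved_seed(seed, {
      if (noise_sd > 0)
        series + array(stats::rnorm(length(series), 0, noise_sd), dim(series))
      else series
    })
  }
  study <- asl_study(m0 = m0, diff_series = series,
                     gm_mask = grid$gm, wm_mask = grid$wm)
  list(study = study, gm_params = gm_params, wm_params = wm_params,
       protocol = protocol, truth = truth)
}
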