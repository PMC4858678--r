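#' Configuration for the synthetic TF-induction experiment
#'
#' Bundles every knob of the synthetic-data generators. The defaults describe
#' a small but realistic screen: each TF line is profiled in three induced and
#' three control replicate wells, about 5% of genes respond to a given TF, and
#' planted effect sizes exceed the 1.5-fold calling threshold so the truth is
#' recoverable.
#'
#' @param n_genes Number of genes on the array.
#' @param n_tfs Number of inducible TF lines.
#' @param reps_per_condition Replicate wells per condition (induced/control).
#' @param frac_affected Fraction of genes with a true effect per TF.
#' @param effect_loc Mean absolute planted effect on the log10 scale; must
#'   exceed `effect_floor` because magnitudes are drawn as
#'   `effect_floor + Exponential`, guaranteeing planted effects clear the
#'   fold threshold.
#' @param effect_floor Minimum absolute planted effect (log10); default
#'   `log10(1.5)`, the responder fold threshold. Set to `log10(2)` to plant
#'   effects that are all at least 2-fold.
#' @param noise_sd Replicate noise SD on the log10 scale.
#' @param n_tissues Number of tissues in the synthetic atlas; must be at least
#'   `n_tfs` so every TF can be aligned with a distinct tissue.
#' @param atlas_reps Replicates per tissue in the atlas.
#' @param alignment_strength Multiplier mapping a TF's planted effects onto
#'   its aligned tissue's expression shifts; 0 removes the alignment.
#' @param frac_marker Fraction of genes acting as markers of each unaligned
#'   tissue (gives the atlas its own significant genes).
#' @param frac_bound Fraction of a TF's upregulated effect genes that receive
#'   a planted ChIP-seq peak.
#' @param n_peak_samples Number of replicate peak samples; planted peaks occur
#'   in every sample, decoys in a single sample each.
#' @param peak_width_bp Width of simulated peaks in bp.
#' @param promoter_frac Fraction of planted peaks placed < 500 bp from the
#'   TSS (the rest are placed in the 500 bp - 50 kb enhancer band).
#' @param seed Integer seed; all generators derive their streams from it, so
#'   identical configurations give byte-identical outputs.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, n_tfs = 2, seed = 7)
sim_config <- function(n_genes = 2000, n_tfs = 4, reps_per_condition = 3,
                       frac_affected = 0.05, effect_loc = log10(2),
                       effect_floor = log10(1.5),
                       noise_sd = 0.05, n_tissues = n_tfs + 2, atlas_reps = 3,
                       alignment_strength = 1.5, frac_marker = 0.05,
                       frac_bound = 0.5, n_peak_samples = 3,
                       peak_width_bp = 400, promoter_frac = 0.5, seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_tfs = n_tfs, reps_per_condition = reps_per_condition,
    frac_affected = frac_affected, effect_loc = effect_loc,
    effect_floor = effect_floor, noise_sd = noise_sd, n_tissues = n_tissues, atlas_reps = atlas_reps,
    alignment_strength = alignment_strength, frac_marker = frac_marker,
    frac_bound = frac_bound, n_peak_samples = n_peak_samples,
    peak_width_bp = peak_width_bp, promoter_frac = promoter_frac,
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_tfs", "reps_per_condition", "n_tissues",
              "atlas_reps", "n_peak_samples", "peak_width_bp")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1) {
      abort(sprintf("Invalid sim_config: `%s` must be a count >= 1.", f))
    }
  }
  fracs <- c("frac_affected", "frac_marker", "frac_bound", "promoter_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      abort(sprintf("Invalid sim_config: `%s` must be a fraction in [0, 1].", f))
    }
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort("Invalid sim_config: `noise_sd` must be > 0.")
  }
  if (cfg$effect_floor < 0) {
    abort("Invalid sim_config: `effect_floor` must be >= 0.")
  }
  if (cfg$effect_loc <= cfg$effect_floor) {
    abort("Invalid sim_config: `effect_loc` must exceed `effect_floor`.")
  }
  if (cfg$alignment_strength < 0) {
    abort("Invalid sim_config: `alignment_strength` must be >= 0.")
  }
  structure(cfg, class = "sim_config")
}
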