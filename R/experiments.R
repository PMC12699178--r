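# Reusable in-silico experiments built from the pipeline stages.

#' Bundled reference morphometry tables
#'
#' Stage-level and per-tip summary tables of ureteric-bud cell morphometry
#' (branching-competent stages and branching-incompetent tips) shipped with
#' the package as inputs for the aggregation utilities: per-tip cell counts
#' and mean values of the seven geometric parameters.
#'
#' @param which `"bc_stages"` (five branch-cycle stages) or `"bi_tips"`
#'   (three branching-incompetent tips).
#' @return A data.frame.
#' @examples
#' bi <- morphometry_reference("bi_tips")
#' pooled_mean(bi$volume, bi$n_cells)
#' @export
morphometry_reference <- function(which = c("bc_stages", "bi_tips")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "bc_stages") "bc_stage_summary.csv"
                   else "bi_tip_summary.csv",
                   package = "ubmorph", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}

#' Branch-cycle stage-structure recovery experiment
#'
#' Simulates one tip per branch-cycle stage (initial bud, ampulla,
#' asymmetric ampulla, T-bud) with the stage-default cell-shape
#' distributions, runs the full reconstruction pipeline
#' (watershed segmentation, feature extraction), and checks whether the
#' recovered median elongation reproduces the expected progression: rising
#' from initial bud through ampulla to the asymmetric ampulla, then
#' dropping at the T-bud.
#'
#' Tissues use compact lumen geometries (just large enough that lumen and
#' exterior basins stay outside the 50-500 um^3 cell gate) so the
#' experiment stays cheap; the planted signal lives entirely in the
#' stage axis distributions, which are the package defaults.
#'
#' @param seed integer seed for the four tissues.
#' @param n_cells vector of cells per stage, chosen so all four tissues
#'   have comparable packing density (watershed crests between neighbours
#'   sit mid-gap, so strongly unequal crowding would bias recovered tangent
#'   axes differently across stages).
#' @return A list: `features` (combined `cell_feature_table`),
#'   `median_elongation` (named per stage), `rank_ok` (logical: bud <
#'   ampulla < asymmetric ampulla and T-bud < asymmetric ampulla).
#' @export
branch_cycle_recovery <- function(seed, n_cells = c(14, 18, 18, 30)) {
  stages <- c("initial_bud", "ampulla", "asymmetric_ampulla", "t_bud")
  lumens <- list(
    initial_bud = list(sphere(c(0, 0, 0), 9.4)),
    ampulla = list(sphere(c(0, 0, 0), 10.3)),
    asymmetric_ampulla = list(sphere(c(0, 0, 0), 10.5),
                              sphere(c(0, 0, 13), 6)),
    t_bud = list(sphere(c(0, 0, -13), 10.2), sphere(c(0, 0, 13), 10.2)))
  cfg <- segment_config(radius = 0) # pristine membranes: no gap closing
  tabs <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    tt <- generate_tip_tissue(tissue_spec(
      stages[i], n_cells = n_cells[i], lumen_params = lumens[[i]],
      pad = 2, seed = seed * 10 + i))
    seg <- segment_pipeline(tt$prob, cfg)
    tabs[[i]] <- compute_features(seg, tip_id = paste0(stages[i], "_", seed),
                                  stage = stages[i])
  }
  feats <- do.call(bind_feature_tables, tabs)
  med <- vapply(stages, function(s)
    median(feats$elongation[feats$stage == s]), numeric(1))
  rank_ok <- med[["initial_bud"]] < med[["ampulla"]] &&
    med[["ampulla"]] < med[["asymmetric_ampulla"]] &&
    med[["t_bud"]] < med[["asymmetric_ampulla"]]
  list(features = feats, median_elongation = med, rank_ok = rank_ok)
}
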