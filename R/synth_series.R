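#' Default genotype-by-stage simulation presets
#'
#' One row per (genotype, stage) cell of the 2 x 3 design, with the
#' generator parameters that reproduce the study's qualitative pattern:
#' 3xTg microglia more ramified than non-Tg at the pre-symptomatic stage and
#' less ramified at the late stage; microglia density elevated only in late
#' 3xTg; caspase-3 positive fraction rising with stage in 3xTg; GFAP
#' fraction elevated at pre/early and back near control at late; protein
#' aggregates only in 3xTg, confined to the IL band at pre-stage, appearing
#' in the OL and growing from early stage on. Aggregate counts/radii apply
#' to each of the Abeta and pTau channels.
#'
#' @return Data frame with columns genotype, stage, n_primary, max_depth,
#'   branch_prob, seg_len_um, n_microglia, n_ganglion, caspase_p,
#'   gfap_fraction, agg_n_il, agg_n_ol, agg_r_um.
#' @export
stage_presets <- function() {
  data.frame(
    genotype = rep(c("nonTg", "3xTg"), each = 3),
    stage = rep(c("pre", "early", "late"), 2),
    n_primary = c(4, 4, 4, 5, 4, 3),
    max_depth = c(2, 2, 2, 3, 2, 2),
    branch_prob = c(0.6, 0.6, 0.6, 0.8, 0.6, 0.25),
    seg_len_um = c(7, 7, 7, 6.5, 7, 5),
    n_microglia = c(6, 6, 6, 6, 6, 11),
    n_ganglion = 30,
    caspase_p = c(0.02, 0.02, 0.02, 0.06, 0.10, 0.14),
    gfap_fraction = c(0.10, 0.10, 0.10, 0.20, 0.22, 0.12),
    agg_n_il = c(0, 0, 0, 3, 3, 4),
    agg_n_ol = c(0, 0, 0, 0, 2, 3),
    agg_r_um = c(0, 0, 0, 0.7, 1.0, 1.3),
    stringsAsFactors = FALSE)
}

preset_field_spec <- function(preset, seed, size_um = c(160, 160), nz = 6,
                              dx = 0.3, dy = 0.3, dz = 0.5) {
  agg <- data.frame(channel = character(), layer = character(),
                    r_um = numeric())
  for (chn in c("Abeta", "pTau")) {
    if (preset$agg_n_il > 0)
      agg <- rbind(agg, data.frame(channel = chn, layer = "IL",
                                   r_um = rep(preset$agg_r_um, preset$agg_n_il)))
    if (preset$agg_n_ol > 0)
      agg <- rbind(agg, data.frame(channel = chn, layer = "OL",
                                   r_um = rep(preset$agg_r_um, preset$agg_n_ol)))
  }
  field_spec(size_um = size_um, nz = nz, dx = dx, dy = dy, dz = dz,
             n_microglia = preset$n_microglia,
             microglia_params = cell_params(
               n_primary = preset$n_primary,
               max_depth = preset$max_depth,
               branch_prob = preset$branch_prob,
               seg_len_um = preset$seg_len_um,
               thickness_px = 3),
             n_ganglion = preset$n_ganglion,
             caspase_p = preset$caspase_p,
             gfap_fraction = preset$gfap_fraction,
             aggregates = agg,
             seed = seed)
}

#' Generate a seeded genotype-by-stage dataset of synthetic fields
#'
#' Emits `n_fields` fields per (genotype, stage) group. Per-field seeds are
#' derived from the master seed by counter-based splitting, so any field can
#' be regenerated in isolation. Fields are either written to `out_dir`
#' (TIFF + ground-truth JSON per field), handed one by one to a `process`
#' callback (memory-frugal streaming), or returned in memory.
#'
#' @param presets preset table, default [stage_presets()]; must contain
#'   every cell of the 2 x 3 genotype-by-stage design.
#' @param n_fields fields per group (default 16, the study's fields/slices
#'   count per condition).
#' @param seed master integer seed.
#' @param out_dir optional output directory for TIFF + JSON sidecars.
#' @param process optional `function(field, info)` applied to each generated
#'   field (`field` = list(stack, truth), `info` = one manifest row); its
#'   results are returned in `$results` and the stack is then discarded.
#' @param ... field geometry overrides passed to the internal spec builder
#'   (`size_um`, `nz`, `dx`, `dy`, `dz`).
#' @return List with `manifest` (data frame: field_id, genotype, stage,
#'   seed, path, n_microglia, n_ganglion, n_caspase_positive,
#'   gfap_fraction_realized, n_aggregates) and, depending on the mode,
#'   `fields` or `results`.
#' @export
generate_stage_series <- function(presets = stage_presets(), n_fields = 16,
                                  seed = 1, out_dir = NULL, process = NULL,
                                  ...) {
  need <- expand.grid(genotype = c("nonTg", "3xTg"),
                      stage = c("pre", "early", "late"),
                      stringsAsFactors = FALSE)
  have <- paste(presets$genotype, presets$stage)
  miss <- !paste(need$genotype, need$stage) %in% have
  if (any(miss))
    stop("preset table is missing design cells: ",
         paste(paste(need$genotype, need$stage)[miss], collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  manifest <- list(); fields <- list(); results <- list()
  idx <- 0L
  for (r in seq_len(nrow(presets))) {
    pr <- presets[r, ]
    for (f in seq_len(n_fields)) {
      idx <- idx + 1L
      fseed <- rng_child_seed(seed, idx)
      fid <- sprintf("%s_%s_f%02d", pr$genotype, pr$stage, f)
      sp <- preset_field_spec(pr, fseed, ...)
      fld <- generate_field(sp)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(fid, ".tif"))
        write_stack(fld$stack, path)
        write_ground_truth(fld$truth, file.path(out_dir, paste0(fid, ".truth.json")))
      }
      info <- data.frame(field_id = fid, genotype = pr$genotype,
                         stage = pr$stage, seed = fseed, path = path,
                         n_microglia = fld$truth$n_microglia,
                         n_ganglion = fld$truth$n_ganglion_neurons,
                         n_caspase_positive = fld$truth$n_caspase_positive,
                         gfap_fraction_realized = fld$truth$gfap_fraction_realized,
                         n_aggregates = nrow(fld$truth$aggregates),
                         stringsAsFactors = FALSE)
      manifest[[idx]] <- info
      if (!is.null(process)) {
        results[[idx]] <- process(fld, info)
      } else if (is.null(out_dir)) {
        fields[[idx]] <- fld
      }
    }
  }
  out <- list(manifest = do.call(rbind, manifest))
  if (!is.null(process)) out$results <- results
  else if (is.null(out_dir)) out$fields <- fields
  out
}
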