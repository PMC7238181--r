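#' Screen drug-solvent-filament combinations by HSP distance
#'
#' Rank every (solvent, filament) pair for passive-diffusion loading of a
#' drug. The screening rule favours combinations where the drug is poorly
#' miscible with the solvent (large drug-solvent Ra, so that partitioning
#' into the filament is energetically favourable) while the solvent is
#' moderately miscible with the filament (solvent-filament Ra near an
#' intermediate target, enough to plasticise the filament without dissolving
#' it).
#'
#' A pair is `favoured` when `ra_drug_solvent > t_high` and
#' `|ra_solvent_filament - t_mid| <= width`; `borderline` when the
#' drug-solvent criterion holds but the solvent-filament band is missed
#' (workable solvent, suboptimal filament); `rejected` when
#' `ra_drug_solvent <= t_high`, since a drug too miscible with its solvent
#' will not partition into any filament. The rank score
#' `ra_drug_solvent - |ra_solvent_filament - t_mid|` is a convenience
#' ordering invented by this package (higher is better) and is reported
#' alongside the raw Ra values.
#'
#' @param drug A [material()] with role `"drug"`.
#' @param solvents,filaments Lists of [material()] objects.
#' @param t_high Drug-solvent Ra threshold (default 10 MPa^1/2).
#' @param t_mid Target solvent-filament Ra (default 10 MPa^1/2).
#' @param width Half-width of the acceptable solvent-filament band
#'   (default 3 MPa^1/2).
#' @return A tibble with one row per (solvent, filament) pair, columns
#'   `drug`, `solvent`, `filament`, `ra_drug_solvent`, `ra_solvent_filament`,
#'   `ra_drug_filament`, `rank_score`, `verdict`, sorted by `rank_score`
#'   descending with ties broken lexicographically by (solvent, filament).
#' @examples
#' mats <- nfd_reference_materials()
#' screen_combinations(mats$NFD, mats[c("ethanol", "ethyl acetate")],
#'                     mats[c("PVA", "HS", "PLA", "TPU")])
#' @export
screen_combinations <- function(drug, solvents, filaments,
                                t_high = 10, t_mid = 10, width = 3) {
  if (length(solvents) == 0L) stop_domain("`solvents` must be non-empty")
  if (length(filaments) == 0L) stop_domain("`filaments` must be non-empty")
  if (!inherits(drug, "material")) stop_domain("`drug` must be a material")
  rows <- list()
  for (s in solvents) {
    for (f in filaments) {
      ra_ds <- ra_distance(drug$hsp, s$hsp)
      ra_sf <- ra_distance(s$hsp, f$hsp)
      ra_df <- ra_distance(drug$hsp, f$hsp)
      in_high <- ra_ds > t_high
      in_band <- abs(ra_sf - t_mid) <= width
      verdict <- if (in_high && in_band) {
        "favoured"
      } else if (in_high) {
        "borderline"
      } else {
        "rejected"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        drug = drug$name, solvent = s$name, filament = f$name,
        ra_drug_solvent = ra_ds, ra_solvent_filament = ra_sf,
        ra_drug_filament = ra_df,
        rank_score = ra_ds - abs(ra_sf - t_mid),
        verdict = verdict
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$rank_score, out$solvent, out$filament), , drop = FALSE]
}
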