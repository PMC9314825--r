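#' Classify photosynthetic operation from carbon isotope composition
#'
#' Leaf delta 13C (vs the PDB standard) discriminates plants that grew
#' using C4 photosynthesis from those that did not: values strictly above
#' -16 permil indicate C4 operation. The boundary is strict, so exactly
#' -16 classifies as non-C4. Values outside the plausible range
#' [-40, 0] permil are still classified, with a warning.
#'
#' @param d13c numeric vector of delta 13C values (permil vs PDB).
#' @param threshold classification boundary (default -16).
#' @return Character vector, `"C4-type"` or `"non-C4"` (`NA` stays `NA`).
#' @export
classify_d13c <- function(d13c, threshold = -16) {
  out_of_range <- !is.na(d13c) & (d13c < -40 | d13c > 0)
  if (any(out_of_range)) {
    warn(sprintf("%d delta13C value(s) outside the plausible range [-40, 0] permil",
                 sum(out_of_range)))
  }
  ifelse(is.na(d13c), NA_character_,
         ifelse(d13c > threshold, "C4-type", "non-C4"))
}

#' Mid-parent additivity analysis of hybrid traits
#'
#' For each hybrid and trait, computes the deviation of the hybrid from the
#' mid-parent value `(mother + father) / 2` and the scaled dominance
#' `deviation / (|mother - father| / 2)` (the standard quantitative-
#' genetics index: 0 = perfect additivity, +1/-1 = full dominance of the
#' high/low parent, beyond that transgressive). When the parents are equal
#' the index is undefined and flagged.
#'
#' @param traits tibble with columns `accession_id`, `trait`, `value` (one
#'   value per accession x trait; extra columns are ignored).
#' @param pedigree tibble with columns `hybrid`, `mother`, `father`.
#' @return Tibble with one row per hybrid x trait: parental and hybrid
#'   values, `midparent`, `deviation`, `scaled_dominance`, and a `note`
#'   column (`NA` when the row is clean; rows with a missing family member
#'   carry an explanatory note instead of failing).
#' @export
midparent_analysis <- function(traits, pedigree) {
  traits <- tibble::as_tibble(traits)
  pedigree <- tibble::as_tibble(pedigree)
  need_t <- c("accession_id", "trait", "value")
  if (!all(need_t %in% names(traits))) {
    abort("traits needs columns accession_id, trait, value")
  }
  if (!all(c("hybrid", "mother", "father") %in% names(pedigree))) {
    abort("pedigree needs columns hybrid, mother, father")
  }
  if (anyDuplicated(traits[, c("accession_id", "trait")])) {
    abort("traits must have one value per accession x trait")
  }

  lookup <- function(id, tr) {
    v <- traits$value[traits$accession_id == id & traits$trait == tr]
    if (length(v) == 0) NA_real_ else v
  }

  purrr::pmap_dfr(pedigree[, c("hybrid", "mother", "father")], function(hybrid, mother, father) {
    trs <- unique(traits$trait[traits$accession_id %in% c(hybrid, mother, father)])
    purrr::map_dfr(trs, function(tr) {
      hv <- lookup(hybrid, tr)
      mv <- lookup(mother, tr)
      fv <- lookup(father, tr)
      missing_ids <- c(hybrid, mother, father)[is.na(c(hv, mv, fv))]
      note <- NA_character_
      mid <- dev <- sdom <- NA_real_
      if (length(missing_ids) > 0) {
        note <- paste0("missing value for ", paste(missing_ids, collapse = ", "))
      } else {
        mid <- (mv + fv) / 2
        dev <- hv - mid
        if (mv == fv) {
          note <- "parents equal; scaled dominance undefined"
        } else {
          sdom <- dev / (abs(mv - fv) / 2)
        }
      }
      tibble::tibble(hybrid = hybrid, mother = mother, father = father, trait = tr,
                     mother_value = mv, father_value = fv, hybrid_value = hv,
                     midparent = mid, deviation = dev, scaled_dominance = sdom,
                     note = note)
    })
  })
}
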