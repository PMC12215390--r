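#' Chemistry presets: induced T-to-C conversion probabilities
#'
#' Default induced conversion probabilities (`p_c`) for the chemical
#' conversion methods and platform combinations benchmarked by the package.
#' The values are the observed mean T-to-C substitution rates of each
#' method on ZF4 zebrafish fibroblast cells, used here as approximate
#' conversion-probability defaults: an observed raw rate conflates the true
#' per-position conversion probability of new molecules with the fraction of
#' new molecules and the background rate, so these presets are starting
#' points for simulation, not physical constants.
#'
#' Available presets:
#'
#' | name | chemistry | p_c |
#' |------|-----------|-----|
#' | `mcpba_tfea_ph7.4`   | on-beads mCPBA/TFEA, pH 7.4 (Drop-seq) | 0.0840 |
#' | `mcpba_tfea_ph5.2`   | on-beads mCPBA/TFEA, pH 5.2 (Drop-seq) | 0.0811 |
#' | `naio4_tfea_ph5.2`   | on-beads NaIO4/TFEA, pH 5.2 (Drop-seq) | 0.0819 |
#' | `onbeads_iaa_32c`    | on-beads IAA, 32 C (Drop-seq)          | 0.0639 |
#' | `onbeads_iaa_37c`    | on-beads IAA, 37 C (Drop-seq)          | 0.0384 |
#' | `c4_onbeads_iaa`     | on-beads IAA (MGI C4)                  | 0.0844 |
#' | `c4_insitu_iaa`      | in-situ IAA, pH 8.0 (MGI C4)           | 0.0574 |
#' | `dropseq_insitu_iaa` | in-situ IAA, pH 8.0 (Drop-seq)         | 0.0353 |
#' | `insitu_iaa_ph8`     | in-situ IAA, pH 8.0 (group mean)       | 0.0262 |
#' | `control`            | no chemical conversion                  | background |
#'
#' For `control` the induced rate equals the background rate `p_e`, i.e.
#' chemistry contributes nothing.
#'
#' @param name preset name (see table), or `NULL` to list all presets.
#' @param p_e background conversion probability, substituted for `control`.
#' @return a single conversion probability, or a named numeric vector of all
#'   presets when `name` is `NULL`.
#' @examples
#' chemistry_preset("mcpba_tfea_ph7.4")
#' chemistry_preset()  # all presets
#' @export
chemistry_preset <- function(name = NULL, p_e = 0.002) {
  presets <- c(
    "mcpba_tfea_ph7.4"   = 0.0840,
    "mcpba_tfea_ph5.2"   = 0.0811,
    "naio4_tfea_ph5.2"   = 0.0819,
    "onbeads_iaa_32c"    = 0.0639,
    "onbeads_iaa_37c"    = 0.0384,
    "c4_onbeads_iaa"     = 0.0844,
    "c4_insitu_iaa"      = 0.0574,
    "dropseq_insitu_iaa" = 0.0353,
    "insitu_iaa_ph8"     = 0.0262,
    "control"            = NA_real_
  )
  if (is.null(name)) {
    presets["control"] <- p_e
    return(presets)
  }
  if (!name %in% names(presets)) {
    stop("unknown chemistry preset: '", name, "'. Known presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  if (name == "control") return(p_e)
  unname(presets[name])
}
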