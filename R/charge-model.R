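#' Integer per-residue charge model
#'
#' Charge conventions at pH 7 for the disordered-region analyses: arginine and
#' lysine carry +1e, aspartate and glutamate -1e, phosphoserine (SEP) and
#' phosphothreonine (TPO) -2e, and every other residue -- including histidine,
#' which is modelled N-epsilon-protonated and therefore neutral -- carries 0.
#' The acetyl (ACE) and N-methylamide (NME) caps are neutral, so capped
#' constructs have no terminal charges.
#'
#' @return Named integer vector mapping one-letter codes (plus the
#'   three-letter phospho codes `SEP`/`TPO` and caps `ACE`/`NME`) to charges
#'   in units of elementary charge e.
#' @export
#' @examples
#' charge_model()[c("R", "K", "D", "E", "H", "SEP")]
charge_model <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  q <- stats::setNames(integer(length(aa)), aa)
  q[c("R", "K")] <- 1L
  q[c("D", "E")] <- -1L
  c(q, SEP = -2L, TPO = -2L, ACE = 0L, NME = 0L)
}

#' Net charge of a region
#'
#' Sums per-residue integer charges over the sequence, with annotated
#' phosphosites counted as SEP/TPO (-2e each, replacing the 0 of S/T). This is
#' the "sum of basic (+e) and acidic (-e) amino acids and phosphate (-2e)
#' groups" bookkeeping used for the capped, neutral-histidine constructs.
#'
#' @param region A [region()] object.
#' @param model Charge table from [charge_model()].
#' @return Integer net charge in units of e.
#' @export
#' @examples
#' r <- region("demo", "PTBP2", "Nterm", 1, "DEKRH")
#' net_charge(r)  # +2 and -2 cancel, His neutral -> 0
net_charge <- function(region, model = charge_model()) {
  stopifnot(inherits(region, "idr_region"))
  aa <- strsplit(region$sequence, "")[[1]]
  unknown <- which(!aa %in% names(model))
  if (length(unknown) > 0) {
    stop("unknown residue code '", aa[unknown[1]], "' at position ",
         region$first_residue + unknown[1] - 1L, call. = FALSE)
  }
  q <- unname(model[aa])
  if (nrow(region$phosphosites) > 0) {
    idx <- region$phosphosites$residue_number - region$first_residue + 1L
    q[idx] <- ifelse(region$phosphosites$residue_letter == "S",
                     model[["SEP"]], model[["TPO"]])
  }
  as.integer(sum(q))
}

#' Fraction of phosphorylated residues
#'
#' Number of annotated phosphosites divided by the region length, reported
#' rounded to 3 decimals. Depends only on counts, so it is invariant under
#' renumbering of the region.
#'
#' @inheritParams net_charge
#' @return Fraction in \[0, 1\], rounded to 3 decimals.
#' @export
phospho_fraction <- function(region) {
  stopifnot(inherits(region, "idr_region"))
  len <- nchar(region$sequence)
  stopifnot(len > 0)
  round(nrow(region$phosphosites) / len, 3)
}

#' Charge introduced by phosphorylation
#'
#' Each phosphosite converts a neutral S/T into a -2e phospho residue, so the
#' total charge introduced is -2e per site.
#'
#' @inheritParams net_charge
#' @return Integer charge in units of e (0 or negative).
#' @export
charge_introduced <- function(region) {
  stopifnot(inherits(region, "idr_region"))
  -2L * nrow(region$phosphosites)
}
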