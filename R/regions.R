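#' Disordered-region record
#'
#' A `region` bundles one disordered segment of a PTB paralog: the paralog and
#' region name, the residue numbering offset used in the source tables, the
#' one-letter sequence, and the set of annotated phosphosites. Phosphosites
#' are given as strings like `"S16"` (residue letter + residue number in
#' region numbering); each must fall inside the region span and its letter
#' must match the stored sequence.
#'
#' @param name Short identifier, e.g. `"P2Nterm"` or `"P2phosNterm"`.
#' @param paralog `"PTBP1"` or `"PTBP2"`.
#' @param region_name `"Nterm"`, `"L1"` or `"L2"`.
#' @param first_residue Integer; number of the first residue in the region.
#' @param sequence One-letter amino-acid string.
#' @param phosphosites Character vector like `c("S16", "T38")`; empty for an
#'   unphosphorylated region.
#' @param capped Logical; whether neutral ACE/NME caps are modelled (default
#'   `TRUE`, matching the simulated constructs).
#' @return An object of class `idr_region`.
#' @export
#' @examples
#' region("P2L2", "PTBP2", "L2", 283,
#'        "GALNVQGDLNVQGKETVQGALNVQGSLNVQGAENVQGALNVQGRLNVEGALNVQGALNVQGA",
#'        phosphosites = c("T298", "S308"))
region <- function(name, paralog, region_name, first_residue, sequence,
                   phosphosites = character(), capped = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  paralog <- match.arg(paralog, c("PTBP1", "PTBP2"))
  first_residue <- as.integer(first_residue)
  sites <- parse_phosphosites(phosphosites)
  len <- nchar(sequence)
  if (nrow(sites) > 0) {
    bad <- sites$residue_number < first_residue |
      sites$residue_number > first_residue + len - 1L
    if (any(bad)) {
      stop("phosphosite ", phosphosites[bad][1], " outside region span ",
           first_residue, "-", first_residue + len - 1L, call. = FALSE)
    }
    at <- substring(sequence, sites$residue_number - first_residue + 1L,
                    sites$residue_number - first_residue + 1L)
    mism <- at != sites$residue_letter
    if (any(mism)) {
      stop("phosphosite ", phosphosites[mism][1],
           " disagrees with sequence letter '", at[mism][1], "'",
           call. = FALSE)
    }
    if (anyDuplicated(sites$residue_number)) {
      stop("duplicated phosphosite residue number", call. = FALSE)
    }
  }
  structure(
    list(name = name, paralog = paralog, region_name = region_name,
         first_residue = first_residue, sequence = sequence,
         phosphosites = sites, capped = isTRUE(capped)),
    class = "idr_region"
  )
}

parse_phosphosites <- function(x) {
  x <- x[nzchar(x)]
  if (length(x) == 0) {
    return(data.frame(residue_number = integer(), residue_letter = character(),
                      stringsAsFactors = FALSE))
  }
  letter <- substr(x, 1, 1)
  num <- suppressWarnings(as.integer(substring(x, 2)))
  if (any(!letter %in% c("S", "T")) || anyNA(num)) {
    stop("phosphosites must look like 'S16' or 'T38' (S/T + residue number)",
         call. = FALSE)
  }
  data.frame(residue_number = num, residue_letter = letter,
             stringsAsFactors = FALSE)
}

#' @export
print.idr_region <- function(x, ...) {
  cat(sprintf("<region %s: %s %s, residues %d-%d (%d aa), %d phosphosite(s)>\n",
              x$name, x$paralog, x$region_name, x$first_residue,
              x$first_residue + nchar(x$sequence) - 1L, nchar(x$sequence),
              nrow(x$phosphosites)))
  invisible(x)
}

#' Load the packaged region and phosphosite tables
#'
#' Reads two tab-delimited tables -- one describing the six disordered regions
#' (name, paralog, region, first_residue, declared residue count and
#' unphosphorylated net charge, sequence) and one listing the phosphosites per
#' region -- and returns the six unphosphorylated plus six phosphorylated
#' region records. Declared lengths and net charges are cross-checked against
#' the sequences; any mismatch is an error. The phosphorylated variant of a
#' region `X` is named `P<n>phos<region>` following the source-table naming
#' (e.g. `P2phosNterm`).
#'
#' The packaged default region table carries synthetic stand-in sequences
#' (see `inst/extdata/regions_synthetic.tsv`): the published sequences are
#' only available as a figure, so the fixture encodes every published
#' constraint (lengths, unphosphorylated net charges, phosphosite letters and
#' positions, and the charged residues named in the salt-bridge results)
#' with neutral filler elsewhere. The phosphosite table is the published one.
#'
#' @param table1_source Path to the region table (default: packaged fixture).
#' @param table2_source Path to the phosphosite table (default: packaged
#'   fixture).
#' @return Named list of [region()] objects, unphosphorylated and
#'   phosphorylated variants for each row of the region table.
#' @export
#' @examples
#' regs <- load_region_tables()
#' net_charge(regs$P2phosNterm)
load_region_tables <- function(
    table1_source = system.file("extdata", "regions_synthetic.tsv",
                                package = "idrflex"),
    table2_source = system.file("extdata", "phosphosites.tsv",
                                package = "idrflex")) {
  t1 <- utils::read.delim(table1_source, stringsAsFactors = FALSE)
  t2 <- utils::read.delim(table2_source, stringsAsFactors = FALSE)
  need1 <- c("name", "paralog", "region", "first_residue", "total_residues",
             "net_charge", "sequence")
  if (!all(need1 %in% names(t1))) {
    stop("region table must have columns: ", paste(need1, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("name", "phosphosites") %in% names(t2))) {
    stop("phosphosite table must have columns: name, phosphosites",
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(t1))) {
    row <- t1[i, ]
    if (nchar(row$sequence) != row$total_residues) {
      stop("region ", row$name, ": declared ", row$total_residues,
           " residues but sequence has ", nchar(row$sequence), call. = FALSE)
    }
    unphos <- region(row$name, row$paralog, row$region, row$first_residue,
                     row$sequence)
    if (net_charge(unphos) != row$net_charge) {
      stop("region ", row$name, ": declared net charge ", row$net_charge,
           " but sequence sums to ", net_charge(unphos), call. = FALSE)
    }
    out[[row$name]] <- unphos
    j <- match(row$name, t2$name)
    if (!is.na(j)) {
      sites <- trimws(strsplit(t2$phosphosites[j], ",")[[1]])
      phos_name <- sub("^(P[12])", "\\1phos", row$name)
      out[[phos_name]] <- region(phos_name, row$paralog, row$region,
                                 row$first_residue, row$sequence,
                                 phosphosites = sites)
    }
  }
  out
}
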