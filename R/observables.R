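# Per-frame geometric observables, cross-replica statistics, the convergence
# stopping rule, and the percent-spliced-in formula.

#' Mass-weighted radius of gyration of a frame
#'
#' \eqn{R_g = \sqrt{\sum_i m_i \|r_i - \bar r\|^2 / \sum_i m_i}} with
#' \eqn{\bar r} the centre of mass. All atoms in the topology contribute with
#' their stored masses (element masses for all-atom frames, residue masses
#' for coarse-grained beads).
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param top The matching [topology()].
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, top) {
  stopifnot(inherits(top, "idr_topology"), nrow(frame) == nrow(top),
            nrow(frame) >= 2)
  m <- top$mass
  if (sum(m) <= 0) stop("zero total mass", call. = FALSE)
  com <- colSums(frame * m) / sum(m)
  d2 <- rowSums((frame - matrix(com, nrow(frame), 3, byrow = TRUE))^2)
  sqrt(sum(m * d2) / sum(m))
}

#' End-to-end (N/C-termini) distance of a frame
#'
#' Euclidean distance between the CA atom of the first and the last standard
#' (non-cap) residue. ACE/NME caps are excluded. For coarse-grained chains
#' the beads are CA pseudo-atoms, so this is the first-to-last bead distance.
#' A single-residue chain has distance 0.
#'
#' @inheritParams radius_of_gyration
#' @return Distance in Angstrom.
#' @export
end_to_end_distance <- function(frame, top) {
  stopifnot(inherits(top, "idr_topology"), nrow(frame) == nrow(top))
  std <- which(!top$resname %in% CAP_RESNAMES)
  if (length(std) == 0) stop("no standard residues", call. = FALSE)
  resids <- top$resid[std]
  first_res <- min(resids)
  last_res <- max(resids)
  i <- std[which(resids == first_res & top$atom[std] == "CA")]
  j <- std[which(resids == last_res & top$atom[std] == "CA")]
  if (length(i) != 1 || length(j) != 1) {
    stop("missing terminal CA atom", call. = FALSE)
  }
  sqrt(sum((frame[i, ] - frame[j, ])^2))
}

#' Per-frame observable series for an ensemble or replica set
#'
#' @param x An [ensemble()] or `replica_set`.
#' @param observables Which observables to compute, subset of
#'   `c("Rg", "Ree")`.
#' @return Tidy `data.frame` with columns `copy`, `frame`, `name`, `value`,
#'   `units` (single ensembles report copy 1).
#' @export
observable_series <- function(x, observables = c("Rg", "Ree")) {
  observables <- match.arg(observables, several.ok = TRUE)
  ens_list <- if (inherits(x, "replica_set")) x$ensembles else list(x)
  out <- list()
  for (cp in seq_along(ens_list)) {
    ens <- ens_list[[cp]]
    stopifnot(inherits(ens, "idr_ensemble"))
    nf <- n_frames(ens)
    for (obs in observables) {
      f <- switch(obs, Rg = radius_of_gyration, Ree = end_to_end_distance)
      vals <- vapply(seq_len(nf),
                     function(k) f(get_frame(ens, k), ens$topology),
                     numeric(1))
      out[[length(out) + 1]] <- data.frame(
        copy = cp, frame = seq_len(nf), name = obs, value = vals,
        units = "A", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cross-replica statistics for an observable
#'
#' Grand mean of per-copy means, with the standard error of the mean across
#' copies: \eqn{SEM = sd(\text{copy means}) / \sqrt{n_{copies}}} (sample
#' standard deviation, ddof = 1).
#'
#' @param series Tidy series from [observable_series()] (columns `copy`,
#'   `name`, `value`), or a list of per-copy numeric vectors for a single
#'   observable.
#' @return `data.frame` of class `ensemble_stat` with one row per observable:
#'   `name`, `grand_mean`, `sem`, `n_copies`, plus per-copy means in
#'   `copy_means` (list column).
#' @export
replica_stats <- function(series) {
  if (is.list(series) && !is.data.frame(series)) {
    series <- do.call(rbind, lapply(seq_along(series), function(cp) {
      data.frame(copy = cp, name = "value", value = series[[cp]])
    }))
  }
  stopifnot(all(c("copy", "name", "value") %in% names(series)))
  if (length(unique(series$copy)) < 2) {
    stop("need >= 2 copies for a standard error across copies", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(series, series$name), function(d) {
    means <- tapply(d$value, d$copy, mean)
    data.frame(name = d$name[1], grand_mean = mean(means),
               sem = stats::sd(means) / sqrt(length(means)),
               n_copies = length(means), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "copy_means") <- lapply(split(series, series$name),
                                    function(d) tapply(d$value, d$copy, mean))
  class(out) <- c("ensemble_stat", "data.frame")
  out
}

#' Cross-replica convergence rule
#'
#' The run is converged when the relative standard error
#' \eqn{SEM / |\text{grand mean}|} is strictly below the threshold for BOTH
#' the radius of gyration and the N/C-termini distance. A zero grand mean
#' with nonzero SEM is degenerate and reported as not converged.
#'
#' @param stats An `ensemble_stat` data.frame containing rows named `Rg` and
#'   `Ree`.
#' @param threshold Relative-SEM threshold (default 0.05, i.e. < 5\%).
#' @return List with `converged` (logical) and `report` (per-observable
#'   data.frame: name, grand_mean, sem, ratio, pass, degenerate).
#' @export
check_convergence <- function(stats, threshold = 0.05) {
  stopifnot(is.data.frame(stats),
            all(c("name", "grand_mean", "sem") %in% names(stats)))
  need <- c("Rg", "Ree")
  if (!all(need %in% stats$name)) {
    stop("convergence requires both Rg and Ree statistics", call. = FALSE)
  }
  s <- stats[stats$name %in% need, ]
  degenerate <- s$grand_mean == 0 & s$sem > 0
  ratio <- ifelse(s$grand_mean == 0, Inf, s$sem / abs(s$grand_mean))
  ratio[s$grand_mean == 0 & s$sem == 0] <- 0
  pass <- ratio < threshold & !degenerate
  list(converged = all(pass),
       report = data.frame(name = s$name, grand_mean = s$grand_mean,
                           sem = s$sem, ratio = ratio, pass = pass,
                           degenerate = degenerate, stringsAsFactors = FALSE))
}

#' Percent spliced-in (PSI)
#'
#' \eqn{100 \times \text{included} / (\text{included} + \text{excluded})}
#' from included/excluded band intensities, reported to one decimal.
#'
#' @param included_intensity,excluded_intensity Non-negative band
#'   intensities, not both zero.
#' @return PSI in percent, rounded to 1 decimal.
#' @export
#' @examples
#' compute_psi(30, 70)  # 30.0
compute_psi <- function(included_intensity, excluded_intensity) {
  stopifnot(included_intensity >= 0, excluded_intensity >= 0)
  total <- included_intensity + excluded_intensity
  if (total == 0) stop("both intensities are zero", call. = FALSE)
  round(100 * included_intensity / total, 1)
}
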