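#' Combined methyl chemical-shift perturbation
#'
#' Two-nucleus quadrature CSP with the 13C axis compressed onto the 1H
#' scale: `csp = sqrt(dH^2 + (c_scale * dC)^2)`.  The default scaling
#' factor 0.133 reflects the relative methyl 1H/13C shift dispersions.
#'
#' @param delta_H_ppm,delta_C_ppm Shift differences in ppm (finite).
#' @param c_scale 13C scaling factor (default 0.133).
#' @return Combined perturbation in ppm (>= 0); zero iff both shift
#'   differences are zero.
#' @export
#' @examples
#' csp(0, 1.0)    # 0.133
#' csp(0.1, 0)    # 0.1
csp <- function(delta_H_ppm, delta_C_ppm, c_scale = 0.133) {
  check_number(delta_H_ppm, "delta_H_ppm")
  check_number(delta_C_ppm, "delta_C_ppm")
  check_number(c_scale, "c_scale", nonneg = TRUE)
  sqrt(delta_H_ppm^2 + (c_scale * delta_C_ppm)^2)
}

#' Chemical-shift perturbation profile between two states
#'
#' Pairs the methyl peaks of two states on the `(residue, methyl)` key and
#' computes the combined CSP for every shared peak with shifts in both
#' tables.  Unmatched keys are reported via the `unmatched` attribute,
#' never silently dropped.  The profile is symmetric in its arguments
#' (shift differences enter squared).
#'
#' @param state_a,state_b `peak_table`s with `shift_H_ppm` / `shift_C_ppm`
#'   present.
#' @inheritParams csp
#' @return A `csp_profile` tibble: `residue_index`, `methyl_id`,
#'   `delta_H_ppm`, `delta_C_ppm`, `csp_ppm`, `c_scale`.
#' @export
csp_profile <- function(state_a, state_b, c_scale = 0.133) {
  stopifnot(inherits(state_a, "peak_table"), inherits(state_b, "peak_table"))
  key <- c("residue_index", "methyl_id")
  a <- dplyr::select(as_tibble(state_a), dplyr::all_of(key),
                     h_a = "shift_H_ppm", c_a = "shift_C_ppm")
  b <- dplyr::select(as_tibble(state_b), dplyr::all_of(key),
                     h_b = "shift_H_ppm", c_b = "shift_C_ppm")
  j <- dplyr::inner_join(a, b, by = key)
  if (nrow(j) == 0L) {
    abort_empty("The two tables share no (residue, methyl) keys.")
  }
  has_shifts <- is.finite(j$h_a) & is.finite(j$h_b) &
    is.finite(j$c_a) & is.finite(j$c_b)
  if (!any(has_shifts)) {
    abort_validation("No shared peak carries chemical shifts in both tables.")
  }
  k <- j[has_shifts, ]
  unmatched <- dplyr::bind_rows(
    dplyr::anti_join(a, b, by = key)[, key],
    dplyr::anti_join(b, a, by = key)[, key]
  )
  out <- tibble(
    residue_index = k$residue_index,
    methyl_id = k$methyl_id,
    delta_H_ppm = k$h_a - k$h_b,
    delta_C_ppm = k$c_a - k$c_b,
    csp_ppm = csp(k$h_a - k$h_b, k$c_a - k$c_b, c_scale),
    c_scale = c_scale
  )
  structure(
    dplyr::arrange(out, .data$residue_index, .data$methyl_id),
    unmatched = unmatched,
    class = c("csp_profile", class(tibble()))
  )
}

#' Rank or threshold a CSP profile
#'
#' Returns perturbed peaks ranked by CSP, optionally restricted to those
#' at or above a cutoff.  No default cutoff is claimed; choose one
#' appropriate for the spectra at hand (a common heuristic is mean + 1 sd
#' of the trimmed CSP distribution).
#'
#' @param profile A `csp_profile`.
#' @param cutoff Optional minimum `csp_ppm` to retain.
#' @return The profile rows sorted by decreasing CSP.
#' @export
csp_top <- function(profile, cutoff = NULL) {
  stopifnot(inherits(profile, "csp_profile"))
  out <- dplyr::arrange(as_tibble(profile), dplyr::desc(.data$csp_ppm))
  if (!is.null(cutoff)) {
    check_number(cutoff, "cutoff", nonneg = TRUE)
    out <- out[out$csp_ppm >= cutoff, ]
  }
  out
}
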