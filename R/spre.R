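#' Effective net charge from dual-cosolute solvent PREs
#'
#' Combines the solvent-PRE intensity ratios measured with a negatively
#' and a positively charged paramagnetic cosolute into a single signed
#' per-residue parameter.  Under the default convention
#' `phi = I_ratio(minus) - I_ratio(plus)`: a negatively charged cosolute
#' concentrates at positively charged surface patches and broadens their
#' peaks more strongly (larger ratio), so `phi > 0` marks a net positively
#' charged region and `phi < 0` a net negatively charged one.  `phi` is a
#' proxy for the near-surface electrostatic environment, not a potential
#' in physical units.
#'
#' @param ratio_minus,ratio_plus Intensity ratios from the negatively and
#'   positively charged cosolute samples (finite; bleached peaks have no
#'   numeric phi).
#' @param convention `"minus_minus_plus"` (default, phi > 0 means net
#'   positive surface) or `"plus_minus_minus"` for the opposite sign
#'   order.
#' @return Signed effective net charge(s); antisymmetric under swapping
#'   the two cosolutes.
#' @export
#' @examples
#' phi_value(3.0, 1.2)   # +1.8, net positive patch
phi_value <- function(ratio_minus, ratio_plus,
                      convention = c("minus_minus_plus", "plus_minus_minus")) {
  convention <- match.arg(convention)
  check_number(ratio_minus, "ratio_minus")
  check_number(ratio_plus, "ratio_plus")
  if (convention == "minus_minus_plus") ratio_minus - ratio_plus
  else ratio_plus - ratio_minus
}

#' Uncertainty of the effective net charge
#'
#' Quadrature sum of the two cosolute ratio uncertainties:
#' `sigma_phi = sqrt(sigma_plus^2 + sigma_minus^2)`.
#'
#' @param sigma_ratio_plus,sigma_ratio_minus Ratio uncertainties (>= 0).
#' @return `sigma_phi` (>= 0).
#' @export
phi_uncertainty <- function(sigma_ratio_plus, sigma_ratio_minus) {
  check_number(sigma_ratio_plus, "sigma_ratio_plus", nonneg = TRUE)
  check_number(sigma_ratio_minus, "sigma_ratio_minus", nonneg = TRUE)
  sqrt(sigma_ratio_plus^2 + sigma_ratio_minus^2)
}

#' Build a per-residue effective net charge profile
#'
#' Runs the PRE ratio analysis for the positive- and negative-cosolute
#' samples against a shared cosolute-free (diamagnetic) reference, then
#' combines the two ratios into phi with propagated uncertainty.  Peaks
#' bleached under either cosolute (or missing from one sample) get no
#' numeric phi and carry `bleached_any = TRUE`.
#'
#' @param dia Cosolute-free `peak_table` (diamagnetic reference).
#' @param plus,minus `peak_table`s with the positively / negatively
#'   charged cosolute.
#' @param bleach_snr_threshold Passed to [build_pre_profile()].
#' @inheritParams phi_value
#' @return A `phi_profile` tibble: `residue_index`, `methyl_id`,
#'   `ratio_plus`, `ratio_minus`, `sigma_plus`, `sigma_minus`, `phi`,
#'   `sigma_phi`, `bleached_any`, plus `construct` and `pH` provenance.
#' @export
build_phi_profile <- function(dia, plus, minus, bleach_snr_threshold = 3,
                              convention = c("minus_minus_plus",
                                             "plus_minus_minus")) {
  convention <- match.arg(convention)
  prof_plus <- build_pre_profile(dia, plus, bleach_snr_threshold)
  prof_minus <- build_pre_profile(dia, minus, bleach_snr_threshold)
  key <- c("residue_index", "methyl_id")
  tp <- dplyr::select(as_tibble(prof_plus), dplyr::all_of(key),
                      ratio_plus = "i_ratio", sigma_plus = "sigma_ratio",
                      bleached_plus = "bleached")
  tm <- dplyr::select(as_tibble(prof_minus), dplyr::all_of(key),
                      ratio_minus = "i_ratio", sigma_minus = "sigma_ratio",
                      bleached_minus = "bleached")
  j <- dplyr::full_join(tp, tm, by = key)
  bleached_any <- is.na(j$ratio_plus) | is.na(j$ratio_minus) |
    j$bleached_plus %in% TRUE | j$bleached_minus %in% TRUE
  meta <- table_meta(dia)
  out <- tibble(
    residue_index = j$residue_index,
    methyl_id = j$methyl_id,
    ratio_plus = j$ratio_plus,
    ratio_minus = j$ratio_minus,
    sigma_plus = j$sigma_plus,
    sigma_minus = j$sigma_minus,
    phi = ifelse(bleached_any, NA_real_,
                 (j$ratio_minus - j$ratio_plus) *
                   (if (convention == "minus_minus_plus") 1 else -1)),
    sigma_phi = ifelse(bleached_any, NA_real_,
                       sqrt(j$sigma_plus^2 + j$sigma_minus^2)),
    bleached_any = bleached_any,
    construct = meta$construct,
    pH = meta$pH
  )
  structure(
    dplyr::arrange(out, .data$residue_index, .data$methyl_id),
    convention = convention,
    class = c("phi_profile", class(tibble()))
  )
}

#' Construct a phi profile from precomputed values
#'
#' Convenience constructor for building a `phi_profile` directly from
#' per-residue `(phi, sigma_phi)` values, e.g. in simulations or when
#' importing published tables.
#'
#' @param residue_index Integer residues.
#' @param phi,sigma_phi Effective net charge and uncertainty.
#' @param methyl_id Optional peak labels (defaults to the residue index).
#' @param construct,pH Provenance fields.
#' @return A `phi_profile`.
#' @export
phi_profile <- function(residue_index, phi, sigma_phi,
                        methyl_id = NULL, construct = "WT", pH = NA_real_) {
  residue_index <- as.integer(residue_index)
  if (is.null(methyl_id)) methyl_id <- as.character(residue_index)
  out <- tibble(
    residue_index = residue_index,
    methyl_id = methyl_id,
    ratio_plus = NA_real_, ratio_minus = NA_real_,
    sigma_plus = NA_real_, sigma_minus = NA_real_,
    phi = as.numeric(phi), sigma_phi = as.numeric(sigma_phi),
    bleached_any = !is.finite(phi),
    construct = construct, pH = pH
  )
  structure(out, class = c("phi_profile", class(tibble())))
}

#' pH difference of the effective net charge
#'
#' `delta_phi = phi(low pH) - phi(high pH)` per residue, with quadrature
#' uncertainty.  Residues bleached or missing at either pH are excluded
#' and listed in the `excluded` attribute with a reason.
#'
#' @param phi_low,phi_high `phi_profile`s at the lower and higher pH
#'   (conventionally 6.5 and 7.5).
#' @return A tibble `residue_index`, `methyl_id`, `phi_low`, `phi_high`,
#'   `sigma_low`, `sigma_high`, `delta_phi`, `sigma_delta_phi`; excluded
#'   residues in `attr(, "excluded")`.
#' @export
delta_phi <- function(phi_low, phi_high) {
  stopifnot(inherits(phi_low, "phi_profile"), inherits(phi_high, "phi_profile"))
  key <- c("residue_index", "methyl_id")
  lo <- dplyr::select(as_tibble(phi_low), dplyr::all_of(key),
                      phi_low = "phi", sigma_low = "sigma_phi")
  hi <- dplyr::select(as_tibble(phi_high), dplyr::all_of(key),
                      phi_high = "phi", sigma_high = "sigma_phi")
  j <- dplyr::full_join(lo, hi, by = key)
  ok <- is.finite(j$phi_low) & is.finite(j$phi_high)
  if (!any(ok)) {
    abort_empty("No residue has a numeric phi at both pH values.")
  }
  excluded <- tibble(
    residue_index = j$residue_index[!ok],
    methyl_id = j$methyl_id[!ok],
    reason = dplyr::case_when(
      !is.finite(j$phi_low[!ok]) & !is.finite(j$phi_high[!ok]) ~ "unavailable at both pH",
      !is.finite(j$phi_low[!ok]) ~ "bleached/missing at low pH",
      TRUE ~ "bleached/missing at high pH"
    )
  )
  out <- j[ok, ]
  out$delta_phi <- out$phi_low - out$phi_high
  out$sigma_delta_phi <- sqrt(out$sigma_low^2 + out$sigma_high^2)
  structure(
    dplyr::arrange(out, .data$residue_index, .data$methyl_id),
    excluded = excluded,
    class = c("delta_phi", class(tibble()))
  )
}

#' Residues excluded from a phi comparison
#' @param x An object carrying an `excluded` attribute
#'   ([delta_phi()], [significance_filter()]).
#' @return A tibble of excluded residues with reasons.
#' @export
excluded_residues <- function(x) attr(x, "excluded") %||% tibble()

#' Significance filter for effective net charge divergence
#'
#' Identifies residues whose pH response of the effective net charge
#' differs significantly between two constructs (e.g. a point mutant vs
#' wild type).  For each residue with numeric phi in all four samples
#' (two constructs x two pHs) it computes
#' `ddphi = |delta_phi(mut) - delta_phi(wt)|` where
#' `delta_phi = phi(low pH) - phi(high pH)`, and applies two filters:
#'
#' * `passes_ddphi`: `ddphi >= ddphi_threshold` (default 0.4);
#' * `passes_sigma_filter`: in all four underlying samples the phi
#'   uncertainty satisfies `sigma_phi <= sigma_fraction * |phi|`
#'   (default 20%).
#'
#' `significant` is the conjunction of the two.  Residues missing any of
#' the four samples are excluded with a reason (see
#' [excluded_residues()]); the full per-residue audit trail (all phi and
#' sigma values, both deltas, both flags) is retained in the output.
#'
#' @param wt_low,wt_high `phi_profile`s of the reference construct at the
#'   low and high pH.
#' @param mut_low,mut_high `phi_profile`s of the comparison construct.
#' @param ddphi_threshold Minimum `|ddphi|` called significant (default 0.4).
#' @param sigma_fraction Maximum allowed `sigma_phi / |phi|` in each of
#'   the four samples (default 0.2).
#' @return A `significance` tibble with one row per testable residue and
#'   an `excluded` attribute.
#' @export
significance_filter <- function(wt_low, wt_high, mut_low, mut_high,
                                ddphi_threshold = 0.4, sigma_fraction = 0.2) {
  check_number(ddphi_threshold, "ddphi_threshold", nonneg = TRUE)
  check_number(sigma_fraction, "sigma_fraction", nonneg = TRUE)
  key <- c("residue_index", "methyl_id")
  pull <- function(p, tag) {
    stopifnot(inherits(p, "phi_profile"))
    d <- dplyr::select(as_tibble(p), dplyr::all_of(key), "phi", "sigma_phi")
    names(d)[3:4] <- paste0(c("phi_", "sigma_"), tag)
    d
  }
  j <- Reduce(
    function(x, y) dplyr::full_join(x, y, by = key),
    list(pull(wt_low, "wt_low"), pull(wt_high, "wt_high"),
         pull(mut_low, "mut_low"), pull(mut_high, "mut_high"))
  )
  if (nrow(j) == 0L) abort_empty("No residues in the four input sets.")
  phis <- as.matrix(j[, paste0("phi_", c("wt_low", "wt_high", "mut_low", "mut_high"))])
  sigs <- as.matrix(j[, paste0("sigma_", c("wt_low", "wt_high", "mut_low", "mut_high"))])
  complete <- rowSums(!is.finite(phis)) == 0L
  excluded <- tibble(
    residue_index = j$residue_index[!complete],
    methyl_id = j$methyl_id[!complete],
    reason = as.character(
      apply(!is.finite(phis[!complete, , drop = FALSE]), 1L, function(m) {
        paste("missing/bleached:",
              paste(c("wt_low", "wt_high", "mut_low", "mut_high")[m], collapse = ", "))
      })
    )
  )
  k <- j[complete, ]
  delta_wt <- k$phi_wt_low - k$phi_wt_high
  delta_mut <- k$phi_mut_low - k$phi_mut_high
  ddphi <- abs(delta_mut - delta_wt)
  sig_ok <- rowSums(
    sigs[complete, , drop = FALSE] >
      sigma_fraction * abs(phis[complete, , drop = FALSE])
  ) == 0L
  out <- tibble(
    residue_index = k$residue_index,
    methyl_id = k$methyl_id,
    phi_wt_low = k$phi_wt_low, phi_wt_high = k$phi_wt_high,
    phi_mut_low = k$phi_mut_low, phi_mut_high = k$phi_mut_high,
    sigma_wt_low = k$sigma_wt_low, sigma_wt_high = k$sigma_wt_high,
    sigma_mut_low = k$sigma_mut_low, sigma_mut_high = k$sigma_mut_high,
    delta_phi_wt = delta_wt,
    delta_phi_mut = delta_mut,
    ddphi = ddphi,
    passes_ddphi = ddphi >= ddphi_threshold,
    passes_sigma_filter = sig_ok,
    significant = (ddphi >= ddphi_threshold) & sig_ok
  )
  structure(
    dplyr::arrange(out, .data$residue_index, .data$methyl_id),
    excluded = excluded,
    ddphi_threshold = ddphi_threshold,
    sigma_fraction = sigma_fraction,
    class = c("significance", class(tibble()))
  )
}
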