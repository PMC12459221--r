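#' Synthetic two-population loop ensemble model
#'
#' Ground-truth forward model for spin-label PRE experiments: the label
#' samples a small set of positions (a conformational ensemble with
#' weights), each NMR-visible methyl probe sits at a fixed position, and
#' the PRE rate at a probe is the population-weighted fast-exchange
#' average `Gamma2 = K * sum_i w_i * r_i^-6` over label-probe distances.
#' The Solomon-Bloembergen spectral-density prefactor is lumped into the
#' single calibratable constant `K`; by default `K` is calibrated so that
#' a label 25 Angstroms away attenuates the peak by ~5% over the
#' evolution time (`Gamma2(25 A) * t = 0.05`), reproducing the ~25 A
#' observability ceiling of nitroxide probes.
#'
#' @param members n x 3 matrix of label positions in Angstroms.
#' @param probe_sites Named list (or 3-column matrix with rownames) of
#'   probe coordinates; names like `"V197"` encode residue type + index.
#' @param weights Ensemble populations (positive, normalized to sum 1;
#'   default uniform).
#' @param pre_scale_K Lumped PRE prefactor in Angstrom^6 s^-1; default
#'   `0.05 / evolution_time_s * 25^6`.
#' @param evolution_time_s Transverse evolution time in seconds over
#'   which PRE attenuation acts (default 0.01).
#' @param base_intensity Diamagnetic peak intensity in arbitrary units.
#' @param noise_sigma Gaussian peak-noise standard deviation, same units.
#' @return A `loop_ensemble_model`.
#' @export
loop_ensemble_model <- function(members, probe_sites, weights = NULL,
                                pre_scale_K = NULL, evolution_time_s = 0.01,
                                base_intensity = 1e5, noise_sigma = 1e3) {
  members <- as.matrix(members)
  stopifnot(ncol(members) == 3L)
  if (!all(is.finite(members))) abort_validation("Label positions must be finite.")
  if (is.null(weights)) weights <- rep(1 / nrow(members), nrow(members))
  check_number(weights, "weights", positive = TRUE)
  if (length(weights) != nrow(members)) {
    abort_validation("One weight per ensemble member is required.")
  }
  weights <- weights / sum(weights)
  if (is.matrix(probe_sites)) {
    probe_sites <- setNames(
      lapply(seq_len(nrow(probe_sites)), function(i) probe_sites[i, ]),
      rownames(probe_sites)
    )
  }
  stopifnot(is.list(probe_sites), !is.null(names(probe_sites)))
  lapply(probe_sites, function(p) check_number(p, "probe_sites"))
  check_number(evolution_time_s, "evolution_time_s", positive = TRUE)
  if (is.null(pre_scale_K)) pre_scale_K <- 0.05 / evolution_time_s * 25^6
  check_number(pre_scale_K, "pre_scale_K", positive = TRUE)
  check_number(base_intensity, "base_intensity", positive = TRUE)
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  if (noise_sigma >= base_intensity) {
    abort_validation("noise_sigma must be smaller than base_intensity.")
  }
  structure(
    list(members = members, weights = weights, probe_sites = probe_sites,
         pre_scale_K = pre_scale_K, evolution_time_s = evolution_time_s,
         base_intensity = base_intensity, noise_sigma = noise_sigma),
    class = "loop_ensemble_model"
  )
}

#' Ensemble-averaged PRE rate at a probe site
#'
#' `Gamma2 = K * sum_i w_i * |label_i - probe|^-6`: the fast-exchange
#' population-weighted r^-6 average, monotone decreasing in every
#' label-probe distance.  A minor population making close approaches
#' dominates the rate (e.g. 8% of the weight at 10 A outweighs 92% at
#' 40 A by a factor ~350), which is why transient loop excursions are
#' detectable by PRE.
#'
#' @param model A [loop_ensemble_model()].
#' @param residue Probe name(s) in `names(model$probe_sites)`; default all.
#' @return Named vector of rates in s^-1.
#' @export
gamma2_from_ensemble <- function(model, residue = names(model$probe_sites)) {
  stopifnot(inherits(model, "loop_ensemble_model"))
  missing_res <- setdiff(residue, names(model$probe_sites))
  if (length(missing_res)) {
    abort_validation(sprintf("Unknown probe site(s): %s",
                             paste(missing_res, collapse = ", ")))
  }
  vapply(residue, function(res) {
    p <- model$probe_sites[[res]]
    d2 <- rowSums(sweep(model$members, 2L, p)^2)
    if (any(d2 == 0)) {
      abort_validation(sprintf(
        "Label position coincides with probe %s (r = 0 singularity).", res
      ))
    }
    model$pre_scale_K * sum(model$weights * d2^(-3))
  }, numeric(1))
}

methyl_label <- function(res_name) {
  first <- substr(res_name, 1L, 1L)
  suffix <- c(V = "g1", I = "d1", L = "d1")[first]
  paste0(res_name, "-", ifelse(is.na(suffix), "m", suffix))
}

residue_number <- function(res_name) as.integer(gsub("[^0-9]", "", res_name))

synth_records <- function(res_names, intensity, noise_sigma) {
  tibble(
    residue_index = residue_number(res_names),
    residue_name = substr(res_names, 1L, 1L),
    methyl_id = methyl_label(res_names),
    shift_H_ppm = NA_real_,
    shift_C_ppm = NA_real_,
    intensity = unname(intensity),
    noise_sigma = pmax(unname(noise_sigma), 1e-12)
  )
}

#' Generate diamagnetic/paramagnetic peak tables from the forward model
#'
#' Realizes the measurement model behind the PRE ratio analysis:
#' `I_dia = base + noise` and
#' `I_para = base * exp(-Gamma2 * t) / c_true + noise`, clipped at zero,
#' with `Gamma2` from the r^-6 ensemble average at each probe.  The
#' paramagnetic sample metadata carries `protein_conc_uM` scaled by
#' `c_true` so that [build_pre_profile()] recovers the planted
#' concentration correction; with no noise the recovered ratios equal
#' `exp(Gamma2 * t)` exactly.
#'
#' @param model A [loop_ensemble_model()].
#' @param residues Probe names to realize (default all).
#' @param c_true Planted paramagnetic/diamagnetic concentration ratio.
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   tables.
#' @param state Allosteric state recorded in the metadata.
#' @return A list `dia`, `para` (both `peak_table`) and `truth` (a tibble
#'   of planted `gamma2_true`, `ratio_true`, and zero-clipping flags).
#' @export
generate_pre_tables <- function(model, residues = names(model$probe_sites),
                                c_true = 1, seed = 1L, state = "trp") {
  stopifnot(inherits(model, "loop_ensemble_model"))
  check_number(c_true, "c_true", positive = TRUE)
  set.seed(seed)
  g2 <- gamma2_from_ensemble(model, residues)
  n <- length(residues)
  i_dia_true <- rep(model$base_intensity, n)
  i_para_true <- model$base_intensity * exp(-g2 * model$evolution_time_s) / c_true
  i_dia <- i_dia_true + rnorm(n, 0, model$noise_sigma)
  i_para <- i_para_true + rnorm(n, 0, model$noise_sigma)
  clipped_dia <- i_dia < 0
  clipped_para <- i_para < 0
  i_dia <- pmax(i_dia, 0)
  i_para <- pmax(i_para, 0)

  meta_common <- list(state = state, pH = 6.5, nacl_mM = 150,
                      construct = "S220C-TEMPO", covalent_label = TRUE)
  meta_dia <- do.call(sample_meta, c(meta_common, list(
    magnetic = "diamagnetic", protein_conc_uM = 200
  )))
  meta_para <- do.call(sample_meta, c(meta_common, list(
    magnetic = "paramagnetic", protein_conc_uM = 200 * c_true
  )))
  list(
    dia = peak_table(synth_records(residues, i_dia, model$noise_sigma), meta_dia),
    para = peak_table(synth_records(residues, i_para, model$noise_sigma), meta_para),
    truth = tibble(
      residue = residues,
      residue_index = residue_number(residues),
      gamma2_true = unname(g2),
      ratio_true = exp(unname(g2) * model$evolution_time_s),
      clipped_dia = clipped_dia,
      clipped_para = clipped_para
    )
  )
}

#' Synthetic near-surface charge model for solvent PREs
#'
#' Ground truth for the dual-cosolute experiment: each residue carries a
#' signed dimensionless near-surface charge parameter `psi`, and the
#' solvent-PRE rate under each cosolute couples to it Boltzmann-like:
#' `Gamma2(minus cosolute) = g0 * exp(+coupling * psi)` and
#' `Gamma2(plus cosolute) = g0 * exp(-coupling * psi)` (the negatively
#' charged cosolute is enriched at positive patches).  With the default
#' sign convention of [phi_value()], the recovered phi correlates
#' positively with the planted psi.
#'
#' @param psi Named numeric vector: residue name (e.g. `"V197"`) to
#'   signed charge parameter.
#' @param cosolute_coupling Positive coupling strength (default 1).
#' @param base_gamma2_per_s Neutral-surface sPRE rate in s^-1 (default 5).
#' @return A `surface_charge_model`.
#' @export
surface_charge_model <- function(psi, cosolute_coupling = 1,
                                 base_gamma2_per_s = 5) {
  check_number(psi, "psi")
  stopifnot(!is.null(names(psi)))
  check_number(cosolute_coupling, "cosolute_coupling", positive = TRUE)
  check_number(base_gamma2_per_s, "base_gamma2_per_s", positive = TRUE)
  structure(
    list(psi = psi, cosolute_coupling = cosolute_coupling,
         base_gamma2_per_s = base_gamma2_per_s),
    class = "surface_charge_model"
  )
}

#' Generate the three-sample solvent-PRE peak tables
#'
#' Realizes the cosolute-free (diamagnetic), positive-cosolute and
#' negative-cosolute spectra of the effective-net-charge experiment from
#' a [surface_charge_model()].  All three samples share the same protein
#' concentration (c = 1).
#'
#' @param scm A [surface_charge_model()].
#' @param residues Residues to realize (default all of `names(scm$psi)`).
#' @param seed Integer RNG seed.
#' @param evolution_time_s,base_intensity,noise_sigma Acquisition
#'   parameters, as in [loop_ensemble_model()].
#' @param construct,pH Metadata recorded on all three samples.
#' @return A list `dia`, `plus`, `minus` (peak tables) and `truth`
#'   (planted psi, per-cosolute rates, and the noiseless phi).
#' @export
generate_spre_tables <- function(scm, residues = names(scm$psi), seed = 1L,
                                 evolution_time_s = 0.01,
                                 base_intensity = 1e5, noise_sigma = 2e3,
                                 construct = "WT", pH = 6.5) {
  stopifnot(inherits(scm, "surface_charge_model"))
  check_number(evolution_time_s, "evolution_time_s", positive = TRUE)
  check_number(base_intensity, "base_intensity", positive = TRUE)
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  set.seed(seed)
  psi <- scm$psi[residues]
  g_minus <- scm$base_gamma2_per_s * exp(+scm$cosolute_coupling * psi)
  g_plus <- scm$base_gamma2_per_s * exp(-scm$cosolute_coupling * psi)
  n <- length(residues)
  noisy <- function(mu) pmax(mu + rnorm(n, 0, noise_sigma), 0)
  i_dia <- noisy(rep(base_intensity, n))
  i_plus <- noisy(base_intensity * exp(-g_plus * evolution_time_s))
  i_minus <- noisy(base_intensity * exp(-g_minus * evolution_time_s))

  mk_meta <- function(magnetic, cosolute) {
    sample_meta(state = "trp", magnetic = magnetic, cosolute = cosolute,
                pH = pH, nacl_mM = 150, protein_conc_uM = 200,
                construct = construct)
  }
  list(
    dia = peak_table(synth_records(residues, i_dia, noise_sigma),
                     mk_meta("diamagnetic", "none")),
    plus = peak_table(synth_records(residues, i_plus, noise_sigma),
                      mk_meta("paramagnetic", "plus")),
    minus = peak_table(synth_records(residues, i_minus, noise_sigma),
                       mk_meta("paramagnetic", "minus")),
    truth = tibble(
      residue = residues,
      residue_index = residue_number(residues),
      psi = unname(psi),
      gamma2_plus = unname(g_plus),
      gamma2_minus = unname(g_minus),
      phi_true = exp(unname(g_minus) * evolution_time_s) -
        exp(unname(g_plus) * evolution_time_s)
    )
  )
}

# Random rigid transform (proper rotation + translation), applied to an
# n x 3 coordinate block.
random_rigid_transform <- function(coords, spread = 50) {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  shift <- runif(3L, -spread, spread)
  sweep(coords %*% q, 2L, shift, "+")
}

#' Generate dimer snapshots with a planted close-approach fraction
#'
#' Builds explicit 3D coordinates for a homodimer with one loop atom
#' (S220 hydroxyl proton) and one active-site atom (V197 methyl proton)
#' per chain, so that the distance census measures, not reads, the
#' planted distances.  Per frame, each of the two inter-protomer
#' loop-site distances is drawn from `close_range` with probability
#' `f_close_inter` and from `far_range` otherwise; both intra-protomer
#' distances are always drawn from `far_range`.  When the four planted
#' distances admit no 3D embedding (the two triangle-inequality windows
#' on the site-site separation are disjoint), only the intra distances
#' are redrawn - still within `far_range` - so the planted close/far
#' assignment of the inter pairs is never altered.  Each frame receives a
#' random rigid rotation and translation.
#'
#' @param n_frames Number of frames (default 600).
#' @param f_close_inter Probability that an inter-protomer pair is close
#'   in a frame (default 0.08).
#' @param close_range,far_range Distance windows in Angstroms; must be
#'   disjoint with `far_range` above `close_range`.
#' @param seed Integer RNG seed.
#' @param frame_interval_ns Time spacing metadata (default 1 ns).
#' @return A list `snapshots` (a `snapshot_set`) and `truth` (per-frame
#'   planted distances and close flags, plus the realized close counts).
#' @export
generate_snapshots <- function(n_frames = 600, f_close_inter = 0.08,
                               close_range = c(5, 15), far_range = c(25, 45),
                               seed = 1L, frame_interval_ns = 1) {
  check_number(n_frames, "n_frames", positive = TRUE)
  check_number(f_close_inter, "f_close_inter", nonneg = TRUE)
  if (f_close_inter > 1) abort_validation("`f_close_inter` must be <= 1.")
  check_number(close_range, "close_range", positive = TRUE)
  check_number(far_range, "far_range", positive = TRUE)
  if (close_range[2] > far_range[1]) {
    abort_validation("`close_range` and `far_range` must be disjoint (far above close).")
  }
  set.seed(seed)

  draw <- function(range) runif(1L, range[1], range[2])
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    close_ab <- runif(1L) < f_close_inter
    close_ba <- runif(1L) < f_close_inter
    d_ab <- draw(if (close_ab) close_range else far_range)
    d_ba <- draw(if (close_ba) close_range else far_range)
    # intra draws, redrawn until the two windows on the site-site
    # separation D overlap (always possible near the far-range floor)
    repeat {
      d_aa <- draw(far_range)
      d_bb <- draw(far_range)
      lo <- max(abs(d_aa - d_ab), abs(d_ba - d_bb))
      hi <- min(d_aa + d_ab, d_ba + d_bb)
      if (hi - lo > 1e-3) break
    }
    margin <- 0.05 * (hi - lo)
    D <- runif(1L, lo + margin, hi - margin)

    site_a <- c(0, 0, 0)
    site_b <- c(D, 0, 0)
    xa <- (d_aa^2 - d_ab^2 + D^2) / (2 * D)
    loop_a <- c(xa, sqrt(max(d_aa^2 - xa^2, 0)), 0)
    xb <- (d_ba^2 - d_bb^2 + D^2) / (2 * D)
    loop_b <- c(xb, 0, sqrt(max(d_ba^2 - xb^2, 0)))

    coords <- random_rigid_transform(rbind(loop_a, site_a, loop_b, site_b))
    dimnames(coords) <- NULL
    frames[[f]] <- tibble(
      frame = f,
      chain = c("A", "A", "B", "B"),
      resno = c(220L, 197L, 220L, 197L),
      resname = c("SER", "VAL", "SER", "VAL"),
      atom = c("HG1", "HG11", "HG1", "HG11"),
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    )
    truth[[f]] <- tibble(
      frame = f, close_ab = close_ab, close_ba = close_ba,
      d_inter_ab = d_ab, d_inter_ba = d_ba,
      d_intra_aa = d_aa, d_intra_bb = d_bb
    )
  }
  truth <- dplyr::bind_rows(truth)
  snaps <- new_snapshot_set(dplyr::bind_rows(frames), frame_interval_ns)
  list(
    snapshots = snaps,
    truth = structure(
      truth,
      f_close_inter = f_close_inter,
      n_close_inter = sum(truth$close_ab) + sum(truth$close_ba)
    )
  )
}
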