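# Fixtures are built in code at test time; nothing binary is stored.

meta_dia <- function(...) {
  sample_meta(state = "trp", magnetic = "diamagnetic", construct = "S220C-TEMPO",
              covalent_label = TRUE, ...)
}

meta_para <- function(...) {
  sample_meta(state = "trp", magnetic = "paramagnetic", construct = "S220C-TEMPO",
              covalent_label = TRUE, ...)
}

# A small well-formed peak record block.
demo_records <- function(n = 5, intensity = 100, noise = 2) {
  res <- c(12L, 20L, 31L, 197L, 211L, 214L, 225L, 237L)[seq_len(n)]
  nm <- c("L12-d1", "V20-g1", "I31-d1", "V197-g1", "V211-g1",
          "V214-g1", "I225-d1", "I237-d1")[seq_len(n)]
  tibble::tibble(
    residue_index = res,
    residue_name = substr(nm, 1, 1),
    methyl_id = nm,
    shift_H_ppm = 0.5 + 0.01 * seq_len(n),
    shift_C_ppm = 22 + 0.1 * seq_len(n),
    intensity = rep_len(intensity, n),
    noise_sigma = rep_len(noise, n)
  )
}

write_peak_file <- function(df, path, delim = "\t") {
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  path
}

# Monte-Carlo oracle for the ratio / phi uncertainty (independent of the
# analytic propagation under test).
mc_ratio_sigma <- function(i_dia, s_dia, i_para, s_para, cc = 1,
                           n = 1e5, seed = 42) {
  set.seed(seed)
  stats::sd(rnorm(n, i_dia, s_dia) / (rnorm(n, i_para, s_para) * cc))
}

mc_phi_sigma <- function(r_minus, s_minus, r_plus, s_plus, n = 1e5, seed = 42) {
  set.seed(seed)
  stats::sd(rnorm(n, r_minus, s_minus) - rnorm(n, r_plus, s_plus))
}

# Brute-force distance census: plain double loop over frames and chain
# pairs, no shared code with distance_series().
brute_force_census <- function(atoms, loop_resno = 220, loop_atom = "HG1",
                               site_resno = 197, site_atom = "HG11") {
  frames <- sort(unique(atoms$frame))
  chains <- sort(unique(atoms$chain))
  rows <- list()
  k <- 0L
  for (f in frames) {
    for (lc in chains) {
      la <- atoms[atoms$frame == f & atoms$chain == lc &
                    atoms$resno == loop_resno & atoms$atom == loop_atom, ]
      for (sc in chains) {
        sa <- atoms[atoms$frame == f & atoms$chain == sc &
                      atoms$resno == site_resno & atoms$atom == site_atom, ]
        k <- k + 1L
        rows[[k]] <- data.frame(
          frame = f, loop_chain = lc, site_chain = sc,
          class = if (lc == sc) "intra" else "inter",
          distance_A = sqrt((la$x - sa$x)^2 + (la$y - sa$y)^2 + (la$z - sa$z)^2)
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Backward-constructed significance fixture: four phi profiles in which
# exactly `planted` passes the ddphi >= 0.4 AND sigma <= 20% filter.
# Decoys fail one criterion each; one residue is absent from a sample.
significance_fixture <- function(planted = c(12L, 19L, 104L, 185L, 201L,
                                             211L, 214L, 237L, 238L, 251L)) {
  ddphi_small <- c(30L, 45L, 60L)    # fails the ddphi threshold
  sigma_fail <- c(70L, 85L)          # passes ddphi, fails the 20% filter
  incomplete <- 90L                  # missing from mut_high
  residues <- sort(c(planted, ddphi_small, sigma_fail, incomplete))
  n <- length(residues)

  phi_wt_low <- rep(1.0, n)
  phi_wt_high <- rep(0.8, n)          # delta_phi_wt = 0.2 everywhere
  phi_mut_high <- rep(0.8, n)
  ddphi <- numeric(n)
  ddphi[residues %in% planted] <- 0.45 + 0.02 * seq_along(planted)
  ddphi[residues %in% ddphi_small] <- 0.10
  ddphi[residues %in% sigma_fail] <- 0.60
  ddphi[residues %in% incomplete] <- 0.60
  phi_mut_low <- phi_mut_high + 0.2 + ddphi  # delta_phi_mut = 0.2 + ddphi

  sig_frac <- rep(0.10, n)
  sig_frac[residues %in% sigma_fail] <- 0.25

  mk <- function(phi, frac, drop = NULL, pH) {
    keep <- !(residues %in% drop)
    phi_profile(residues[keep], phi[keep], frac[keep] * abs(phi[keep]), pH = pH)
  }
  list(
    wt_low = mk(phi_wt_low, rep(0.10, n), pH = 6.5),
    wt_high = mk(phi_wt_high, rep(0.10, n), pH = 7.5),
    mut_low = mk(phi_mut_low, sig_frac, pH = 6.5),
    mut_high = mk(phi_mut_high, rep(0.10, n), drop = incomplete, pH = 7.5),
    planted = planted,
    ddphi = setNames(ddphi, residues)
  )
}
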