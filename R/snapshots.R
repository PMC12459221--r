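#' Atom selector for distance measurements
#'
#' Identifies one atom per chain per frame by residue number and an
#' ordered vector of candidate atom names.  The first candidate present
#' in a frame is used, which lets a proton selector fall back to its
#' parent heavy atom on heavy-atom-only snapshots (the ~1 Angstrom offset
#' is negligible against the 15/25 Angstrom thresholds); any fallback is
#' reported.  The defaults target the serine hydroxyl proton at the loop
#' centre and a valine methyl gamma-1 proton at the active site.
#'
#' @param residue_index Residue number.
#' @param atom_names Character vector of candidate atom names, highest
#'   priority first.
#' @return An `atom_selector`.
#' @export
atom_selector <- function(residue_index, atom_names) {
  stopifnot(length(atom_names) >= 1L)
  structure(
    list(residue_index = as.integer(residue_index),
         atom_names = as.character(atom_names)),
    class = "atom_selector"
  )
}

#' @rdname atom_selector
#' @export
loop_selector_default <- function() atom_selector(220L, c("HG1", "HG", "OG"))

#' @rdname atom_selector
#' @export
site_selector_default <- function() {
  atom_selector(197L, c("HG11", "1HG1", "CG1"))
}

new_snapshot_set <- function(atoms, frame_interval_ns = NA_real_,
                             rejected_frames = tibble()) {
  structure(
    as_tibble(atoms),
    frame_interval_ns = frame_interval_ns,
    rejected_frames = rejected_frames,
    class = c("snapshot_set", class(tibble()))
  )
}

#' Read homodimer coordinate snapshots
#'
#' Ingests exported simulation snapshots from either a multi-model PDB
#' file (one MODEL per frame) or a per-frame coordinate table (TSV with
#' columns `frame`, `chain`, `resno`, `atom`, `x`, `y`, `z`, and
#' optionally `resname`).  Both chains of the dimer must be present.
#' Frames in which any required selector cannot be resolved on every
#' chain are rejected with a warning and listed in the `rejected_frames`
#' attribute.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"tsv"`.
#' @param require List of [atom_selector()]s that must resolve in every
#'   retained frame; defaults to the loop and active-site selectors.
#'   `NULL` skips the per-frame check.
#' @param frame_interval_ns Optional time spacing metadata.
#' @return A `snapshot_set`: a tibble of per-frame atom coordinates in
#'   Angstroms.
#' @export
read_snapshots <- function(path, format = c("auto", "pdb", "tsv"),
                           require = list(loop_selector_default(),
                                          site_selector_default()),
                           frame_interval_ns = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_format(sprintf("Snapshot file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  }
  atoms <- if (format == "pdb") read_snapshots_pdb(path) else read_snapshots_tsv(path)

  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    bad <- unique(atoms$frame[!(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))])
    abort_format(sprintf("Non-finite coordinates in frame(s) %s.",
                         paste(bad, collapse = ", ")))
  }
  chains <- sort(unique(atoms$chain))
  if (length(chains) < 2L) {
    abort_validation(
      "Snapshots contain a single chain; a homodimer (two chains) is required."
    )
  }

  rejected <- tibble()
  if (!is.null(require)) {
    frames <- sort(unique(atoms$frame))
    ok <- vapply(frames, function(f) {
      fa <- atoms[atoms$frame == f, ]
      all(vapply(chains, function(ch) {
        ca <- fa[fa$chain == ch, ]
        all(vapply(require, function(sel) {
          any(ca$resno == sel$residue_index & ca$atom %in% sel$atom_names)
        }, logical(1)))
      }, logical(1)))
    }, logical(1))
    if (any(!ok)) {
      rejected <- tibble(frame = frames[!ok],
                         reason = "required selector atom missing")
      warn(sprintf("Rejected %d frame(s) missing required atoms: %s",
                   sum(!ok), paste(frames[!ok], collapse = ", ")))
      atoms <- atoms[atoms$frame %in% frames[ok], ]
      if (nrow(atoms) == 0L) {
        abort_validation("All frames were rejected for missing required atoms.")
      }
    }
  }
  new_snapshot_set(atoms, frame_interval_ns, rejected)
}

read_snapshots_pdb <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort_format(sprintf("Unparsable PDB: %s", conditionMessage(e)))
  )
  n_frames <- nrow(pdb$xyz)
  n_atoms <- nrow(pdb$atom)
  per_frame <- lapply(seq_len(n_frames), function(f) {
    m <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
    tibble(
      frame = f,
      chain = pdb$atom$chain,
      resno = as.integer(pdb$atom$resno),
      resname = pdb$atom$resid,
      atom = pdb$atom$elety,
      x = m[, 1], y = m[, 2], z = m[, 3]
    )
  })
  dplyr::bind_rows(per_frame)
}

read_snapshots_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  needed <- c("frame", "chain", "resno", "atom", "x", "y", "z")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort_format(sprintf("Snapshot TSV missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  tibble(
    frame = as.integer(raw$frame),
    chain = as.character(raw$chain),
    resno = as.integer(raw$resno),
    resname = if ("resname" %in% names(raw)) as.character(raw$resname) else NA_character_,
    atom = as.character(raw$atom),
    x = as.numeric(raw$x), y = as.numeric(raw$y), z = as.numeric(raw$z)
  )
}

#' Write snapshots to multi-model PDB or TSV
#'
#' The TSV form preserves full coordinate precision; the PDB form rounds
#' to the standard 3 decimal places.
#'
#' @param snaps A `snapshot_set`.
#' @param path Output path; format chosen by extension (`.pdb` vs
#'   anything else = TSV) unless `format` is given.
#' @param format `"auto"`, `"pdb"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snaps, path, format = c("auto", "pdb", "tsv")) {
  stopifnot(inherits(snaps, "snapshot_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(as_tibble(snaps), path, progress = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in sort(unique(snaps$frame))) {
    fa <- snaps[snaps$frame == f, ]
    writeLines(sprintf("MODEL     %4d", f), con)
    nm <- ifelse(nchar(fa$atom) < 4L, sprintf(" %-3s", fa$atom), fa$atom)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      seq_len(nrow(fa)), nm,
      ifelse(is.na(fa$resname), "UNK", fa$resname),
      fa$chain, fa$resno, fa$x, fa$y, fa$z, substr(fa$atom, 1L, 1L)
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Resolve one selector over all (frame, chain) groups; returns one row
# per group with the chosen atom and its priority among the candidates.
resolve_selector <- function(atoms, sel, role) {
  hits <- atoms[atoms$resno == sel$residue_index &
                  atoms$atom %in% sel$atom_names, ]
  if (nrow(hits) == 0L) {
    abort_selection(sprintf(
      "Selector %s (residue %d, atoms %s) matches no atom.",
      role, sel$residue_index, paste(sel$atom_names, collapse = "/")
    ))
  }
  hits$priority <- match(hits$atom, sel$atom_names)
  picked <- dplyr::slice_min(dplyr::group_by(hits, .data$frame, .data$chain),
                             .data$priority, with_ties = TRUE)
  picked <- dplyr::ungroup(picked)
  counts <- dplyr::count(picked, .data$frame, .data$chain)
  if (any(counts$n > 1L)) {
    bad <- counts[counts$n > 1L, ][1L, ]
    matches <- picked$atom[picked$frame == bad$frame & picked$chain == bad$chain]
    abort_selection(sprintf(
      "Selector %s is ambiguous in frame %d chain %s: matches %s.",
      role, bad$frame, bad$chain, paste(matches, collapse = ", ")
    ))
  }
  missing <- nrow(dplyr::distinct(atoms[, c("frame", "chain")])) - nrow(picked)
  if (missing > 0L) {
    abort_validation(sprintf(
      "Selector %s does not resolve in every frame/chain (%d group(s) missing); reread with read_snapshots(require=...) to drop incomplete frames.",
      role, missing
    ))
  }
  picked
}

#' Loop-to-active-site distance census over all chain pairings
#'
#' For every frame, measures the Euclidean distance from the loop atom of
#' each chain to the active-site atom of each chain: four values per
#' frame for a dimer (A->A, A->B, B->A, B->B).  Same-chain pairs are
#' classed `"intra"`, cross-chain pairs `"inter"`.  Coordinates are used
#' as exported; no periodic-boundary correction is applied.
#'
#' @param snaps A `snapshot_set` (two chains).
#' @param loop_sel,site_sel [atom_selector()]s for the loop and
#'   active-site atoms; defaults target the S220 hydroxyl proton and the
#'   V197 gamma-1 methyl proton, with heavy-atom fallback.
#' @return A `distance_census` tibble: `frame`, `loop_chain`,
#'   `site_chain`, `class` (`"intra"`/`"inter"`), `distance_A`.  Atom
#'   names actually used are in `attr(, "atoms_used")`; a warning is
#'   issued when a fallback (non-primary) atom name was used.
#' @export
distance_series <- function(snaps, loop_sel = loop_selector_default(),
                            site_sel = site_selector_default()) {
  stopifnot(inherits(snaps, "snapshot_set"))
  chains <- sort(unique(snaps$chain))
  if (length(chains) != 2L) {
    abort_validation(sprintf(
      "Expected exactly two chains (homodimer); found %d (%s).",
      length(chains), paste(chains, collapse = ", ")
    ))
  }
  loops <- resolve_selector(as_tibble(snaps), loop_sel, "loop")
  sites <- resolve_selector(as_tibble(snaps), site_sel, "site")
  atoms_used <- tibble(
    role = c("loop", "site"),
    atom = c(paste(sort(unique(loops$atom)), collapse = ","),
             paste(sort(unique(sites$atom)), collapse = ","))
  )
  if (any(loops$priority > 1L) || any(sites$priority > 1L)) {
    warn("Primary selector atom absent in some frames; fell back to an alternative atom (see attr(, 'atoms_used')).")
  }
  l <- dplyr::select(loops, "frame", loop_chain = "chain",
                     lx = "x", ly = "y", lz = "z")
  s <- dplyr::select(sites, "frame", site_chain = "chain",
                     sx = "x", sy = "y", sz = "z")
  j <- dplyr::inner_join(l, s, by = "frame", relationship = "many-to-many")
  out <- tibble(
    frame = j$frame,
    loop_chain = j$loop_chain,
    site_chain = j$site_chain,
    class = ifelse(j$loop_chain == j$site_chain, "intra", "inter"),
    distance_A = sqrt((j$lx - j$sx)^2 + (j$ly - j$sy)^2 + (j$lz - j$sz)^2)
  )
  structure(
    dplyr::arrange(out, .data$frame, .data$loop_chain, .data$site_chain),
    atoms_used = atoms_used,
    class = c("distance_census", class(tibble()))
  )
}

census_class <- function(census, class) {
  stopifnot(inherits(census, "distance_census"))
  class <- match.arg(class, c("inter", "intra"))
  d <- census$distance_A[census$class == class]
  if (length(d) == 0L) {
    abort_empty(sprintf("No %s-protomer records in the census.", class))
  }
  d
}

#' Close-approach fraction of a distance class
#'
#' Fraction of distances in the half-open interval `[low, high)` among
#' all records of the requested class, computed from exact integer
#' counts.  The default 5--15 Angstrom window corresponds to the
#' separation range over which a nitroxide label produces strong PRE
#' broadening.
#'
#' @param census A `distance_census`.
#' @param class `"inter"` or `"intra"`.
#' @param low,high Window bounds in Angstroms (half-open `[low, high)`).
#' @return Fraction in `[0, 1]`.
#' @export
close_fraction <- function(census, class = c("inter", "intra"),
                           low = 5, high = 15) {
  check_number(low, "low", nonneg = TRUE)
  check_number(high, "high", positive = TRUE)
  d <- census_class(census, class)
  sum(d >= low & d < high) / length(d)
}

#' Minimum distance within a class
#'
#' Exact minimum over all records of the requested class; used to verify
#' e.g. that intra-protomer approaches never enter the PRE-detectable
#' range (25 Angstroms for a nitroxide label).
#'
#' @inheritParams close_fraction
#' @return Minimum distance in Angstroms.
#' @export
min_class_distance <- function(census, class = c("inter", "intra")) {
  min(census_class(census, class))
}

#' Distance histogram per class
#'
#' @inheritParams close_fraction
#' @param binwidth Bin width in Angstroms (default 1).
#' @return A tibble `class`, `bin_low`, `bin_high`, `count`; counts per
#'   class sum to the number of records of that class.
#' @export
distance_histogram <- function(census, binwidth = 1) {
  stopifnot(inherits(census, "distance_census"))
  check_number(binwidth, "binwidth", positive = TRUE)
  hi <- ceiling(max(census$distance_A) / binwidth) * binwidth
  breaks <- seq(0, hi + binwidth, by = binwidth)
  dplyr::bind_rows(lapply(sort(unique(census$class)), function(cl) {
    d <- census$distance_A[census$class == cl]
    idx <- findInterval(d, breaks, rightmost.closed = FALSE, left.open = FALSE)
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    keep <- counts > 0L
    tibble(
      class = cl,
      bin_low = breaks[-length(breaks)][keep],
      bin_high = breaks[-1L][keep],
      count = counts[keep]
    )
  }))
}
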