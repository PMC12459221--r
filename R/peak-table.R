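#' Sample metadata for a peak table
#'
#' Describes the experimental condition under which one 2D methyl spectrum
#' was recorded: allosteric state (which effector is bound), whether the
#' sample is paramagnetic or diamagnetic, which charged cosolute (if any)
#' is present, buffer pH and salt, protein concentration, and the construct
#' label.  A paramagnetic sample must carry its paramagnetic centre: either
#' a charged cosolute or a covalently attached spin label.
#'
#' @param state Allosteric state of the enzyme: `"apo"`, `"trp"`
#'   (activator-bound) or `"tyr"` (inhibitor-bound).
#' @param magnetic `"diamagnetic"` (reduced label / no cosolute) or
#'   `"paramagnetic"` (oxidized label or paramagnetic cosolute present).
#' @param cosolute Charged solvent probe: `"none"`, `"plus"` (positively
#'   charged nitroxide) or `"minus"` (negatively charged nitroxide).
#' @param pH Buffer pH (typically 6.0--8.0).
#' @param nacl_mM NaCl concentration in mM.
#' @param protein_conc_uM Protein concentration in micromolar; must be > 0.
#'   Ratios of the paramagnetic to diamagnetic concentration supply the
#'   concentration correction `c` used by [intensity_ratio()].
#' @param construct Free-text construct label, e.g. `"WT"`, `"D215A"`,
#'   `"S220C-TEMPO"`.
#' @param covalent_label `TRUE` when a spin label is covalently attached
#'   (required for a paramagnetic sample without cosolute).
#' @param evolution_delays_ms Optional ordered pair `c(Ta, Tb)` of
#'   transverse evolution delays in ms for two-time-point rate data;
#'   requires `Tb > Ta >= 0`.
#'
#' @return An object of class `sample_meta`.
#' @seealso [read_peak_table()], [pair_tables()]
#' @export
#' @examples
#' sample_meta(state = "trp", magnetic = "paramagnetic",
#'             construct = "S220C-TEMPO", covalent_label = TRUE)
sample_meta <- function(state = c("apo", "trp", "tyr"),
                        magnetic = c("diamagnetic", "paramagnetic"),
                        cosolute = c("none", "plus", "minus"),
                        pH = 7.0,
                        nacl_mM = 150,
                        protein_conc_uM = 200,
                        construct = "WT",
                        covalent_label = FALSE,
                        evolution_delays_ms = NULL) {
  state <- match.arg(state)
  magnetic <- match.arg(magnetic)
  cosolute <- match.arg(cosolute)
  check_number(pH, "pH")
  check_number(nacl_mM, "nacl_mM", nonneg = TRUE)
  check_number(protein_conc_uM, "protein_conc_uM", positive = TRUE)
  if (magnetic == "paramagnetic" && cosolute == "none" && !isTRUE(covalent_label)) {
    abort_validation(
      "A paramagnetic sample needs a paramagnetic centre: set cosolute to 'plus'/'minus' or covalent_label = TRUE."
    )
  }
  if (!is.null(evolution_delays_ms)) {
    check_number(evolution_delays_ms, "evolution_delays_ms", nonneg = TRUE)
    if (length(evolution_delays_ms) != 2L ||
        evolution_delays_ms[2] <= evolution_delays_ms[1]) {
      abort_validation("`evolution_delays_ms` must be an ordered pair (Ta, Tb) with Tb > Ta >= 0.")
    }
  }
  structure(
    list(
      state = state, magnetic = magnetic, cosolute = cosolute,
      pH = pH, nacl_mM = nacl_mM, protein_conc_uM = protein_conc_uM,
      construct = construct, covalent_label = isTRUE(covalent_label),
      evolution_delays_ms = evolution_delays_ms
    ),
    class = "sample_meta"
  )
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf(
    "<sample_meta> %s %s / %s, cosolute=%s, pH %.2f, %g mM NaCl, %g uM\n",
    x$construct, x$state, x$magnetic, x$cosolute, x$pH, x$nacl_mM,
    x$protein_conc_uM
  ))
  invisible(x)
}

#' Read sample metadata blocks from a sidecar file
#'
#' The sidecar is a YAML (or JSON) file with one named block per sample;
#' each block holds `sample_meta()` fields.
#'
#' @param path Path to the YAML/JSON sidecar.
#' @return A named list of `sample_meta` objects.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) {
    abort_format(sprintf("Metadata file not found: %s", path))
  }
  blocks <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == "")) {
    abort_format("Metadata sidecar must contain named sample blocks.")
  }
  lapply(blocks, function(b) {
    if ("evolution_delays_ms" %in% names(b)) {
      b$evolution_delays_ms <- as.numeric(unlist(b$evolution_delays_ms))
    }
    do.call(sample_meta, b)
  })
}

required_peak_columns <- c("residue_index", "methyl_id", "intensity", "noise_sigma")

validate_peak_records <- function(records) {
  if (nrow(records) == 0L) {
    abort_validation("Peak table has no records.")
  }
  if (any(records$noise_sigma <= 0)) {
    bad <- records$methyl_id[records$noise_sigma <= 0]
    abort_validation(sprintf(
      "noise_sigma must be > 0; offending peaks: %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  if (any(records$intensity < 0)) {
    abort_validation("Peak intensities must be >= 0.")
  }
  key <- paste(records$residue_index, records$methyl_id, sep = "/")
  if (anyDuplicated(key)) {
    dups <- unique(records$methyl_id[duplicated(key)])
    abort_validation(
      sprintf("Duplicate (residue, methyl) keys: %s", paste(dups, collapse = ", ")),
      duplicates = dups
    )
  }
  invisible(records)
}

new_peak_table <- function(records, meta) {
  stopifnot(inherits(meta, "sample_meta"))
  validate_peak_records(records)
  structure(
    as_tibble(records),
    meta = meta,
    class = c("peak_table", class(tibble())))
}

#' Construct a peak table from in-memory records
#'
#' @param records A data frame with columns `residue_index`, `methyl_id`,
#'   `intensity`, `noise_sigma`, and optionally `residue_name`,
#'   `shift_H_ppm`, `shift_C_ppm`.
#' @param meta A [sample_meta()] object shared by all records.
#' @return A `peak_table`: a tibble with the sample metadata attached as
#'   the `meta` attribute.
#' @export
peak_table <- function(records, meta) {
  records <- as_tibble(records)
  missing_cols <- setdiff(required_peak_columns, names(records))
  if (length(missing_cols)) {
    abort_format(sprintf(
      "Missing required column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("residue_name", "shift_H_ppm", "shift_C_ppm")) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "residue_name") NA_character_ else NA_real_
    }
  }
  records$residue_index <- as.integer(records$residue_index)
  records <- records[, c("residue_index", "residue_name", "methyl_id",
                         "shift_H_ppm", "shift_C_ppm", "intensity", "noise_sigma")]
  new_peak_table(records, meta)
}

#' Extract the sample metadata of a peak table or profile
#' @param x A `peak_table` or derived profile object.
#' @return The attached `sample_meta` (or list of metas for derived objects).
#' @export
table_meta <- function(x) attr(x, "meta")

#' Read a peak-intensity table
#'
#' Reads one tabular peak list exported from spectral assignment software.
#' Both tab- and comma-separated files with a header row are accepted;
#' column names are matched case-insensitively.  Required columns are
#' `residue_index`, `methyl_id`, `intensity` and `noise_sigma`; the
#' chemical-shift columns `shift_H_ppm` / `shift_C_ppm` and `residue_name`
#' are optional.  Rows whose intensity is not numeric are rejected with
#' row-level diagnostics (a warning naming the rows, plus a `rejected`
#' attribute on the result).
#'
#' @param path Path to the TSV/CSV peak list.
#' @param meta A [sample_meta()] object, or the path of a metadata sidecar
#'   containing exactly one block (see [read_sample_meta()]).
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path, meta, delim = NULL) {
  if (!file.exists(path)) {
    abort_format(sprintf("Peak table not found: %s", path))
  }
  if (is.character(meta)) {
    blocks <- read_sample_meta(meta)
    if (length(blocks) != 1L) {
      abort_format("Sidecar referenced from read_peak_table() must contain exactly one sample block.")
    }
    meta <- blocks[[1L]]
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE
  )
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(required_peak_columns, names(raw))
  if (length(missing_cols)) {
    abort_format(
      sprintf("Missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      missing_columns = missing_cols
    )
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  intensity <- num(raw$intensity)
  bad_rows <- which(is.na(intensity))
  if (length(bad_rows)) {
    warn(sprintf(
      "Rejected %d row(s) with non-numeric intensity: row(s) %s",
      length(bad_rows), paste(bad_rows, collapse = ", ")
    ))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad_rows)
  records <- tibble(
    residue_index = as.integer(num(raw$residue_index[keep])),
    residue_name = if ("residue_name" %in% names(raw)) raw$residue_name[keep] else NA_character_,
    methyl_id = raw$methyl_id[keep],
    shift_H_ppm = if ("shift_h_ppm" %in% names(raw)) num(raw$shift_h_ppm[keep]) else NA_real_,
    shift_C_ppm = if ("shift_c_ppm" %in% names(raw)) num(raw$shift_c_ppm[keep]) else NA_real_,
    intensity = intensity[keep],
    noise_sigma = num(raw$noise_sigma[keep])
  )
  out <- new_peak_table(records, meta)
  if (length(bad_rows)) {
    attr(out, "rejected") <- tibble(row = bad_rows, reason = "non-numeric intensity")
  }
  out
}

#' Write a peak table to delimited text
#'
#' Numeric fields are written at full precision so that a write/read
#' round trip reproduces all text-representable values exactly.  Sample
#' metadata is not embedded; keep it in a sidecar (see
#' [read_sample_meta()]).
#'
#' @param x A `peak_table`.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "peak_table"))
  readr::write_delim(as_tibble(x), path, delim = delim, progress = FALSE)
  invisible(path)
}

meta_compatible <- function(a, b) {
  fields <- character(0)
  if (!identical(a$state, b$state)) fields <- c(fields, "state")
  if (!identical(a$construct, b$construct)) fields <- c(fields, "construct")
  if (abs(a$pH - b$pH) > 1e-9) fields <- c(fields, "pH")
  fields
}

#' Pair diamagnetic and paramagnetic peak tables
#'
#' Matches records on the `(residue_index, methyl_id)` key.  Records
#' present in only one table are never dropped silently: they are listed
#' in the unmatched reports, and peaks present in the diamagnetic table
#' but absent from the paramagnetic one are additionally flagged as
#' candidate bleached peaks (complete signal loss under strong PRE is the
#' usual reason a paramagnetic peak goes missing).
#'
#' @param dia,para `peak_table`s of the diamagnetic and paramagnetic
#'   sample.  Their metadata must agree on state, construct and pH; the
#'   magnetic and cosolute fields are expected to differ.
#' @return A list of class `peak_pairing` with elements `pairs` (one row
#'   per matched key, intensities and noise from both tables),
#'   `unmatched_dia`, `unmatched_para`, and `candidate_bleached` (keys of
#'   diamagnetic-only peaks).
#' @export
pair_tables <- function(dia, para) {
  stopifnot(inherits(dia, "peak_table"), inherits(para, "peak_table"))
  bad <- meta_compatible(table_meta(dia), table_meta(para))
  if (length(bad)) {
    abort_pairing(sprintf(
      "Cannot pair tables: metadata differs in %s.", paste(bad, collapse = ", ")
    ))
  }
  key <- c("residue_index", "methyl_id")
  d <- dplyr::select(as_tibble(dia), dplyr::all_of(key), "residue_name",
                     i_dia = "intensity", sigma_dia = "noise_sigma",
                     shift_H_dia = "shift_H_ppm", shift_C_dia = "shift_C_ppm")
  p <- dplyr::select(as_tibble(para), dplyr::all_of(key),
                     i_para = "intensity", sigma_para = "noise_sigma",
                     shift_H_para = "shift_H_ppm", shift_C_para = "shift_C_ppm")
  pairs <- dplyr::inner_join(d, p, by = key)
  unmatched_dia <- dplyr::anti_join(as_tibble(dia), as_tibble(para), by = key)
  unmatched_para <- dplyr::anti_join(as_tibble(para), as_tibble(dia), by = key)
  structure(
    list(
      pairs = dplyr::arrange(pairs, .data$residue_index, .data$methyl_id),
      unmatched_dia = unmatched_dia,
      unmatched_para = unmatched_para,
      candidate_bleached = unmatched_dia[, key]
    ),
    meta_dia = table_meta(dia),
    meta_para = table_meta(para),
    class = "peak_pairing"
  )
}

#' @export
print.peak_pairing <- function(x, ...) {
  cat(sprintf(
    "<peak_pairing> %d pairs, %d dia-only (candidate bleached), %d para-only\n",
    nrow(x$pairs), nrow(x$unmatched_dia), nrow(x$unmatched_para)
  ))
  invisible(x)
}
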