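#' Read per-window Hamiltonian-difference samples
#'
#' Parses a two-column whitespace text file (xvg-like dialect) of
#' `time  dU` rows. Lines starting with `#` or `@` are comments. Energies
#' default to kJ/mol (GROMACS convention) and are converted to kcal/mol on
#' read (1 kcal = 4.184 kJ).
#'
#' @param path file path.
#' @param unit energy unit of the file: `"kJ/mol"` (default) or
#'   `"kcal/mol"`.
#' @param direction `"forward"` or `"reverse"`; recorded as an attribute
#'   for downstream assembly into a [window_samples()].
#' @return data frame with columns `time` (ps) and `du` (kcal/mol),
#'   attribute `direction`.
#' @seealso [read_window_samples()]
#' @export
read_dhdl <- function(path, unit = c("kJ/mol", "kcal/mol"),
                      direction = c("forward", "reverse")) {
  unit <- match.arg(unit)
  direction <- match.arg(direction)
  if (!file.exists(path)) {
    .fail(sprintf("file not found: %s", path), "felbind_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (length(data_lines) == 0L) {
    .fail(sprintf("no data lines in %s", path), "felbind_empty_input_error")
  }
  line_no <- which(keep)
  parsed <- lapply(seq_along(data_lines), function(i) {
    fields <- strsplit(trimws(data_lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      .fail(sprintf("malformed numeric line %d in %s: '%s'",
                    line_no[i], path, data_lines[i]),
            "felbind_parse_error")
    }
    vals[1:2]
  })
  m <- do.call(rbind, parsed)
  du <- m[, 2]
  if (unit == "kJ/mol") du <- du / .kJ_per_kcal
  structure(data.frame(time = m[, 1], du = du), direction = direction)
}

#' Assemble a window pair from forward and reverse sample files
#'
#' @param forward_path,reverse_path dhdl-style files, see [read_dhdl()].
#' @param lambda_j,lambda_k lambda values of the two states.
#' @param temperature temperature in Kelvin.
#' @param unit energy unit of both files.
#' @return a [window_samples()] object.
#' @export
read_window_samples <- function(forward_path, reverse_path,
                                lambda_j, lambda_k, temperature = 298,
                                unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  fwd <- read_dhdl(forward_path, unit = unit, direction = "forward")
  rev <- read_dhdl(reverse_path, unit = unit, direction = "reverse")
  window_samples(lambda_j, lambda_k, fwd$du, rev$du, temperature)
}

#' Read a benchmark dataset of complexes
#'
#' Reads a CSV with one row per protein-ligand complex. Required columns:
#' `complex_id`, `affinity_value`, `affinity_unit`, `affinity_type`,
#' `dg_calculated`. Optional columns (absent fields allowed): any of
#' `dg_calculated_se`, `dg_correction`, `dg_correction_se`, `dg_corrected`,
#' `dg_experimental`. `affinity_type` is one of `IC50`, `Ki`, `direct_dG`;
#' for the first two the affinity value must be positive and the unit one
#' of `M`, `mM`, `uM`/`µM`, `nM`.
#'
#' @param path CSV file path.
#' @return data frame of class `complex_dataset` with one record per row.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    .fail(sprintf("file not found: %s", path), "felbind_input_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("complex_id", "affinity_value", "affinity_unit",
                "affinity_type", "dg_calculated")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .fail(sprintf("dataset is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "felbind_validation_error")
  }
  if (nrow(df) == 0L) {
    .fail("dataset has no data rows", "felbind_empty_input_error")
  }
  for (i in seq_len(nrow(df))) {
    type <- df$affinity_type[i]
    if (!type %in% c("IC50", "Ki", "direct_dG")) {
      .fail(sprintf("row %d (%s): unknown affinity_type '%s'",
                    i, df$complex_id[i], type),
            "felbind_validation_error")
    }
    if (type != "direct_dG") {
      tryCatch(.unit_factor(df$affinity_unit[i]), felbind_error = function(e) {
        .fail(sprintf("row %d (%s): unknown affinity_unit '%s'",
                      i, df$complex_id[i], df$affinity_unit[i]),
              "felbind_validation_error")
      })
      if (!is.finite(df$affinity_value[i]) || df$affinity_value[i] <= 0) {
        .fail(sprintf("row %d (%s): affinity_value must be positive",
                      i, df$complex_id[i]),
              "felbind_validation_error")
      }
    }
  }
  class(df) <- c("complex_dataset", "data.frame")
  df
}

#' Write a benchmark dataset or report table as CSV
#'
#' Plain CSV emission preserving full numeric precision (at least 6
#' significant digits survive a read/write round trip).
#'
#' @param x data frame (e.g. a `complex_dataset` or per-window report).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

## Atomic masses (amu) used when reading PDB records, keyed by element.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.990, K = 39.098,
  CA = 40.078)

#' Read atomic coordinates into a structure
#'
#' Accepts two plain-text dialects, auto-detected from the content:
#' \describe{
#'   \item{PDB subset}{`ATOM`/`HETATM` records; fixed-column coordinates
#'     in Angstrom are converted to nm; masses are assigned from the
#'     element column (or the first letter of the atom name).}
#'   \item{xyz + mass table}{whitespace-separated `mass x y z` rows, one
#'     atom per line, coordinates already in nm; `#` lines are comments.}
#' }
#'
#' @param path file path.
#' @return a [mol_structure()] with N >= 1 atoms and positive masses.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) {
    .fail(sprintf("file not found: %s", path), "felbind_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^(ATOM|HETATM)", lines))) {
    return(.read_pdb(lines, path))
  }
  .read_xyz_mass(lines, path)
}

.read_pdb <- function(lines, path) {
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(rec) == 0L) {
    .fail(sprintf("no ATOM/HETATM records in %s", path),
          "felbind_empty_input_error")
  }
  coords <- matrix(NA_real_, length(rec), 3)
  masses <- numeric(length(rec))
  for (i in seq_along(rec)) {
    l <- rec[i]
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz)) {
      .fail(sprintf("malformed coordinates in %s record %d", path, i),
            "felbind_parse_error")
    }
    coords[i, ] <- xyz / 10 # Angstrom -> nm
    elem <- toupper(trimws(substr(l, 77, 78)))
    if (!nzchar(elem)) {
      name <- trimws(substr(l, 13, 16))
      elem <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1, 1))
    }
    if (!elem %in% names(.element_masses)) {
      .fail(sprintf("unknown element '%s' in %s record %d", elem, path, i),
            "felbind_validation_error")
    }
    masses[i] <- .element_masses[[elem]]
  }
  mol_structure(coords, masses)
}

.read_xyz_mass <- function(lines, path) {
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- lines[keep]
  if (length(rows) == 0L) {
    .fail(sprintf("no data lines in %s", path), "felbind_empty_input_error")
  }
  line_no <- which(keep)
  m <- lapply(seq_along(rows), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]),
                                                 "\\s+")[[1]]))
    if (length(vals) != 4L || anyNA(vals)) {
      .fail(sprintf(
        "line %d in %s: expected 'mass x y z' (4 numeric fields)",
        line_no[i], path),
        "felbind_parse_error")
    }
    vals
  })
  m <- do.call(rbind, m)
  if (any(m[, 1] <= 0)) {
    .fail(sprintf("non-positive mass in %s", path),
          "felbind_validation_error")
  }
  mol_structure(m[, 2:4, drop = FALSE], m[, 1])
}

#' Serialize a free energy landscape as portable CSV
#'
#' Writes the grid as long-format CSV (`rg_index`, `rmsd_index`,
#' `rg_center`, `rmsd_center`, `count`, `g`) preceded by `#`-comment
#' header lines carrying the bin edges, `kT` and sample count, so the
#' grid reconstructs exactly.
#'
#' @param fel a [build_fel()] grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fel <- function(fel, path) {
  if (!inherits(fel, "fel_grid")) {
    .fail("`fel` must be a fel_grid", "felbind_input_error")
  }
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  header <- c(
    sprintf("# felbind fel v1"),
    sprintf("# kT %s", num(fel$kT)),
    sprintf("# n_samples %d", fel$n_samples),
    sprintf("# rg_edges %s", num(fel$rg_edges)),
    sprintf("# rmsd_edges %s", num(fel$rmsd_edges)))
  idx <- which(fel$counts >= 0, arr.ind = TRUE)
  rg_c <- (fel$rg_edges[-1] + fel$rg_edges[-length(fel$rg_edges)]) / 2
  rmsd_c <- (fel$rmsd_edges[-1] + fel$rmsd_edges[-length(fel$rmsd_edges)]) / 2
  df <- data.frame(rg_index = idx[, 1], rmsd_index = idx[, 2],
                   rg_center = rg_c[idx[, 1]],
                   rmsd_center = rmsd_c[idx[, 2]],
                   count = fel$counts[idx],
                   g = fel$g[idx])
  df <- df[df$count > 0, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a landscape written by [write_fel()]
#'
#' @param path CSV file path.
#' @return a `fel_grid` identical (to numeric precision) to the one
#'   written.
#' @export
read_fel <- function(path) {
  if (!file.exists(path)) {
    .fail(sprintf("file not found: %s", path), "felbind_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  get <- function(key) {
    l <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (length(l) != 1L) {
      .fail(sprintf("missing '%s' header in %s", key, path),
            "felbind_parse_error")
    }
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", l), "\\s+")[[1]])
  }
  kt <- get("kT")
  n_samples <- as.integer(get("n_samples"))
  rg_edges <- get("rg_edges")
  rmsd_edges <- get("rmsd_edges")
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  counts <- matrix(0L, length(rg_edges) - 1L, length(rmsd_edges) - 1L)
  counts[cbind(df$rg_index, df$rmsd_index)] <- df$count
  g <- matrix(NA_real_, nrow(counts), ncol(counts))
  g[cbind(df$rg_index, df$rmsd_index)] <- df$g
  structure(list(rg_edges = rg_edges, rmsd_edges = rmsd_edges,
                 g = g, counts = counts, kT = kt, n_samples = n_samples),
            class = "fel_grid")
}
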