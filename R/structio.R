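#' Read a (multi-model) PDB file of backbone coordinates
#'
#' Parses fixed-column ATOM records of a PDB file into one
#' [chain_coordinates()] per MODEL. Files without MODEL records are read as a
#' single model. Only backbone heavy atoms (N, CA, C, O, CB) are retained;
#' other atom names are ignored. A missing CB is tolerated (always absent on
#' glycine); a missing backbone atom is an error naming the residue, and a
#' malformed ATOM record is a parse error naming the offending line.
#'
#' @param path PDB file path.
#' @return list of `chain_coordinates`, one per model.
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- NULL
  flush_model <- function(rows) {
    if (is.null(rows) || nrow(rows) == 0L) return(NULL)
    chain_coordinates(rows$residue_id, rows$residue_name, rows$atom,
                      cbind(rows$x, rows$y, rows$z))
  }
  cur_rows <- NULL
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      cur_rows <- data.frame()
    } else if (r == "ENDMDL") {
      models[[length(models) + 1L]] <- flush_model(cur_rows)
      cur_rows <- NULL
    } else if (r == "ATOM  ") {
      ln <- lines[i]
      if (nchar(ln) < 54)
        stop("malformed ATOM record (too short) at line ", i)
      atom <- trimws(substr(ln, 13, 16))
      resn <- trimws(substr(ln, 18, 20))
      resi <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (is.na(resi) || is.na(x) || is.na(y) || is.na(z))
        stop("malformed ATOM record at line ", i)
      if (!(atom %in% ALLOWED_ATOMS)) next
      row <- data.frame(residue_id = resi, residue_name = resn, atom = atom,
                        x = x, y = y, z = z, stringsAsFactors = FALSE)
      if (is.null(cur_rows)) cur_rows <- data.frame()
      cur_rows <- rbind(cur_rows, row)
    }
  }
  tail_model <- flush_model(cur_rows)
  if (!is.null(tail_model)) models[[length(models) + 1L]] <- tail_model
  if (length(models) == 0L) stop("no ATOM records found in ", path)
  models
}

#' Write chains as a multi-model PDB file
#'
#' Fixed-column ATOM records, one MODEL/ENDMDL block per conformer, chain id
#' `A`, occupancy 1.00, B-factor 0.00, coordinates to 3 decimals (the same
#' dialect [read_pdb_models()] reads, so write-then-read is the identity on
#' ids, atom names and coordinates to 1e-3 A).
#'
#' @param models a single `chain_coordinates` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "chain_coordinates")) models <- list(models)
  if (length(models) == 0L) stop("empty model list")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_along(models)) {
    ch <- models[[m]]
    stopifnot(inherits(ch, "chain_coordinates"))
    writeLines(sprintf("MODEL     %4d", m), con)
    nm <- ch$atom
    # PDB atom-name column convention: 1-3 char names start in column 14
    nm_fmt <- sprintf(" %-3s", nm)
    lines <- sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(ch)), nm_fmt, ch$residue_name, ch$residue_id,
      ch$x, ch$y, ch$z)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Chemical-shift table
#'
#' Observed chemical shifts, one row per (residue, atom). Atom names are
#' restricted to `CA, CB, C, HA, N, HN`; shifts must be finite and in a
#' plausible ppm range for the nucleus (e.g. CA in 40-70 ppm).
#'
#' @param residue_id integer vector.
#' @param residue_name three-letter residue codes.
#' @param atom atom names.
#' @param shift chemical shifts in ppm.
#' @return a `shift_table` data frame.
#' @export
shift_table <- function(residue_id, residue_name, atom, shift) {
  tab <- data.frame(residue_id = as.integer(residue_id),
                    residue_name = toupper(as.character(residue_name)),
                    atom = toupper(as.character(atom)),
                    shift = as.numeric(shift),
                    stringsAsFactors = FALSE)
  allowed <- c("CA", "CB", "C", "HA", "N", "HN")
  bad <- setdiff(unique(tab$atom), allowed)
  if (length(bad))
    stop("unknown shift atom name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab[, c("residue_id", "atom")]))
    stop("duplicate (residue, atom) row in shift table")
  if (!all(is.finite(tab$shift))) stop("non-finite chemical shift")
  ranges <- list(CA = c(40, 70), CB = c(10, 80), C = c(165, 185),
                 HA = c(1, 7), N = c(95, 140), HN = c(5, 12))
  for (a in names(ranges)) {
    s <- tab$shift[tab$atom == a]
    if (length(s) && (any(s < ranges[[a]][1]) || any(s > ranges[[a]][2])))
      stop("implausible ", a, " shift outside [",
           ranges[[a]][1], ", ", ranges[[a]][2], "] ppm")
  }
  class(tab) <- c("shift_table", "data.frame")
  tab
}

#' Read a chemical-shift table from disk
#'
#' Two dialects are supported. `csv`: a header line with columns
#' `residue_id, residue_name, atom, shift` (any order, extra columns
#' ignored). `nmrstar_lite`: the reduced NMR-STAR assigned-chemical-shift
#' loop as deposited for backbone assignments — a `loop_` block whose
#' `_Atom_chem_shift` tags include `Seq_ID` (or `Comp_index_ID`), `Comp_ID`,
#' `Atom_ID` and `Val`; rows with atom names outside the supported set are
#' skipped with a warning.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"nmrstar_lite"`.
#' @return a [shift_table()].
#' @export
read_shift_table <- function(path, dialect = c("csv", "nmrstar_lite")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("residue_id", "residue_name", "atom", "shift")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("shift CSV missing column(s): ", paste(miss, collapse = ", "))
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    tagpat <- "^_Atom_chem_shift\\.(\\S+)"
    tag_idx <- grep(tagpat, lines)
    if (!length(tag_idx)) stop("no _Atom_chem_shift loop found in ", path)
    tags <- sub(tagpat, "\\1", lines[tag_idx])
    body <- lines[(max(tag_idx) + 1L):length(lines)]
    stop_at <- which(body %in% c("stop_", "loop_") | grepl("^_", body))
    if (length(stop_at)) body <- body[seq_len(min(stop_at) - 1L)]
    body <- body[nzchar(body) & !startsWith(body, "#")]
    fields <- strsplit(body, "\\s+")
    ok <- vapply(fields, length, 1L) == length(tags)
    if (!all(ok)) stop("malformed NMR-STAR data row in ", path)
    mat <- do.call(rbind, fields)
    colnames(mat) <- tags
    seq_col <- intersect(c("Seq_ID", "Comp_index_ID"), tags)[1]
    if (is.na(seq_col) || !all(c("Comp_ID", "Atom_ID", "Val") %in% tags))
      stop("NMR-STAR loop lacks Seq_ID/Comp_ID/Atom_ID/Val tags")
    df <- data.frame(residue_id = as.integer(mat[, seq_col]),
                     residue_name = mat[, "Comp_ID"],
                     atom = toupper(mat[, "Atom_ID"]),
                     shift = as.numeric(mat[, "Val"]),
                     stringsAsFactors = FALSE)
    # deposition uses H for the amide proton
    df$atom[df$atom == "H"] <- "HN"
  }
  allowed <- c("CA", "CB", "C", "HA", "N", "HN")
  unknown <- !(toupper(df$atom) %in% allowed)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " row(s) with unsupported atom name: ",
            paste(unique(df$atom[unknown]), collapse = ", "))
    df <- df[!unknown, , drop = FALSE]
  }
  shift_table(df$residue_id, df$residue_name, df$atom, df$shift)
}

#' Small-angle scattering curve
#'
#' @param q scattering vector magnitudes in 1/A, strictly increasing, >= 0.
#' @param I intensities (arbitrary units).
#' @param sigma point uncertainties; if `NULL`, defaulted to
#'   `pmax(0.01 * I, 1e-8)`.
#' @return a `scattering_curve` data frame with columns `q`, `I`, `sigma`.
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I lengths differ")
  if (any(q < 0)) stop("negative q")
  if (any(diff(q) <= 0)) stop("q not strictly increasing")
  if (is.null(sigma)) sigma <- pmax(0.01 * I, 1e-8)
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(q)) stop("sigma length differs")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  out <- data.frame(q = q, I = I, sigma = sigma)
  class(out) <- c("scattering_curve", "data.frame")
  out
}

#' Read a 3-column SAXS curve
#'
#' Whitespace-delimited text with 2 (q, I) or 3 (q, I, sigma) columns;
#' lines starting with `#` are comments. With 2 columns the uncertainty is
#' defaulted as in [scattering_curve()].
#'
#' @param path file path.
#' @return a [scattering_curve()].
#' @export
read_saxs_curve <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\\s+")
  ncol <- unique(vapply(fields, length, 1L))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L)))
    stop("SAXS file must have a constant 2 or 3 columns")
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE))
  if (anyNA(mat)) stop("non-numeric value in SAXS file ", path)
  scattering_curve(mat[, 1], mat[, 2],
                   sigma = if (ncol == 3L) mat[, 3] else NULL)
}

#' 1-D decay series (relaxation delay or gradient-strength series)
#'
#' @param x delay times in ms (relaxation) or gradient strengths in
#'   arbitrary units (diffusion), ascending.
#' @param y intensities.
#' @param kind `"relaxation"` or `"diffusion"`.
#' @return a `decay_series` data frame.
#' @export
decay_series <- function(x, y, kind = c("relaxation", "diffusion")) {
  kind <- match.arg(kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4L) stop("decay series needs >= 4 points for fitting")
  if (any(diff(x) <= 0)) stop("x not strictly ascending")
  if (!all(is.finite(y))) stop("non-finite intensity")
  out <- data.frame(x = x, y = y)
  attr(out, "kind") <- kind
  class(out) <- c("decay_series", "data.frame")
  out
}

# average residue masses (Da) of the 20 standard amino acids, plus one water
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_AVG_MASS <- 18.0153

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water, for an unmodified linear
#' peptide given as a 1-letter sequence. Used to check construct identity
#' against the monomer mass seen by native mass spectrometry.
#'
#' @param sequence character string of 1-letter residue codes.
#' @return average molecular mass in Da.
#' @export
peptide_average_mass <- function(sequence) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(aa, names(AA_AVG_MASS))
  if (length(bad)) stop("unknown residue code(s): ",
                        paste(unique(bad), collapse = ", "))
  sum(AA_AVG_MASS[aa]) + WATER_AVG_MASS
}
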